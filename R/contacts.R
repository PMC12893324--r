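## State-specific noncovalent contact tables: parsing, collapsing,
## residue contact-dynamics classification, and class-effect comparisons.

CONTACT_CODES <- c(sb = "salt_bridge", pc = "pi_cation",
                   hbss = "hb_sidechain_sidechain",
                   hbsb = "hb_sidechain_backbone")

parse_contact_atom <- function(atom) {
  parts <- stringr::str_split_fixed(atom, ":", 4)
  bad <- parts[, 4] == "" | is.na(suppressWarnings(as.integer(parts[, 3])))
  if (any(bad)) {
    stop("malformed atom identifier: ", paste(atom[bad][1]),
         " (expected chain:resname:resid:atom)")
  }
  tibble::tibble(chain = parts[, 1], res_name = parts[, 2],
                 resid = as.integer(parts[, 3]), atom = parts[, 4])
}

#' Parse a contact table
#'
#' Reads a tab-separated contact table (comment lines starting with `#`;
#' columns frame, interaction-type code, atom1, atom2, with atoms encoded
#' as `chain:resname:resid:atom`), maps atom-level rows to residue pairs,
#' keeps only the four conformation-specific interaction types (salt
#' bridges, pi-cation, side chain-side chain and side chain-backbone
#' hydrogen bonds), drops self-pairs, and canonicalises each unordered
#' pair.
#'
#' @param x Path to a TSV file or a character vector of its lines.
#' @param state `"active"` or `"inactive"` label attached to the records.
#' @return Tibble `interaction_type`, `residue_a`, `residue_b`, `state`
#'   (duplicated rows collapsed).
#' @export
parse_contacts <- function(x, state) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble::tibble(interaction_type = character(),
                          residue_a = integer(), residue_b = integer(),
                          state = character()))
  }
  f <- stringr::str_split_fixed(lines, "\t", 4)
  if (any(f[, 4] == "")) {
    stop("malformed contact row: expected 4 tab-separated columns")
  }
  code <- f[, 2]
  keep <- code %in% names(CONTACT_CODES)
  f <- f[keep, , drop = FALSE]
  a1 <- parse_contact_atom(f[, 3])
  a2 <- parse_contact_atom(f[, 4])
  out <- tibble::tibble(
    interaction_type = unname(CONTACT_CODES[f[, 2]]),
    residue_a = pmin(a1$resid, a2$resid),
    residue_b = pmax(a1$resid, a2$resid),
    state = state)
  out <- out[out$residue_a != out$residue_b, ]
  dplyr::distinct(out)
}

#' Collapse duplicate contacts
#'
#' Contacts of the same type between the same residue pair are collapsed
#' into one record; a pair annotated both as salt bridge and side
#' chain-side chain hydrogen bond is collapsed to the salt bridge.
#' Idempotent.
#'
#' @param records Contact tibble as returned by [parse_contacts()].
#' @return Deduplicated contact tibble.
#' @export
collapse_contacts <- function(records) {
  r <- dplyr::distinct(tibble::as_tibble(records))
  key <- paste(r$residue_a, r$residue_b, if ("state" %in% names(r))
    r$state else "")
  is_sb <- r$interaction_type == "salt_bridge"
  is_hbss <- r$interaction_type == "hb_sidechain_sidechain"
  drop <- is_hbss & key %in% key[is_sb]
  r[!drop, ]
}

#' Classify residues by contact dynamics
#'
#' For each residue and interaction type, compares the sets of contact
#' partners in the active- and inactive-state structures: `static` when the
#' partner sets are equal and non-empty, `active_only` / `inactive_only`
#' when one set is empty, `swapping` when both are non-empty but differ.
#' Partner comparison is by partner residue identity. Exchanging the two
#' input states maps active_only to inactive_only and leaves swapping and
#' static fixed.
#'
#' @param active,inactive Collapsed contact tibbles for the two states.
#' @return Tibble `residue`, `interaction_type`, `klass`.
#' @export
classify_residue_dynamics <- function(active, inactive) {
  expand <- function(r, st) {
    dplyr::bind_rows(
      tibble::tibble(residue = r$residue_a, partner = r$residue_b,
                     interaction_type = r$interaction_type),
      tibble::tibble(residue = r$residue_b, partner = r$residue_a,
                     interaction_type = r$interaction_type)) |>
      dplyr::mutate(state = st)
  }
  both <- dplyr::bind_rows(expand(collapse_contacts(active), "active"),
                           expand(collapse_contacts(inactive), "inactive"))
  both |>
    dplyr::group_by(.data$residue, .data$interaction_type) |>
    dplyr::summarise(klass = {
      pa <- sort(unique(.data$partner[.data$state == "active"]))
      pi_ <- sort(unique(.data$partner[.data$state == "inactive"]))
      if (!length(pa) && !length(pi_)) "none"
      else if (!length(pi_)) "active_only"
      else if (!length(pa)) "inactive_only"
      else if (identical(pa, pi_)) "static"
      else "swapping"
    }, .groups = "drop")
}

#' Compare energy-effect distributions across contact classes
#'
#' Two-sided Wilcoxon rank-sum tests on |ddGa| between residue contact
#' classes, per interaction type, BH-adjusted across all comparisons.
#' Classes with fewer than `min_n` mutations are excluded.
#'
#' @param classes Output of [classify_residue_dynamics()].
#' @param energies Tibble with per-mutation `ddGa_mean` and `position`
#'   (or `mutation` ids to parse).
#' @param min_n Minimum mutations per class.
#' @return Tibble `interaction_type`, `class_a`, `class_b`, `n_a`, `n_b`,
#'   `p_value`, `fdr`.
#' @export
compare_class_effects <- function(classes, energies, min_n = 3) {
  e <- tibble::as_tibble(energies)
  if (!"position" %in% names(e)) {
    e$position <- parse_mutation(e$mutation)$position
  }
  joined <- dplyr::inner_join(tibble::as_tibble(classes), e,
                              by = c(residue = "position"),
                              relationship = "many-to-many")
  rows <- list()
  for (ty in unique(joined$interaction_type)) {
    sub <- joined[joined$interaction_type == ty, ]
    counts <- table(sub$klass)
    kl <- names(counts)[counts >= min_n]
    if (length(kl) < 2) next
    for (i in seq_len(length(kl) - 1)) {
      for (j in seq(i + 1, length(kl))) {
        xa <- abs(sub$ddGa_mean[sub$klass == kl[i]])
        xb <- abs(sub$ddGa_mean[sub$klass == kl[j]])
        p <- stats::wilcox.test(xa, xb, exact = FALSE)$p.value
        rows[[length(rows) + 1]] <- tibble::tibble(
          interaction_type = ty, class_a = kl[i], class_b = kl[j],
          n_a = length(xa), n_b = length(xb), p_value = p)
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(interaction_type = character(),
                          class_a = character(), class_b = character(),
                          n_a = integer(), n_b = integer(),
                          p_value = numeric(), fdr = numeric()))
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(fdr = bh_fdr(.data$p_value))
}
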