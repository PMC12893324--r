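## Mutation classification (z-tests + FDR) and Fisher-exact enrichments.

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up adjustment with monotonicity enforcement; input order is
#' preserved.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

one_sided_p <- function(mean, sd, boundary, direction) {
  # direction "greater": P(effect <= boundary) small when mean >> boundary
  z <- (boundary - mean) / sd
  p <- ifelse(direction == "greater", stats::pnorm(z),
              stats::pnorm(z, lower.tail = FALSE))
  # sd = 0: infinite z; call p = 0 when the point estimate is past the
  # boundary, 1 otherwise
  zero_sd <- sd == 0
  if (any(zero_sd)) {
    past <- ifelse(direction == "greater", mean > boundary, mean < boundary)
    p[zero_sd] <- ifelse(past[zero_sd], 0, 1)
  }
  p
}

#' Classify mutations by their energy effects
#'
#' For each energy, tests each mutation against the signed effect-size
#' boundary with a one-sided z-test (`Z = (boundary - mean)/sd`, normal
#' p-value): `+threshold` for destabilising/inactivating calls,
#' `-threshold` for stabilising/activating calls, choosing the boundary on
#' the side of the point estimate. P-values are BH-adjusted across all
#' tested mutations per energy, and a label is assigned iff
#' `|mean| > threshold` and `FDR < fdr_cut`.
#'
#' @param estimates Tibble with columns `mutation`, `ddGf_mean`, `ddGf_sd`,
#'   `ddGa_mean`, `ddGa_sd` (kcal/mol).
#' @param threshold Effect-size boundary in kcal/mol.
#' @param fdr_cut FDR cutoff for labelling.
#' @return Input tibble with `fdr_f`, `fdr_a`, logical `stabilizing`,
#'   `destabilizing`, `activating`, `inactivating` columns and a
#'   convenience `label_f` / `label_a` string.
#' @export
classify_mutations <- function(estimates, threshold = 0.5, fdr_cut = 0.1) {
  e <- tibble::as_tibble(estimates)
  need <- c("mutation", "ddGf_mean", "ddGf_sd", "ddGa_mean", "ddGa_sd")
  stopifnot(all(need %in% names(e)))
  test_energy <- function(mean, sd) {
    dir <- ifelse(mean >= 0, "greater", "less")
    boundary <- ifelse(mean >= 0, threshold, -threshold)
    bh_fdr(one_sided_p(mean, sd, boundary, dir))
  }
  e$fdr_f <- test_energy(e$ddGf_mean, e$ddGf_sd)
  e$fdr_a <- test_energy(e$ddGa_mean, e$ddGa_sd)
  e$destabilizing <- e$ddGf_mean > threshold & e$fdr_f < fdr_cut
  e$stabilizing <- e$ddGf_mean < -threshold & e$fdr_f < fdr_cut
  e$inactivating <- e$ddGa_mean > threshold & e$fdr_a < fdr_cut
  e$activating <- e$ddGa_mean < -threshold & e$fdr_a < fdr_cut
  e$label_f <- dplyr::case_when(e$destabilizing ~ "destabilizing",
                                e$stabilizing ~ "stabilizing",
                                TRUE ~ "none")
  e$label_a <- dplyr::case_when(e$inactivating ~ "inactivating",
                                e$activating ~ "activating",
                                TRUE ~ "none")
  e
}

#' Fisher's exact enrichment of a 2x2 table
#'
#' Two-sided exact (hypergeometric) p-value with the sample odds ratio
#' `(a*d)/(b*c)`; the OR is reported as `Inf` (or 0) when a zero cell makes
#' it undefined, with no continuity correction — the p-value carries the
#' inference, the OR is descriptive.
#'
#' @param in_group Counts `c(hits, non_hits)` inside the group.
#' @param out_group Counts `c(hits, non_hits)` outside the group.
#' @return Tibble with `odds_ratio`, `p_value` and the four counts.
#' @export
fisher_enrichment <- function(in_group, out_group) {
  cnt <- c(in_group, out_group)
  if (any(cnt < 0)) stop("negative counts")
  if (sum(cnt) == 0) stop("empty table")
  m <- matrix(cnt, 2, 2, byrow = TRUE)
  p <- stats::fisher.test(m)$p.value
  a <- m[1, 1]; b <- m[1, 2]; c_ <- m[2, 1]; d <- m[2, 2]
  or <- if (b * c_ == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c_)
  tibble::tibble(odds_ratio = or, p_value = min(p, 1),
                 a = a, b = b, c = c_, d = d)
}

#' Enrichment of a mutation class across residue groups
#'
#' For each group, builds the 2x2 table of class-positive vs class-negative
#' mutations inside vs outside the group, computes [fisher_enrichment()],
#' and BH-adjusts across groups.
#'
#' @param mutations Tibble with a `position` column and a logical column
#'   named by `class_col`.
#' @param groups Tibble with columns `position` and `group` assigning each
#'   position to a group (e.g. secondary-structure element).
#' @param class_col Name of the logical class column in `mutations`.
#' @return Tibble per group: counts, `odds_ratio`, `p_value`, `fdr`.
#' @export
group_enrichment <- function(mutations, groups, class_col) {
  m <- dplyr::inner_join(tibble::as_tibble(mutations),
                         tibble::as_tibble(groups), by = "position")
  hit <- m[[class_col]]
  out <- m |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(a = sum(.data[[class_col]]),
                     b = sum(!.data[[class_col]]), .groups = "drop") |>
    dplyr::mutate(c = sum(hit) - .data$a,
                  d = sum(!hit) - .data$b)
  res <- purrr::pmap_dfr(out[, c("a", "b", "c", "d")], function(a, b, c, d) {
    fisher_enrichment(c(a, b), c(c, d))[, c("odds_ratio", "p_value")]
  })
  dplyr::bind_cols(out, res) |>
    dplyr::mutate(fdr = bh_fdr(.data$p_value))
}

#' Identify major allosteric sites
#'
#' A major allosteric site is a residue outside the active site that is
#' enriched in mutations that modulate activity beyond abundance effects.
#' Per residue, a Fisher's exact test compares its count of
#' activity-modulating (|ddGa|-significant) mutations with the rest of the
#' domain; p-values are BH-adjusted across residues, and residues passing
#' the OR and FDR cuts are returned, excluding active-site residues.
#' `mode = "inhibitory"` restricts the numerator to inactivating mutations
#' (same cuts); `mode = "activating"` uses activating mutations with the
#' conventional weaker cuts (OR > 1, unadjusted p < 0.05).
#'
#' @param classified Output of [classify_mutations()] with a `position`
#'   column (join [parse_mutation()] if needed).
#' @param active_site Integer vector of active-site residues (excluded from
#'   the output; empty set allowed with a warning).
#' @param or_cut,fdr_cut Enrichment cuts for `mode` `"all"`/`"inhibitory"`.
#' @param mode Which mutation class defines the enrichment.
#' @return Tibble per residue: counts, `odds_ratio`, `p_value`, `fdr`,
#'   logical `major_site`, filtered to qualifying residues via attribute
#'   `sites` (also returned by `$residue[x$major_site]`).
#' @export
major_allosteric_sites <- function(classified, active_site,
                                   or_cut = 2, fdr_cut = 0.1,
                                   mode = c("all", "inhibitory",
                                            "activating")) {
  mode <- match.arg(mode)
  if (!length(active_site)) {
    warning("empty active-site set; no residues will be excluded")
  }
  cl <- tibble::as_tibble(classified)
  if (!"position" %in% names(cl)) {
    cl$position <- parse_mutation(cl$mutation)$position
  }
  cl$hit <- switch(mode,
                   all = cl$inactivating | cl$activating,
                   inhibitory = cl$inactivating,
                   activating = cl$activating)
  per_res <- cl |>
    dplyr::group_by(residue = .data$position) |>
    dplyr::summarise(a = sum(.data$hit), b = sum(!.data$hit),
                     .groups = "drop") |>
    dplyr::mutate(c = sum(cl$hit) - .data$a, d = sum(!cl$hit) - .data$b)
  fet <- purrr::pmap_dfr(per_res[, c("a", "b", "c", "d")],
                         function(a, b, c, d) {
                           fisher_enrichment(c(a, b), c(c, d))[
                             , c("odds_ratio", "p_value")]
                         })
  res <- dplyr::bind_cols(per_res, fet) |>
    dplyr::mutate(fdr = bh_fdr(.data$p_value))
  res$major_site <- if (mode == "activating") {
    res$odds_ratio > 1 & res$p_value < 0.05
  } else {
    res$odds_ratio > or_cut & res$fdr < fdr_cut
  }
  res$major_site <- res$major_site & res$a > 0 &
    !res$residue %in% active_site
  res
}

#' Per-site summary of activity energies
#'
#' Inverse-variance weighted mean of ddGa per residue (weights `1/sd^2`;
#' plain mean when SDs are missing or zero), plus the mean of |ddGa|.
#'
#' @param estimates Tibble with `mutation`, `ddGa_mean` and optionally
#'   `ddGa_sd`.
#' @return Tibble `residue`, `n_mut`, `mean_ddGa`, `weighted_mean_ddGa`,
#'   `mean_abs_ddGa`.
#' @export
site_energy_summary <- function(estimates) {
  e <- tibble::as_tibble(estimates)
  if (!"position" %in% names(e)) {
    e$position <- parse_mutation(e$mutation)$position
  }
  if (!"ddGa_sd" %in% names(e)) e$ddGa_sd <- NA_real_
  e |>
    dplyr::group_by(residue = .data$position) |>
    dplyr::summarise(
      n_mut = dplyr::n(),
      mean_ddGa = mean(.data$ddGa_mean),
      weighted_mean_ddGa = {
        w <- 1 / .data$ddGa_sd^2
        if (all(is.finite(w)) && sum(w) > 0) {
          sum(w * .data$ddGa_mean) / sum(w)
        } else mean(.data$ddGa_mean)
      },
      mean_abs_ddGa = mean(abs(.data$ddGa_mean)), .groups = "drop")
}
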