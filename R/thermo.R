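#' Thermodynamic constants
#'
#' Gas constant and absolute temperature used to convert free energies
#' (kcal/mol) into dimensionless Boltzmann exponents. The default temperature
#' corresponds to growth assays run at 30 degrees C (303.15 K), giving
#' RT of about 0.6025 kcal/mol.
#'
#' @param R Gas constant in kcal/(mol K).
#' @param temperature Absolute temperature in Kelvin.
#' @return A list of class `thermo_const` with elements `R`, `temperature`
#'   and the precomputed product `rt`.
#' @examples
#' thermo_const()$rt
#' @export
thermo_const <- function(R = 0.001987, temperature = 303.15) {
  stopifnot(is.numeric(R), is.numeric(temperature), R * temperature > 0)
  structure(list(R = R, temperature = temperature, rt = R * temperature),
            class = "thermo_const")
}

# stable log(sum(exp(cols))) across the columns of a matrix
logsumexp_rows <- function(m) {
  mx <- do.call(pmax, c(as.data.frame(m), list(na.rm = FALSE)))
  mx + log(rowSums(exp(m - mx)))
}

#' Two-state fraction folded
#'
#' Boltzmann probability that a protein with folding free energy `dGf`
#' occupies the folded state of a two-state (unfolded/folded) equilibrium:
#' `1 / (1 + exp(dGf / RT))`. Strictly decreasing in `dGf`.
#'
#' @param dGf Folding free energy in kcal/mol (vectorised).
#' @param const A [thermo_const()] object.
#' @return Probability in (0, 1).
#' @examples
#' fraction_folded(0) # 0.5
#' @export
fraction_folded <- function(dGf, const = thermo_const()) {
  stopifnot(all(is.finite(dGf)))
  stats::plogis(-dGf / const$rt)
}

#' Three-state fraction folded and active
#'
#' Probability of the folded-and-active state in a three-state equilibrium
#' with states unfolded-inactive (reference), folded-inactive (energy `dGf`)
#' and folded-active (energy `dGf + dGa`):
#' `w_fa / (1 + w_fi + w_fa)` with `w_fi = exp(-dGf/RT)` and
#' `w_fa = exp(-(dGf + dGa)/RT)`, computed in log space so it is stable for
#' `|dG|/RT` well beyond 100.
#'
#' @inheritParams fraction_folded
#' @param dGa Activity (folded-inactive to folded-active) free energy,
#'   kcal/mol.
#' @return Probability in (0, 1).
#' @examples
#' fraction_folded_active(0, 0) # 1/3
#' @export
fraction_folded_active <- function(dGf, dGa, const = thermo_const()) {
  stopifnot(all(is.finite(dGf)), all(is.finite(dGa)))
  n <- max(length(dGf), length(dGa))
  u <- rep_len(dGf / const$rt, n)
  v <- rep_len(dGa / const$rt, n)
  # 1 / (1 + e^v + e^(u+v)); log-denominator via logsumexp
  logz <- logsumexp_rows(cbind(0, v, u + v))
  exp(-logz)
}

#' Four-state active fraction
#'
#' Occupancy of two distinct active conformations summed, for the four-state
#' alternative in which a mutation can act independently on two active
#' states: states are unfolded (reference), folded-inactive (`dGf`), and two
#' folded-active states (`dGf + dGa1`, `dGf + dGa2`).
#'
#' @inheritParams fraction_folded_active
#' @param dGa1,dGa2 Free energies of the two active states relative to the
#'   folded-inactive state, kcal/mol.
#' @return Probability in (0, 1).
#' @export
fraction_active_four_state <- function(dGf, dGa1, dGa2, const = thermo_const()) {
  n <- max(length(dGf), length(dGa1), length(dGa2))
  u <- rep_len(dGf / const$rt, n)
  v1 <- rep_len(dGa1 / const$rt, n)
  v2 <- rep_len(dGa2 / const$rt, n)
  lognum <- logsumexp_rows(cbind(-u - v1, -u - v2))
  logden <- logsumexp_rows(cbind(0, -u, -u - v1, -u - v2))
  exp(lognum - logden)
}

## ---- mutation / genotype string helpers -------------------------------------

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Build mutation identifiers
#'
#' A mutation is encoded as `"<wt><position><mut>"`, e.g. `"L23P"`.
#'
#' @param wt_aa,mut_aa One-letter amino acid codes.
#' @param position 1-based residue index in full-length numbering.
#' @return Character vector of mutation ids.
#' @export
mutation_id <- function(wt_aa, position, mut_aa) {
  stopifnot(all(wt_aa %in% AA_ALPHABET), all(mut_aa %in% AA_ALPHABET),
            all(wt_aa != mut_aa), all(position >= 1))
  paste0(wt_aa, position, mut_aa)
}

#' Parse mutation identifiers into components
#'
#' @param mut Character vector of ids like `"L23P"`.
#' @return Tibble with columns `mutation`, `wt_aa`, `position`, `mut_aa`.
#' @export
parse_mutation <- function(mut) {
  m <- stringr::str_match(mut, "^([A-Y])(\\d+)([A-Y])$")
  bad <- is.na(m[, 1])
  if (any(bad)) {
    stop("malformed mutation id(s): ", paste(mut[bad], collapse = ", "))
  }
  tibble::tibble(mutation = mut, wt_aa = m[, 2],
                 position = as.integer(m[, 3]), mut_aa = m[, 4])
}

# split semicolon-joined genotype strings into lists of mutation ids;
# "" (or NA) is the wild type
split_genotype <- function(genotype) {
  out <- strsplit(ifelse(is.na(genotype), "", genotype), ";", fixed = TRUE)
  lapply(out, function(x) x[nzchar(x)])
}

#' Mutational order of genotype strings
#'
#' Number of substitutions in each semicolon-joined genotype string
#' (0 = wild type, 1 = single, 2 = double).
#'
#' @param genotype Character vector of genotype strings.
#' @return Integer vector.
#' @export
genotype_order <- function(genotype) {
  lengths(split_genotype(genotype))
}

#' Construct an energy model
#'
#' Container for a fitted or ground-truth energy model: per-mutation folding
#' (`ddGf`) and activity (`ddGa`) free-energy changes, wild-type reference
#' energies, and one affine (intercept + slope) output layer per assay and
#' block.
#'
#' @param ddG Tibble with columns `mutation`, `ddGf`, `ddGa` (and `ddGa2` for
#'   the four-state model), energies in kcal/mol.
#' @param wt_dGf,wt_dGa Wild-type folding / activity free energies, kcal/mol.
#' @param affine Tibble with columns `assay`, `block`, `intercept`, `slope`.
#' @param n_states 2, 3 or 4; selects the observation model used by
#'   [predict_fitness()].
#' @param const A [thermo_const()].
#' @param wt_dGa2 Second active-state wild-type energy (four-state only).
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(ddG, wt_dGf, wt_dGa, affine,
                         n_states = 3, const = thermo_const(),
                         wt_dGa2 = wt_dGa) {
  stopifnot(n_states %in% c(2L, 3L, 4L),
            all(c("mutation", "ddGf", "ddGa") %in% names(ddG)),
            all(c("assay", "block", "intercept", "slope") %in% names(affine)),
            all(is.finite(affine$slope)))
  if (n_states == 4 && !"ddGa2" %in% names(ddG)) {
    ddG$ddGa2 <- ddG$ddGa
  }
  structure(list(ddG = tibble::as_tibble(ddG), wt_dGf = wt_dGf,
                 wt_dGa = wt_dGa, wt_dGa2 = wt_dGa2,
                 affine = tibble::as_tibble(affine),
                 n_states = as.integer(n_states), const = const),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> ", x$n_states, "-state, ", nrow(x$ddG),
      " mutations, ", nrow(x$affine), " assay-block layers\n", sep = "")
  cat("  wt_dGf = ", signif(x$wt_dGf, 4), " kcal/mol, wt_dGa = ",
      signif(x$wt_dGa, 4), " kcal/mol\n", sep = "")
  invisible(x)
}

#' Genotype free energies under an energy model
#'
#' Additive genotype-to-energy map: the energy of a variant is the wild-type
#' energy plus the sum of the per-mutation changes of its constituent
#' substitutions.
#'
#' @param genotypes Data frame with a `genotype` column of semicolon-joined
#'   mutation ids (`""` = wild type), or a character vector of such strings.
#' @param model An [energy_model()].
#' @return Tibble with `genotype`, `dGf`, `dGa` (and `dGa2` for four-state
#'   models), kcal/mol.
#' @export
genotype_energies <- function(genotypes, model) {
  gstr <- if (is.data.frame(genotypes)) genotypes$genotype else genotypes
  muts <- split_genotype(gstr)
  all_m <- unique(unlist(muts))
  unknown <- setdiff(all_m, model$ddG$mutation)
  if (length(unknown)) {
    stop("missing energy parameters for mutation(s): ",
         paste(unknown, collapse = ", "))
  }
  idx <- lapply(muts, function(m) match(m, model$ddG$mutation))
  sum_col <- function(col) {
    vapply(idx, function(i) sum(col[i]), numeric(1))
  }
  out <- tibble::tibble(
    genotype = gstr,
    dGf = model$wt_dGf + sum_col(model$ddG$ddGf),
    dGa = model$wt_dGa + sum_col(model$ddG$ddGa)
  )
  if (model$n_states == 4L) {
    out$dGa2 <- model$wt_dGa2 + sum_col(model$ddG$ddGa2)
  }
  out
}

# molecular-phenotype probability for a genotype energy table
model_phenotype <- function(energies, model, assay) {
  const <- model$const
  if (model$n_states == 2L || assay == "abundance") {
    fraction_folded(energies$dGf, const)
  } else if (model$n_states == 3L) {
    fraction_folded_active(energies$dGf, energies$dGa, const)
  } else {
    fraction_active_four_state(energies$dGf, energies$dGa, energies$dGa2, const)
  }
}

#' Predict assay fitness for genotypes
#'
#' Maps genotype energies through the state-occupancy nonlinearity of the
#' model and the affine output layer of the requested assay and block:
#' abundance fitness is an affine function of the two-state fraction folded;
#' activity fitness is an affine function of the fraction folded-and-active
#' (three-state) or of the summed occupancy of the two active states
#' (four-state). Under the two-state alternative both assays share the
#' fraction folded.
#'
#' @param genotypes Data frame with columns `genotype`, `assay`, `block`
#'   (one row per observation to predict).
#' @param model An [energy_model()].
#' @return Input tibble with a `predicted` column appended.
#' @export
predict_fitness <- function(genotypes, model) {
  genotypes <- tibble::as_tibble(genotypes)
  stopifnot(all(c("genotype", "assay", "block") %in% names(genotypes)))
  key <- paste(genotypes$assay, genotypes$block)
  akey <- paste(model$affine$assay, model$affine$block)
  miss <- setdiff(unique(key), akey)
  if (length(miss)) {
    stop("no affine parameters for assay/block: ", paste(miss, collapse = ", "))
  }
  en <- genotype_energies(genotypes$genotype, model)
  p <- numeric(nrow(genotypes))
  for (a in unique(genotypes$assay)) {
    sel <- genotypes$assay == a
    p[sel] <- model_phenotype(en[sel, , drop = FALSE], model, a)
  }
  i <- match(key, akey)
  genotypes$predicted <- model$affine$intercept[i] + model$affine$slope[i] * p
  genotypes
}
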