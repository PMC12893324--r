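## Linear-model prediction of activity energies and full-length vs
## domain-only regulatory comparison.

#' Exponential distance transform
#'
#' Maps a distance to the active site through the fitted global decay,
#' `dtr = exp(k * d)`, so that a linear model in `dtr` captures the
#' exponential distance dependence of allosteric effects.
#'
#' @param d Distance in Angstrom (>= 0).
#' @param k Decay rate in 1/Angstrom (default the global allosteric decay
#'   rate).
#' @return Transformed distance in (0, 1].
#' @export
distance_transform <- function(d, k = -0.063) {
  stopifnot(all(d >= 0))
  exp(k * d)
}

#' Linear prediction of activity energies from features
#'
#' Ordinary least squares of observed ddGa on sequence/structure features
#' (categorical features one-hot encoded), evaluated by k-fold
#' cross-validation: held-out R-squared per fold. Active-site mutations
#' should be excluded beforehand (or via the `active_site` logical column,
#' which is honoured when present). Collinear design columns are dropped
#' with a warning.
#'
#' @param rows Feature tibble including the response column `ddGa` and any
#'   predictor columns; an optional logical `active_site` column marks rows
#'   to exclude.
#' @param features Character vector of predictor column names (defaults to
#'   all columns except the response and bookkeeping columns).
#' @param folds Number of CV folds.
#' @param seed RNG seed for fold assignment.
#' @return List with `coefficients`, `fold_r2` (tibble), `r2_mean`,
#'   `r2_sd`, `fold_of` (row fold assignment).
#' @export
fit_ddga_predictor <- function(rows, features = NULL, folds = 10, seed = 1) {
  r <- tibble::as_tibble(rows)
  stopifnot("ddGa" %in% names(r))
  if ("active_site" %in% names(r)) {
    r <- r[!r$active_site, ]
  }
  drop_cols <- c("ddGa", "mutation", "active_site", "position")
  if (is.null(features)) features <- setdiff(names(r), drop_cols)
  stopifnot(all(features %in% names(r)))
  dat <- r[, features, drop = FALSE]
  dat[] <- lapply(dat, function(x) if (is.character(x)) factor(x) else x)
  X <- stats::model.matrix(~ ., data = dat)
  y <- r$ddGa
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), nrow(X)))
  dropped_any <- FALSE
  fit_predict <- function(train, test) {
    fit <- stats::lm.fit(X[train, , drop = FALSE], y[train])
    beta <- fit$coefficients
    if (anyNA(beta)) {
      dropped_any <<- TRUE
      beta[is.na(beta)] <- 0
    }
    as.numeric(X[test, , drop = FALSE] %*% beta)
  }
  fold_r2 <- purrr::map_dfr(seq_len(folds), function(f) {
    te <- which(fold_of == f); tr <- which(fold_of != f)
    pred <- fit_predict(tr, te)
    tibble::tibble(fold = f,
                   r2 = 1 - sum((y[te] - pred)^2) /
                     sum((y[te] - mean(y[te]))^2))
  })
  if (dropped_any) {
    warning("rank-deficient design: collinear columns dropped from fit")
  }
  full <- stats::lm.fit(X, y)
  list(coefficients = full$coefficients, fold_r2 = fold_r2,
       r2_mean = mean(fold_r2$r2), r2_sd = stats::sd(fold_r2$r2),
       fold_of = fold_of)
}

#' Compare energies between full-length and domain-only constructs
#'
#' Regresses full-length ddGa on domain-only ddGa (ordinary least squares)
#' and uses the residuals as the estimator of the regulatory shift dddGa
#' (full-length minus domain). Z-scores incorporate the errors of both
#' estimates, `z = residual / sqrt(sdFL^2 + sdKD^2)`; one-sided p-values
#' are computed per direction and BH-adjusted within direction. Mutations
#' with `residual < -threshold` (FDR < cut) are flagged as more activating
#' in the full-length protein, and symmetrically for more inhibitory.
#'
#' @param est_fl,est_kd Tibbles with columns `mutation`, `ddGa_mean`,
#'   `ddGa_sd` for the two constructs.
#' @param dddG_threshold Effect-size cut (kcal/mol) on the residual.
#' @param fdr_cut FDR cut for flagging.
#' @return Tibble per shared mutation: `dddGa` (residual), `z`, per
#'   direction p/FDR, logical flags; regression slope and intercept as
#'   attributes.
#' @export
compare_constructs <- function(est_fl, est_kd, dddG_threshold = 1,
                               fdr_cut = 0.1) {
  j <- dplyr::inner_join(
    dplyr::select(tibble::as_tibble(est_fl), "mutation",
                  fl_mean = "ddGa_mean", fl_sd = "ddGa_sd"),
    dplyr::select(tibble::as_tibble(est_kd), "mutation",
                  kd_mean = "ddGa_mean", kd_sd = "ddGa_sd"),
    by = "mutation")
  if (nrow(j) < 10) {
    stop("fewer than 10 shared mutations between constructs")
  }
  fit <- stats::lm(fl_mean ~ kd_mean, data = j)
  j$dddGa <- stats::residuals(fit)
  j$z <- j$dddGa / sqrt(j$fl_sd^2 + j$kd_sd^2)
  j$p_activating <- stats::pnorm(j$z)
  j$p_inhibitory <- stats::pnorm(j$z, lower.tail = FALSE)
  j$fdr_activating <- bh_fdr(j$p_activating)
  j$fdr_inhibitory <- bh_fdr(j$p_inhibitory)
  j$more_activating_fl <- j$dddGa < -dddG_threshold &
    j$fdr_activating < fdr_cut
  j$more_inhibitory_fl <- j$dddGa > dddG_threshold &
    j$fdr_inhibitory < fdr_cut
  attr(j, "intercept") <- unname(stats::coef(fit)[1])
  attr(j, "slope") <- unname(stats::coef(fit)[2])
  j
}

#' Spatially cluster flagged regulatory sites
#'
#' Hierarchical clustering (average linkage) of the pairwise Calpha-Calpha
#' distances between qualifying sites, cut at `cut_height`.
#'
#' @param sites Integer vector of residue numbers.
#' @param s A `structure_model`.
#' @param cut_height Dendrogram cut distance in Angstrom.
#' @return Tibble `residue`, `cluster`.
#' @export
cluster_regulatory_sites <- function(sites, s, cut_height = 10) {
  ca <- ca_coords(s)
  all_res <- as.integer(rownames(ca))
  missing <- setdiff(sites, all_res)
  if (length(missing)) {
    stop("sites missing Calpha coordinates: ",
         paste(missing, collapse = ", "))
  }
  if (length(sites) == 1) {
    return(tibble::tibble(residue = as.integer(sites), cluster = 1L))
  }
  dm <- stats::dist(ca[match(sites, all_res), , drop = FALSE])
  cl <- stats::cutree(stats::hclust(dm, method = "average"),
                      h = cut_height)
  tibble::tibble(residue = as.integer(sites), cluster = as.integer(cl))
}
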