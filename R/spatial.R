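## Distance-decay analysis: exponential fits, directional decay,
## effect-size matched subsampling, spatial clustering tests.

loglinear_start <- function(d, y, eps = 1e-6) {
  fit <- stats::lm.fit(cbind(1, d), log(y + eps))
  c(a = exp(fit$coefficients[[1]]), b = fit$coefficients[[2]])
}

new_decay_fit <- function(amplitude, rate, se_rate, n_points, data,
                          method) {
  ci <- if (is.finite(se_rate)) 1.96 * se_rate else NA_real_
  structure(list(amplitude = amplitude, rate = rate, se_rate = se_rate,
                 ci95_rate = c(rate - ci, rate + ci),
                 d_half = half_decay_or_inf(rate),
                 n_points = n_points, data = data, method = method),
            class = "decay_fit")
}

half_decay_or_inf <- function(k) if (k == 0) Inf else log(2) / abs(k)

#' Half-decay distance of an exponential decay
#'
#' The distance over which a fitted exponential trend `a * exp(k * d)`
#' halves: `ln(2) / |k|`.
#'
#' @param k Decay rate in 1/Angstrom (non-zero).
#' @return Distance in Angstrom.
#' @examples
#' half_decay(-0.038) # 18.24
#' @export
half_decay <- function(k) {
  if (any(k == 0)) stop("half-decay distance undefined for k = 0")
  log(2) / abs(k)
}

#' Fit an exponential distance decay
#'
#' Nonlinear least squares for `y = a * exp(b * d)`, initialised from a
#' log-linear regression of `log(y + eps)` on `d` and refined by
#' Gauss-Newton (`nls`), falling back to Levenberg-Marquardt. Reports the
#' amplitude at distance zero, the signed rate `k = b`, its asymptotic 95%
#' confidence interval, and the half-decay distance `ln(2)/|k|`.
#'
#' @param d Distances (Angstrom), one per site.
#' @param y Non-negative per-site responses (e.g. mean |ddGa|, kcal/mol).
#' @param eps Offset used in the log-linear initialisation.
#' @return A `decay_fit`.
#' @export
fit_exponential_decay <- function(d, y, eps = 1e-6) {
  keep <- is.finite(d) & is.finite(y)
  d <- d[keep]; y <- y[keep]
  if (length(d) < 3) stop("need at least 3 points to fit a decay")
  if (any(y < 0)) stop("responses must be non-negative")
  dat <- tibble::tibble(d = d, y = y)
  if (stats::sd(y) < 1e-12) {
    # flat response: amplitude is the constant level, rate 0
    return(new_decay_fit(mean(y), 0, NA_real_, length(d), dat, "flat"))
  }
  st <- loglinear_start(d, y, eps)
  fit <- tryCatch(
    stats::nls(y ~ a * exp(b * d), data = dat,
               start = list(a = st[["a"]], b = st[["b"]]),
               control = stats::nls.control(maxiter = 200,
                                            warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(b * d), data = dat,
                        start = list(a = st[["a"]], b = st[["b"]]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  }
  if (is.null(fit)) {
    stop("exponential fit did not converge (log-linear estimate: a = ",
         signif(st[["a"]], 4), ", k = ", signif(st[["b"]], 4), ")")
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["b", "Std. Error"],
                 error = function(e) NA_real_)
  new_decay_fit(cf[["a"]], cf[["b"]], se, length(d), dat, "nls")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> a = ", signif(x$amplitude, 4), " kcal/mol, k = ",
      signif(x$rate, 4), " 1/A (95% CI ",
      signif(x$ci95_rate[1], 3), "..", signif(x$ci95_rate[2], 3),
      "), d_half = ", signif(x$d_half, 4), " A, n = ", x$n_points,
      "\n", sep = "")
  invisible(x)
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble::tibble(term = c("amplitude", "rate"),
                 estimate = c(x$amplitude, x$rate),
                 std.error = c(NA_real_, x$se_rate),
                 conf.low = c(NA_real_, x$ci95_rate[1]),
                 conf.high = c(NA_real_, x$ci95_rate[2]))
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble::tibble(amplitude = x$amplitude, rate = x$rate,
                 d_half = x$d_half, n_points = x$n_points,
                 method = x$method)
}

#' Directional (anisotropic) distance decay
#'
#' Quantifies decay of per-site effects along one spatial axis of the
#' structure's native frame. Residues are selected whose Calpha
#' displacement from the active-site reference centroid is at most `slab`
#' in absolute value along the two non-queried axes and whose signed
#' displacement along the queried axis matches `sign`. The decay is fitted
#' against the absolute axial displacement (`distance = "axial"`, default)
#' or against the residue's minimum heavy-atom distance to the active site
#' (`distance = "radial"`; with `slab = Inf` and `sign = "both"` this
#' reproduces the global fit).
#'
#' @param s A `structure_model`.
#' @param site_values Tibble with columns `residue`, `value` (per-site mean
#'   |ddGa|).
#' @param axis `"x"`, `"y"` or `"z"` (structure frame).
#' @param sign `"+"`, `"-"` or `"both"`.
#' @param slab Slab half-width (Angstrom) on the two remaining axes.
#' @param ligands,residues Reference selections, as in
#'   [min_distance_to_active_site()].
#' @param distance Distance variable for the fit (see above).
#' @return A `decay_fit` with a `selection` attribute of the residues used.
#' @export
directional_decay <- function(s, site_values, axis = c("x", "y", "z"),
                              sign = c("+", "-", "both"), slab = 10,
                              ligands = character(), residues = integer(),
                              distance = c("axial", "radial")) {
  axis <- match.arg(axis)
  sign <- match.arg(sign)
  distance <- match.arg(distance)
  origin <- active_site_centroid(s, ligands, residues)
  ca <- ca_coords(s)
  disp <- sweep(ca, 2, origin)
  colnames(disp) <- c("x", "y", "z")
  others <- setdiff(c("x", "y", "z"), axis)
  ok <- abs(disp[, others[1]]) <= slab & abs(disp[, others[2]]) <= slab
  ax <- disp[, axis]
  if (sign == "+") ok <- ok & ax >= 0
  if (sign == "-") ok <- ok & ax <= 0
  res_sel <- as.integer(rownames(ca))[ok]
  sv <- site_values[site_values$residue %in% res_sel, ]
  if (nrow(sv) < 3) {
    stop("fewer than 3 residues selected for axis ", axis, sign)
  }
  dvar <- if (distance == "axial") {
    abs(ax[match(sv$residue, as.integer(rownames(ca)))])
  } else {
    dd <- min_distance_to_active_site(s, ligands, residues)
    dd$distance[match(sv$residue, dd$residue)]
  }
  out <- fit_exponential_decay(dvar, sv$value)
  attr(out, "selection") <- sv$residue
  out
}

# fast decay-rate statistic used inside the subsampling loop: log-linear
# slope of log(per-site mean magnitude + eps) on distance
loglinear_rate <- function(d, mag, eps = 1e-6) {
  ds <- rowsum(cbind(mag, 1), d)
  x <- as.numeric(rownames(ds))
  if (length(x) < 3) return(NA_real_)
  yl <- log(ds[, 1] / ds[, 2] + eps)
  stats::cov(x, yl) / stats::var(x)
}

#' Effect-size matched subsampling decay comparison
#'
#' Tests whether inhibitory mutations decay with distance more steeply than
#' activating mutations independently of their effect sizes. The
#' inactivating set is repeatedly subsampled (with replacement) to match
#' the size and the magnitude distribution of the activating set (binned
#' magnitude matching on deciles of |ddGa| of the activating set); a decay
#' rate is estimated for each subsample, and the p-value is the fraction of
#' subsamples whose decay is no steeper than the activating set's
#' (subsample rate at or above the activating rate): small p means the
#' matched inactivating mutations decay significantly more steeply.
#'
#' @param inactivating Tibble with columns `d` (Angstrom) and `ddGa`
#'   (> 0, kcal/mol).
#' @param activating Tibble with columns `d` and `ddGa` (< 0).
#' @param n_subsamples Number of subsamples.
#' @param n_bins Magnitude-matching bins.
#' @param seed RNG seed.
#' @return List with `p`, `median_k` (median subsample rate), `k_activating`
#'   and the vector of subsample rates.
#' @export
matched_subsample_decay_test <- function(inactivating, activating,
                                         n_subsamples = 10000, n_bins = 10,
                                         seed = 1) {
  stopifnot(nrow(inactivating) > 0, nrow(activating) > 0)
  set.seed(seed)
  mag_in <- abs(inactivating$ddGa)
  mag_ac <- abs(activating$ddGa)
  breaks <- unique(stats::quantile(mag_ac, seq(0, 1, length.out = n_bins + 1)))
  breaks[1] <- -Inf; breaks[length(breaks)] <- Inf
  bin_ac <- cut(mag_ac, breaks)
  bin_in <- cut(mag_in, breaks)
  need <- table(bin_ac)
  idx_by_bin <- split(seq_along(mag_in), bin_in)
  empty <- names(need)[need > 0 &
                         vapply(names(need), function(b)
                           length(idx_by_bin[[b]]) == 0, logical(1))]
  if (length(empty)) {
    stop("inactivating set cannot fill magnitude bins: ",
         paste(empty, collapse = ", "))
  }
  k_act <- loglinear_rate(activating$d, mag_ac)
  n_tot <- sum(need)
  ks <- numeric(n_subsamples)
  for (i in seq_len(n_subsamples)) {
    take <- unlist(lapply(names(need)[need > 0], function(b) {
      idx_by_bin[[b]][sample.int(length(idx_by_bin[[b]]), need[[b]],
                                 replace = TRUE)]
    }), use.names = FALSE)
    ks[i] <- loglinear_rate(inactivating$d[take], mag_in[take])
  }
  list(p = mean(ks >= k_act, na.rm = TRUE),
       median_k = stats::median(ks, na.rm = TRUE),
       k_activating = k_act, subsample_k = ks)
}

#' Spatial clustering / connectivity test for a residue set
#'
#' Compares the observed median Calpha-Calpha statistic of a residue set
#' (`pairwise`: all pairwise distances; `connectivity`: each site's minimum
#' distance to any other site) with a null distribution from random residue
#' subsets of equal size. The p-value is the fraction of random subsets
#' whose median statistic is less than or equal to the observed median.
#'
#' @param sites Integer vector of residue numbers (>= 2).
#' @param s A `structure_model`.
#' @param n_random Number of random subsets.
#' @param mode `"pairwise"` or `"connectivity"`.
#' @param seed RNG seed.
#' @return List with `p`, `observed` and the null vector `null_stats`.
#' @export
site_clustering_test <- function(sites, s, n_random = 1000,
                                 mode = c("pairwise", "connectivity"),
                                 seed = 1) {
  mode <- match.arg(mode)
  stopifnot(length(sites) >= 2)
  ca <- ca_coords(s)
  all_res <- as.integer(rownames(ca))
  if (!all(sites %in% all_res)) {
    stop("sites absent from structure: ",
         paste(setdiff(sites, all_res), collapse = ", "))
  }
  dm <- as.matrix(stats::dist(ca))
  stat <- function(idx) {
    sub <- dm[idx, idx, drop = FALSE]
    if (mode == "pairwise") {
      stats::median(sub[upper.tri(sub)])
    } else {
      diag(sub) <- Inf
      stats::median(apply(sub, 1, min))
    }
  }
  obs <- stat(match(sites, all_res))
  set.seed(seed)
  k <- length(sites)
  null_stats <- vapply(seq_len(n_random), function(i) {
    stat(sample.int(length(all_res), k))
  }, numeric(1))
  list(p = mean(null_stats <= obs), observed = obs,
       null_stats = null_stats)
}

#' Distance-corrected mutation effects
#'
#' Removes the global distance trend with a local-regression (loess)
#' smooth of `y` on `d` and returns per-point residuals, for grouping by
#' structural class (e.g. secondary-structure type).
#'
#' @param d Distances (Angstrom).
#' @param y Per-point responses.
#' @param span Loess span in (0, 1].
#' @return Tibble `d`, `y`, `fitted`, `residual`.
#' @export
distance_corrected_effects <- function(d, y, span = 0.75) {
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  stopifnot(length(d) == length(y))
  if (length(d) < 10) stop("need at least 10 points")
  fit <- stats::loess(y ~ d, span = span, degree = 2,
                      family = "gaussian")
  tibble::tibble(d = d, y = y, fitted = stats::fitted(fit),
                 residual = stats::residuals(fit))
}
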