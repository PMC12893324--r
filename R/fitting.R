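## Energy-model fitting: weighted least squares over the 2/3/4-state
## Boltzmann observation model, with analytic gradients, cross-validation,
## explainable-variance accounting and ensemble uncertainty.

# Pack observations into index structures used by the objective.
build_fit_data <- function(observations, const, exclude_backgrounds = NULL) {
  obs <- tibble::as_tibble(observations)
  stopifnot(all(c("genotype", "assay", "block", "fitness", "sigma")
                %in% names(obs)))
  if (!is.null(exclude_backgrounds)) {
    if (!"background_id" %in% names(obs)) {
      stop("cannot exclude backgrounds: no background_id column")
    }
    obs <- obs[!obs$background_id %in% exclude_backgrounds, ]
  }
  if (any(!is.finite(obs$fitness))) stop("non-finite fitness values")
  if (any(obs$sigma <= 0)) stop("non-positive sigma in observations")
  if (length(unique(obs$assay)) < 2) {
    stop("under-identified: observations must span both assays")
  }
  genos <- sort(unique(obs$genotype))
  muts_list <- split_genotype(genos)
  muts <- sort(unique(unlist(muts_list)))
  gi <- match(obs$genotype, genos)
  ji <- lapply(muts_list, match, table = muts)
  ii <- rep(seq_along(genos), lengths(ji))
  X <- Matrix::sparseMatrix(i = ii, j = unlist(ji), x = 1,
                            dims = c(length(genos), length(muts)))
  akey <- sort(unique(paste(obs$assay, obs$block)))
  ki <- match(paste(obs$assay, obs$block), akey)
  # warn when a mutation is observed in fewer than 2 genetic backgrounds
  if ("background_id" %in% names(obs)) {
    nb <- tapply(obs$background_id[match(genos, obs$genotype)][ii],
                 unlist(ji), function(b) length(unique(b)))
    if (any(nb < 2)) {
      warning(sum(nb < 2), " mutation(s) observed in fewer than 2 ",
              "genetic backgrounds; energies may be poorly constrained")
    }
  }
  list(obs = obs, genos = genos, muts = muts, X = X,
       gi = gi, ki = ki, akey = akey,
       is_activity = obs$assay == "activity",
       y = obs$fitness, w = 1 / obs$sigma^2, const = const)
}

# parameter vector layout helpers
par_layout <- function(M, K, n_states) {
  n_energy_sets <- switch(as.character(n_states), "2" = 1L, "3" = 2L,
                          "4" = 3L)
  list(M = M, K = K, n_sets = n_energy_sets,
       n_par = n_energy_sets * (M + 1L) + 2L * K)
}

unpack_par <- function(theta, lay) {
  M <- lay$M; K <- lay$K; s <- lay$n_sets
  eg <- matrix(theta[seq_len(s * M)], M, s)
  wt <- theta[s * M + seq_len(s)]
  a <- theta[s * (M + 1) + seq_len(K)]
  b <- theta[s * (M + 1) + K + seq_len(K)]
  list(eg = eg, wt = wt, a = a, b = b)
}

clamp <- function(x, lim = 500) pmin(pmax(x, -lim), lim)

# loss and gradient closures for a given dataset and state count;
# `anchor` (optional) adds a weak Gaussian tether N(anchor, tau^2) on the
# per-mutation energy parameters so that directions the data leaves flat
# (fully saturated variants) stay at their direct-inversion estimates
# instead of drifting without bound
make_objective <- function(fd, n_states, anchor = NULL, tau = 10) {
  rt <- fd$const$rt
  lay <- par_layout(length(fd$muts), length(fd$akey), n_states)
  n_anchor <- lay$n_sets * lay$M
  pen_w <- 1 / tau^2
  X <- fd$X; gi <- fd$gi; ki <- fd$ki
  act <- fd$is_activity; y <- fd$y; w <- fd$w
  nG <- length(fd$genos)

  eval_all <- function(theta) {
    p <- unpack_par(theta, lay)
    u <- clamp((p$wt[1] + as.numeric(X %*% p$eg[, 1])) / rt)
    pf <- stats::plogis(-u)
    dpf_du <- -pf * (1 - pf)
    if (n_states == 2L) {
      pg <- pf; dpg_du <- dpf_du
      dpg_dv1 <- dpg_dv2 <- rep(0, nG)
      v1 <- v2 <- NULL
    } else if (n_states == 3L) {
      v1 <- clamp((p$wt[2] + as.numeric(X %*% p$eg[, 2])) / rt)
      logz <- logsumexp_rows(cbind(0, v1, u + v1))
      pg <- exp(-logz)
      dpg_du <- -exp(u + v1 - 2 * logz)
      dpg_dv1 <- -(exp(v1 - 2 * logz) + exp(u + v1 - 2 * logz))
      dpg_dv2 <- rep(0, nG)
    } else {
      v1 <- clamp((p$wt[2] + as.numeric(X %*% p$eg[, 2])) / rt)
      v2 <- clamp((p$wt[3] + as.numeric(X %*% p$eg[, 3])) / rt)
      logA <- logsumexp_rows(cbind(-u - v1, -u - v2))
      logZ <- logsumexp_rows(cbind(0, -u, logA))
      log1pe <- logsumexp_rows(cbind(0, -u)) # log(1 + e^-u)
      pg <- exp(logA - logZ)
      dpg_du <- -exp(logA - 2 * logZ)
      dpg_dv1 <- -exp(-u - v1 + log1pe - 2 * logZ)
      dpg_dv2 <- -exp(-u - v2 + log1pe - 2 * logZ)
    }
    # per-observation phenotype: abundance always two-state fraction folded
    p_obs <- ifelse(act, pg[gi], pf[gi])
    yhat <- p$a[ki] + p$b[ki] * p_obs
    r <- y - yhat
    list(p = p, r = r, p_obs = p_obs, pf = pf,
         dpf_du = dpf_du, dpg_du = dpg_du,
         dpg_dv1 = dpg_dv1, dpg_dv2 = dpg_dv2)
  }

  fn <- function(theta) {
    e <- eval_all(theta)
    pen <- if (is.null(anchor)) 0 else {
      sum(pen_w * (theta[seq_len(n_anchor)] - anchor)^2)
    }
    sum(w * e$r^2) + pen
  }
  # weighted residual vector and sparse Jacobian dr/dtheta for
  # Gauss-Newton refinement
  sw <- sqrt(w)
  resid_jac <- function(theta) {
    e <- eval_all(theta)
    b_obs <- e$p$b[ki]
    dpdu <- ifelse(act, e$dpg_du[gi], e$dpf_du[gi])
    X_obs <- X[gi, , drop = FALSE]
    n <- length(y)
    scale_f <- -(b_obs * dpdu) / rt
    Jf <- Matrix::Diagonal(x = scale_f) %*% X_obs
    Jwt <- cbind(scale_f)
    Jlist <- list(Jf)
    if (lay$n_sets >= 2) {
      dpdv1 <- ifelse(act, e$dpg_dv1[gi], 0)
      scale_a <- -(b_obs * dpdv1) / rt
      Jlist <- c(Jlist, list(Matrix::Diagonal(x = scale_a) %*% X_obs))
      Jwt <- cbind(Jwt, scale_a)
    }
    if (lay$n_sets == 3) {
      dpdv2 <- ifelse(act, e$dpg_dv2[gi], 0)
      scale_a2 <- -(b_obs * dpdv2) / rt
      Jlist <- c(Jlist, list(Matrix::Diagonal(x = scale_a2) %*% X_obs))
      Jwt <- cbind(Jwt, scale_a2)
    }
    Ja <- Matrix::sparseMatrix(i = seq_len(n), j = ki, x = -1,
                               dims = c(n, lay$K))
    Jb <- Matrix::sparseMatrix(i = seq_len(n), j = ki, x = -e$p_obs,
                               dims = c(n, lay$K))
    J <- do.call(cbind, c(Jlist, list(Jwt, Ja, Jb)))
    r_all <- sw * e$r
    J_all <- Matrix::Diagonal(x = sw) %*% J
    if (!is.null(anchor)) {
      J_pen <- Matrix::sparseMatrix(i = seq_len(n_anchor),
                                    j = seq_len(n_anchor),
                                    x = sqrt(pen_w),
                                    dims = c(n_anchor, lay$n_par))
      r_all <- c(r_all,
                 sqrt(pen_w) * (theta[seq_len(n_anchor)] - anchor))
      J_all <- rbind(J_all, J_pen)
    }
    list(r = r_all, J = J_all)
  }
  gr <- function(theta) {
    e <- eval_all(theta)
    gwr <- -2 * w * e$r
    ga <- rowsum(gwr, ki, reorder = TRUE)[, 1]
    gb <- rowsum(gwr * e$p_obs, ki, reorder = TRUE)[, 1]
    # chain through the state-occupancy nonlinearity, per genotype
    gp <- gwr * e$p$b[ki]
    acc <- function(vec) {
      out <- numeric(nG)
      rs <- rowsum(vec, gi)
      out[as.integer(rownames(rs))] <- rs[, 1]
      out
    }
    du <- acc(gp * ifelse(act, e$dpg_du[gi], e$dpf_du[gi])) / rt
    g_f <- as.numeric(Matrix::crossprod(X, du))
    grad_energy <- c(g_f)
    grad_wt <- sum(du)
    if (lay$n_sets >= 2) {
      dv1 <- acc(gp * ifelse(act, e$dpg_dv1[gi], 0)) / rt
      grad_energy <- c(grad_energy, as.numeric(Matrix::crossprod(X, dv1)))
      grad_wt <- c(grad_wt, sum(dv1))
    }
    if (lay$n_sets == 3) {
      dv2 <- acc(gp * ifelse(act, e$dpg_dv2[gi], 0)) / rt
      grad_energy <- c(grad_energy, as.numeric(Matrix::crossprod(X, dv2)))
      grad_wt <- c(grad_wt, sum(dv2))
    }
    g_all <- c(grad_energy, grad_wt, ga, gb)
    if (!is.null(anchor)) {
      g_all[seq_len(n_anchor)] <- g_all[seq_len(n_anchor)] +
        2 * pen_w * (theta[seq_len(n_anchor)] - anchor)
    }
    g_all
  }
  list(fn = fn, gr = gr, resid_jac = resid_jac, lay = lay)
}

# damped Gauss-Newton (Levenberg-Marquardt) on the weighted residuals;
# returns the accepted-step loss trace (monotone by construction)
lm_refine <- function(ob, theta, maxit = 200, rel_tol = 1e-12) {
  rj <- ob$resid_jac(theta)
  loss <- sum(rj$r^2)
  trace <- loss
  lambda <- 1e-4
  for (it in seq_len(maxit)) {
    M <- Matrix::crossprod(rj$J)
    g <- Matrix::crossprod(rj$J, rj$r)
    dM <- Matrix::diag(M)
    # floor the damping relative to the largest curvature so that flat
    # (unidentified) directions cannot drift to huge values
    D <- Matrix::Diagonal(x = pmax(dM, 1e-6 * max(dM, 1e-10)))
    accepted <- FALSE
    for (sub in 1:30) {
      delta <- tryCatch(
        as.numeric(Matrix::solve(M + lambda * D, -g)),
        error = function(e) NULL)
      if (!is.null(delta) && all(is.finite(delta))) {
        cand <- theta + delta
        rj_new <- ob$resid_jac(cand)
        loss_new <- sum(rj_new$r^2)
        if (is.finite(loss_new) && loss_new < loss) {
          theta <- cand; rj <- rj_new
          rel <- (loss - loss_new) / max(loss, 1e-300)
          loss <- loss_new
          trace <- c(trace, loss)
          lambda <- max(lambda / 10, 1e-12)
          accepted <- TRUE
          if (rel < rel_tol) {
            return(list(par = theta, value = loss, trace = trace,
                        convergence = 0L, iters = it))
          }
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!accepted) {
      return(list(par = theta, value = loss, trace = trace,
                  convergence = 0L, iters = it))
    }
  }
  list(par = theta, value = loss, trace = trace, convergence = 1L,
       iters = maxit)
}

init_par <- function(fd, lay, act_scale = NULL) {
  # affine layers from the empirical fitness span; energies by inverting
  # the Boltzmann nonlinearities on wild-type and single-mutant genotypes
  rt <- fd$const$rt
  # pool the span per assay: a single block may legitimately cover only
  # part of the phenotype range, and a per-block span would then both
  # collapse its slope init and over-amplify the inverted energies
  a0 <- b0 <- numeric(lay$K)
  assay_of_k <- sub(" .*$", "", fd$akey)
  for (k in seq_len(lay$K)) {
    ya <- fd$y[assay_of_k[fd$ki] == assay_of_k[k]]
    a0[k] <- stats::quantile(ya, 0.05, names = FALSE)
    b0[k] <- max(stats::quantile(ya, 0.95, names = FALSE) - a0[k], 0.1)
  }
  nG <- length(fd$genos)
  p_hat <- pmin(pmax((fd$y - a0[fd$ki]) / b0[fd$ki], 1e-3), 1 - 1e-3)
  mean_by_geno <- function(vals, sel) {
    out <- rep(NA_real_, nG)
    if (!any(sel)) return(out)
    rs <- rowsum(cbind(vals[sel], 1), fd$gi[sel])
    out[as.integer(rownames(rs))] <- rs[, 1] / rs[, 2]
    out
  }
  # u = dGf/rt from abundance: p_f = 1/(1+e^u)
  fill_na <- function(x) {
    m <- stats::median(x, na.rm = TRUE)
    x[is.na(x)] <- if (is.finite(m)) m else 0
    x
  }
  u_g <- fill_na(mean_by_geno(log((1 - p_hat) / p_hat), !fd$is_activity))
  rs1 <- Matrix::rowSums(fd$X)
  # v = dGa/rt from activity given u: p_fa = 1/(1 + e^v (1 + e^u)).
  # The activity phenotype may span only part of (0,1) (e.g. up to 0.5
  # when the wild type is half-active and nothing activates further), so
  # the inversion slope is scaled by act_scale; when unset, the scale is
  # chosen to make the inverted activity energies most nearly additive
  # over the double mutants
  v_field <- function(s) {
    p_act <- pmin(pmax((fd$y - a0[fd$ki]) / (s * b0[fd$ki]), 1e-3),
                  1 - 1e-3)
    v_obs <- log((1 - p_act) / p_act) -
      log1p(exp(pmin(u_g[fd$gi], 30)))
    fill_na(mean_by_geno(v_obs, fd$is_activity))
  }
  if (is.null(act_scale)) {
    act_scale <- 1
    trip <- Matrix::summary(fd$X)
    single_of_mut <- rep(NA_integer_, lay$M)
    singles_i <- which(rs1 == 1)
    single_of_mut[trip$j[trip$i %in% singles_i]] <-
      trip$i[trip$i %in% singles_i]
    dbl <- which(rs1 == 2)
    wt_i <- which(rs1 == 0)[1]
    if (length(dbl) >= 10 && !is.na(wt_i) && any(fd$is_activity)) {
      if (length(dbl) > 2000) dbl <- dbl[seq(1, length(dbl),
                                             length.out = 2000)]
      pair <- split(trip$j[trip$i %in% dbl], trip$i[trip$i %in% dbl])
      d_i <- as.integer(names(pair))
      m1 <- single_of_mut[vapply(pair, function(p) as.integer(p[1]),
                                 integer(1))]
      m2 <- single_of_mut[vapply(pair, function(p) as.integer(p[2]),
                                 integer(1))]
      ok <- !is.na(m1) & !is.na(m2)
      if (sum(ok) >= 10) {
        scores <- vapply(c(0.75, 1, 1.5, 2, 3, 4), function(s) {
          v <- v_field(s)
          stats::median(abs(v[d_i[ok]] -
                              (v[m1[ok]] + v[m2[ok]] - v[wt_i])))
        }, numeric(1))
        act_scale <- c(0.75, 1, 1.5, 2, 3, 4)[which.min(scores)]
      }
    }
  }
  v_g <- v_field(act_scale)
  for (k in seq_len(lay$K)) {
    if (assay_of_k[k] == "activity") b0[k] <- b0[k] * act_scale
  }
  wt_idx <- which(rs1 == 0)
  wt_u <- if (length(wt_idx)) mean(u_g[wt_idx]) else stats::median(u_g)
  wt_v <- if (length(wt_idx)) mean(v_g[wt_idx]) else stats::median(v_g)
  eg_f <- eg_a <- numeric(lay$M)
  singles <- which(rs1 == 1)
  if (length(singles)) {
    jj <- apply(fd$X[singles, , drop = FALSE], 1, which.max)
    df <- rowsum(cbind(u_g[singles] - wt_u, 1), jj)
    da <- rowsum(cbind(v_g[singles] - wt_v, 1), jj)
    eg_f[as.integer(rownames(df))] <- rt * df[, 1] / df[, 2]
    eg_a[as.integer(rownames(da))] <- rt * da[, 1] / da[, 2]
  }
  energies <- switch(as.character(lay$n_sets),
                     "1" = eg_f,
                     "2" = c(eg_f, eg_a),
                     "3" = c(eg_f, eg_a, eg_a))
  wt <- switch(as.character(lay$n_sets),
               "1" = rt * wt_u,
               "2" = c(rt * wt_u, rt * wt_v),
               "3" = c(rt * wt_u, rt * wt_v, rt * wt_v))
  c(energies, wt, a0, b0)
}

#' Fit an energy model to fitness observations
#'
#' Minimises the error-weighted sum of squares
#' `sum(w_i * (y_i - yhat_i)^2)` with `w_i = 1/sigma_i^2`, jointly across
#' assays and blocks sharing the per-mutation energy parameters, using
#' L-BFGS-B with analytic gradients. Energies enter through the Boltzmann
#' state-occupancy nonlinearities, which pins their sign and scale at fixed
#' RT. Supports the two-state (single trait), three-state
#' (folding + activation) and four-state (two independent active states)
#' observation models, and exclusion of listed genetic backgrounds.
#'
#' @param observations Tibble with columns `genotype`, `assay`
#'   (`"activity"`/`"abundance"`), `block`, `fitness`, `sigma` (> 0), and
#'   optionally `background_id`.
#' @param n_states 2, 3 or 4.
#' @param const A [thermo_const()].
#' @param exclude_backgrounds Character vector of `background_id`s to drop
#'   before fitting (e.g. a degenerate, saturated background).
#' @param init Optional initial parameter vector (expert use).
#' @param maxit,factr Optimiser controls.
#' @param anchor_tau SD (kcal/mol) of a weak Gaussian tether that keeps
#'   each per-mutation energy near its direct single-mutant inversion
#'   estimate. Negligible for data-identified parameters; pins fully
#'   saturated (data-flat) ones at the assay detection limit instead of
#'   letting them drift without bound. `NULL` disables the tether.
#' @param seed Integer; fixed for determinism of any seeded sub-steps.
#' @return An object of class `energy_fit`: the fitted [energy_model()]
#'   plus optimisation metadata (`value`, `loss_trace`, `convergence`).
#' @export
fit_energy_model <- function(observations, n_states = 3,
                             const = thermo_const(),
                             exclude_backgrounds = NULL,
                             init = NULL, maxit = 2000, factr = 1e4,
                             anchor_tau = 10, seed = 1) {
  fd <- build_fit_data(observations, const, exclude_backgrounds)
  lay <- par_layout(length(fd$muts), length(fd$akey), as.integer(n_states))
  theta0 <- if (is.null(init)) init_par(fd, lay) else init
  anchor <- if (is.null(anchor_tau)) NULL else {
    theta0[seq_len(lay$n_sets * lay$M)]
  }
  # the tether is expressed at a reference fitness error of 0.1 and scaled
  # inversely with the dataset's median error, so it vanishes in the
  # error-free limit and never competes with precise data
  tau_eff <- if (is.null(anchor_tau)) 10 else {
    anchor_tau * 0.1 / stats::median(fd$obs$sigma)
  }
  ob <- make_objective(fd, as.integer(n_states), anchor = anchor,
                       tau = tau_eff)
  trace_env <- new.env()
  trace_env$best <- Inf
  trace_env$trace <- numeric(0)
  fn_traced <- function(theta) {
    v <- ob$fn(theta)
    if (is.finite(v) && v < trace_env$best) {
      trace_env$best <- v
      trace_env$trace <- c(trace_env$trace, v)
    }
    v
  }
  # stage 1: short quasi-Newton warm-up from the analytic inversion init
  # (keeps the affine layers honest while energies settle into the basin)
  opt1 <- stats::optim(theta0, fn_traced, ob$gr, method = "L-BFGS-B",
                       control = list(maxit = min(maxit, 150),
                                      factr = factr))
  # stage 2: damped Gauss-Newton to convergence on the weighted residuals
  opt <- lm_refine(ob, opt1$par, maxit = maxit)
  trace_env$trace <- c(trace_env$trace[trace_env$trace >= opt$trace[1]],
                       opt$trace)
  p <- unpack_par(opt$par, ob$lay)
  ddG <- tibble::tibble(mutation = fd$muts, ddGf = p$eg[, 1],
                        ddGa = if (ob$lay$n_sets >= 2) p$eg[, 2] else 0)
  if (ob$lay$n_sets == 3) ddG$ddGa2 <- p$eg[, 3]
  ak <- strsplit(fd$akey, " ", fixed = TRUE)
  affine <- tibble::tibble(assay = vapply(ak, `[`, "", 1),
                           block = as.integer(vapply(ak, `[`, "", 2)),
                           intercept = p$a, slope = p$b)
  wt_a <- if (ob$lay$n_sets >= 2) p$wt[2] else 0
  wt_a2 <- if (ob$lay$n_sets == 3) p$wt[3] else wt_a
  model <- energy_model(ddG, wt_dGf = p$wt[1], wt_dGa = wt_a,
                        wt_dGa2 = wt_a2,
                        affine = affine, n_states = n_states, const = const)
  structure(list(model = model, value = opt$value,
                 loss_trace = trace_env$trace,
                 convergence = opt$convergence, message = opt$message,
                 n_obs = nrow(fd$obs), n_par = ob$lay$n_par,
                 n_states = as.integer(n_states), seed = seed,
                 excluded = exclude_backgrounds),
            class = "energy_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.energy_fit <- function(x, ...) {
  cat("<energy_fit> ", x$n_states, "-state, ", nrow(x$model$ddG),
      " mutations, ", x$n_obs, " observations\n", sep = "")
  cat("  weighted loss ", format(x$value, digits = 4), ", convergence code ",
      x$convergence, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted energy model
#'
#' @param x An `energy_fit`.
#' @param ... Unused.
#' @return Tibble with one row per mutation: energies (and their SDs when
#'   [estimate_uncertainty()] results have been attached).
#' @export
tidy.energy_fit <- function(x, ...) {
  x$model$ddG
}

#' One-row fit summary
#'
#' @param x An `energy_fit`.
#' @param ... Unused.
#' @export
glance.energy_fit <- function(x, ...) {
  tibble::tibble(n_states = x$n_states, n_obs = x$n_obs, n_par = x$n_par,
                 loss = x$value, convergence = x$convergence,
                 wt_dGf = x$model$wt_dGf, wt_dGa = x$model$wt_dGa)
}

#' Cross-validate an energy model on held-out double mutants
#'
#' Folds partition the unique double-mutant genotypes; wild-type and single
#' mutants are always in the training set (they carry the parameters of
#' interest and appear in many doubles). Each fold refits the model and
#' scores predicted versus observed fitness R-squared on the held-out
#' doubles.
#'
#' @inheritParams fit_energy_model
#' @param k_folds Number of folds.
#' @return List with `folds` (tibble fold x assay R-squared, plus pooled
#'   rows with `assay = "all"`) and `median_r2` (pooled-median).
#' @export
crossvalidate <- function(observations, n_states = 3, k_folds = 10,
                          seed = 1, const = thermo_const(),
                          exclude_backgrounds = NULL, ...) {
  obs <- tibble::as_tibble(observations)
  if (!is.null(exclude_backgrounds) && "background_id" %in% names(obs)) {
    obs <- obs[!obs$background_id %in% exclude_backgrounds, ]
  }
  ord <- genotype_order(obs$genotype)
  doubles <- sort(unique(obs$genotype[ord == 2]))
  if (length(doubles) < k_folds) {
    stop("fewer double-mutant genotypes (", length(doubles),
         ") than folds (", k_folds, ")")
  }
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(k_folds), length(doubles)))
  rows <- list()
  for (f in seq_len(k_folds)) {
    held <- doubles[fold_of == f]
    train <- obs[!obs$genotype %in% held, ]
    test <- obs[obs$genotype %in% held, ]
    fit <- fit_energy_model(train, n_states = n_states, const = const,
                            seed = seed + f, ...)
    pred <- predict_fitness(test, fit$model)
    r2 <- function(o, p) 1 - sum((o - p)^2) / sum((o - mean(o))^2)
    by_assay <- pred |>
      dplyr::group_by(.data$assay) |>
      dplyr::summarise(r2 = r2(.data$fitness, .data$predicted),
                       .groups = "drop")
    rows[[f]] <- dplyr::bind_rows(
      dplyr::mutate(by_assay, fold = f),
      tibble::tibble(assay = "all", fold = f,
                     r2 = r2(pred$fitness, pred$predicted)))
  }
  folds <- dplyr::bind_rows(rows)
  list(folds = folds,
       median_r2 = stats::median(folds$r2[folds$assay == "all"]))
}

#' Maximum and fractional explainable variance
#'
#' The maximum explainable variance of a fitness dataset is its total
#' variance minus the mean technical variance,
#' `MEV = Var(fitness) - mean(sigma^2)`, and the fraction of explainable
#' variance is `FEV = MEV / Var(fitness)`. Variants whose errors fall in
#' the top 15th percentile are discarded first to keep outlier errors from
#' dominating the estimate. Normalised model performance is `R^2 / FEV`.
#'
#' @param fitness Numeric fitness values.
#' @param sigma Per-variant fitness errors (> 0).
#' @param error_quantile Errors above this quantile are discarded (0.85
#'   keeps the lower 85%).
#' @return List with `MEV`, `FEV` and `n_retained`.
#' @export
explainable_variance <- function(fitness, sigma, error_quantile = 0.85) {
  stopifnot(length(fitness) == length(sigma), length(fitness) >= 2)
  keep <- sigma <= stats::quantile(sigma, error_quantile)
  fitness <- fitness[keep]; sigma <- sigma[keep]
  v <- stats::var(fitness)
  if (v == 0) stop("zero fitness variance after error filtering")
  mev <- v - mean(sigma^2)
  if (mev < 0) {
    warning("technical variance exceeds total variance; MEV clipped to 0")
    mev <- 0
  }
  list(MEV = mev, FEV = mev / v, n_retained = sum(keep))
}

#' Ensemble uncertainty of fitted energies
#'
#' Refits the model on `n_replicates` training subsets (each dropping one
#' cross-validation fold of double mutants) and reports the SD of each
#' per-mutation energy across the ensemble.
#'
#' @inheritParams crossvalidate
#' @param n_replicates Number of ensemble refits (>= 2).
#' @return Tibble `mutation`, `ddGf_mean`, `ddGf_sd`, `ddGa_mean`,
#'   `ddGa_sd`.
#' @export
estimate_uncertainty <- function(observations, n_states = 3,
                                 n_replicates = 10, seed = 1,
                                 const = thermo_const(), ...) {
  stopifnot(n_replicates >= 2)
  obs <- tibble::as_tibble(observations)
  ord <- genotype_order(obs$genotype)
  doubles <- sort(unique(obs$genotype[ord == 2]))
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(n_replicates), length(doubles)))
  fits <- vector("list", n_replicates)
  for (f in seq_len(n_replicates)) {
    held <- doubles[fold_of == f]
    train <- obs[!obs$genotype %in% held, ]
    fits[[f]] <- tidy(fit_energy_model(train, n_states = n_states,
                                       const = const, seed = seed + f, ...))
  }
  all_f <- dplyr::bind_rows(fits, .id = "rep")
  all_f |>
    dplyr::group_by(.data$mutation) |>
    dplyr::summarise(ddGf_mean = mean(.data$ddGf),
                     ddGf_sd = stats::sd(.data$ddGf),
                     ddGa_mean = mean(.data$ddGa),
                     ddGa_sd = stats::sd(.data$ddGa), .groups = "drop")
}
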