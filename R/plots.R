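## ggplot2 displays for the main result types.

#' Plot an exponential decay fit
#'
#' Per-site values against distance with the fitted exponential overlaid.
#'
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.decay_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(d = seq(min(dat$d), max(dat$d), length.out = 200))
  grid$y <- object$amplitude * exp(object$rate * grid$d)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$d, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "firebrick", linewidth = 1) +
    ggplot2::labs(
      x = "distance to active site (Å)",
      y = "per-site mean |ΔΔGa| (kcal/mol)",
      subtitle = sprintf("a = %.2f, k = %.3f 1/Å, d1/2 = %.1f Å",
                         object$amplitude, object$rate, object$d_half)) +
    ggplot2::theme_minimal()
}

#' Plot a fitted energy model
#'
#' Distributions of the fitted folding and activity energies.
#'
#' @param object An `energy_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.energy_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$model$ddG[, c("ddGf", "ddGa")],
                              dplyr::everything(),
                              names_to = "energy", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey30") +
    ggplot2::facet_wrap(~ energy, scales = "free") +
    ggplot2::labs(x = "kcal/mol", y = "mutations") +
    ggplot2::theme_minimal()
}

#' Scatter of true versus inferred energies
#'
#' @param truth A `ground_truth`.
#' @param fit An `energy_fit`.
#' @return A ggplot faceted by energy with Pearson r annotations.
#' @export
plot_energy_recovery <- function(truth, fit) {
  j <- dplyr::inner_join(truth$ddG, tidy(fit), by = "mutation",
                         suffix = c("_true", "_fit"))
  long <- dplyr::bind_rows(
    tibble::tibble(energy = "ddGf", true = j$ddGf_true, fit = j$ddGf_fit),
    tibble::tibble(energy = "ddGa", true = j$ddGa_true, fit = j$ddGa_fit))
  lab <- long |>
    dplyr::group_by(.data$energy) |>
    dplyr::summarise(r = stats::cor(.data$true, .data$fit),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$true, y = .data$fit)) +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_text(data = lab, x = -Inf, y = Inf, hjust = -0.2,
                       vjust = 1.5,
                       ggplot2::aes(label = sprintf("r = %.3f", .data$r))) +
    ggplot2::facet_wrap(~ energy, scales = "free") +
    ggplot2::labs(x = "true (kcal/mol)", y = "inferred (kcal/mol)") +
    ggplot2::theme_minimal()
}

#' Pocket prioritisation chart
#'
#' Inactivating enrichment odds ratio per unique pocket, shaded by
#' druggability.
#'
#' @param scored Output of [score_pockets()].
#' @return A ggplot.
#' @export
plot_pocket_ranking <- function(scored) {
  s <- tibble::as_tibble(scored)
  s$pocket <- factor(paste0("UP", s$unique_pocket),
                     levels = rev(paste0("UP", s$unique_pocket)))
  or_cap <- ifelse(is.finite(s$or_inactivating), s$or_inactivating,
                   max(s$or_inactivating[is.finite(s$or_inactivating)],
                       1, na.rm = TRUE) * 2)
  s$or_plot <- or_cap
  ggplot2::ggplot(s, ggplot2::aes(x = .data$or_plot, y = .data$pocket,
                                  fill = .data$druggability_median)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = "inactivating enrichment OR", y = NULL,
                  fill = "druggability") +
    ggplot2::theme_minimal()
}
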