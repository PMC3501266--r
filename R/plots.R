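# ggplot2 visualization methods.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.free_pulse <- function(object, xlim = NULL, n = 600, ...) {
  if (is.null(xlim)) xlim <- c(-0.75 * object$d, 1.75 * object$d)
  xi <- seq(xlim[1], xlim[2], length.out = n)
  df <- tibble::tibble(xi = xi, U = pulse_profile(object, xi))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$xi, y = .data$U)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = object$kappa, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = c(0, object$d), linetype = 3,
                        colour = "grey60") +
    ggplot2::labs(x = expression(xi), y = expression(U(xi)),
                  title = sprintf("Traveling pulse (c = %.3g, d = %.3g)",
                                  object$c, object$d)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.locked_pulse <- function(object, xlim = NULL, n = 600, ...) {
  w <- object$d2 - object$d1
  if (is.null(xlim)) xlim <- c(object$d1 - 0.75 * w, object$d2 + 0.75 * w)
  xi <- seq(xlim[1], xlim[2], length.out = n)
  s <- object$stimulus
  df <- tibble::tibble(xi = xi, U = pulse_profile(object, xi))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$xi, y = .data$U)) +
    ggplot2::annotate("rect", xmin = 0, xmax = s$width, ymin = -Inf,
                      ymax = Inf, alpha = 0.12, fill = "steelblue") +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = object$kappa, linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_vline(xintercept = c(object$d1, object$d2), linetype = 3,
                        colour = "grey60") +
    ggplot2::labs(x = expression(xi), y = expression(U(xi)),
                  title = sprintf(
                    "Stimulus-locked pulse (d1 = %.3g, d2 = %.3g, v = %g)",
                    object$d1, object$d2, s$v)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.spectrum_report <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$re, y = .data$im)) +
    ggplot2::geom_vline(xintercept = object$essential_re,
                        colour = "firebrick", linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = expression(Re(lambda)), y = expression(Im(lambda)),
                  title = sprintf("Discrete spectrum (%s)", object$verdict),
                  subtitle = "dashed line: essential spectrum") +
    ggplot2::theme_minimal()
}

#' Plot a branch-scan table
#'
#' Speed and width of the free-pulse branches against the threshold,
#' colored by stability.
#'
#' @param scan Tibble from \code{\link{branch_scan}}.
#' @return A ggplot object.
#' @export
plot_branches <- function(scan) {
  long <- tidyr::pivot_longer(scan, c("c", "d"), names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$kappa, y = .data$value,
                                     colour = .data$stability)) +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::facet_wrap(~quantity, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(c = "pulse speed c", d = "pulse width d"))) +
    ggplot2::scale_colour_manual(values = c(stable = "black",
                                            unstable = "grey60",
                                            unknown = "orange")) +
    ggplot2::labs(x = expression(kappa), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a locking-tongue classification grid
#'
#' @param tongues Tibble from \code{\link{locking_tongues}}.
#' @return A ggplot object.
#' @export
plot_tongues <- function(tongues) {
  tongues$class <- with(tongues, dplyr::case_when(
    is.na(n_stable) ~ "failed",
    n_stable >= 1 & n_unstable >= 1 ~ "stable + unstable",
    n_stable >= 1 ~ "stable only",
    n_unstable >= 1 ~ "unstable only",
    TRUE ~ "no locking"))
  ggplot2::ggplot(tongues, ggplot2::aes(x = .data$v, y = .data$I0,
                                        fill = .data$class)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      "no locking" = "white", "stable + unstable" = "grey80",
      "unstable only" = "grey50", "stable only" = "grey30",
      "failed" = "red")) +
    ggplot2::labs(x = "stimulus speed v", y = expression(I[0])) +
    ggplot2::theme_minimal()
}

#' Plot ensemble wandering curves
#'
#' Mean level-set position and its across-trial variance against time,
#' per pulse edge.
#'
#' @param stats Tibble from \code{\link{ensemble_stats}}.
#' @return A ggplot object.
#' @export
plot_wandering <- function(stats) {
  long <- tidyr::pivot_longer(stats, c("mean_pos", "var_pos"),
                              names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$value,
                                     colour = .data$edge)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(mean_pos = "mean position",
                            var_pos = "position variance"))) +
    ggplot2::labs(x = "t", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.wave_ensemble <- function(object, trial = 1, times = NULL, ...) {
  if (is.null(object$snapshots))
    stop("no snapshots recorded; rerun with n_snapshot_trials > 0")
  tt <- object$times
  if (is.null(times)) times <- tt[round(seq(1, length(tt), length.out = 4))]
  idx <- vapply(times, function(t) which.min(abs(tt - t)), integer(1))
  df <- dplyr::bind_rows(lapply(idx, function(i) {
    tibble::tibble(x = object$x, u = object$snapshots[, trial, i],
                   time = sprintf("t = %g", tt[i]))
  }))
  df$time <- factor(df$time, levels = unique(df$time))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$u)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$firing$kappa, linetype = 2,
                        colour = "grey50") +
    ggplot2::facet_wrap(~time) +
    ggplot2::labs(x = "x", y = "U(x, t)") +
    ggplot2::theme_minimal()
}
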