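#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an ancestry-covariance decay curve
#'
#' @param object a `decay_curve`.
#' @param fit optional `date_fit` to overlay.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot decay_curve
#' @export
autoplot.decay_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$mid, y = .data$value)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::labs(x = "genetic distance (Morgans)",
                  y = "weighted ancestry covariance")
  if (!is.null(fit) && isTRUE(fit$signal)) {
    grid <- tibble::tibble(mid = seq(min(object$mid), max(object$mid),
                                     length.out = 400))
    grid$value <- fit$A * exp(-fit$t * grid$mid) + fit$c
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick") +
      ggplot2::ggtitle(sprintf("t = %.0f +/- %.0f generations",
                               fit$t, fit$se))
  }
  p
}

#' Plot an effective-size likelihood profile
#'
#' @param object an `ne_fit`.
#' @param ... unused.
#' @return a ggplot of the profile with the MLE and 95% CI marked.
#' @method autoplot ne_fit
#' @export
autoplot.ne_fit <- function(object, ...) {
  grid <- object$grid
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$two_ne / 2, y = .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$ne, colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$ci_ne[is.finite(object$ci_ne)],
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Ne", y = "log likelihood")
}

#' Plot a calibration posterior
#'
#' @param object a `cal_result`.
#' @param ... unused.
#' @return a ggplot of the calendar posterior with HPD intervals shaded.
#' @method autoplot cal_result
#' @export
autoplot.cal_result <- function(object, ...) {
  post <- attr(object, "posterior")
  in_hpd <- rep(FALSE, nrow(post))
  for (k in seq_len(nrow(object)))
    in_hpd <- in_hpd | (post$cal_bp <= object$start_cal_bp[k] &
                          post$cal_bp >= object$end_cal_bp[k])
  post$hpd <- in_hpd
  ggplot2::ggplot(post, ggplot2::aes(x = .data$cal_bp, y = .data$prob)) +
    ggplot2::geom_area(data = post[post$hpd, ], fill = "grey70") +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "cal BP", y = "posterior probability")
}

#' Plot PCA scores with projected individuals
#'
#' @param basis a `pca_basis`.
#' @param projected optional tibble from [project_individuals()].
#' @param dims which two components to draw (default 1:2).
#' @return a ggplot.
#' @export
plot_pca <- function(basis, projected = NULL, dims = 1:2) {
  xs <- paste0("PC", dims[1]); ys <- paste0("PC", dims[2])
  p <- ggplot2::ggplot(basis$ref_scores,
                       ggplot2::aes(x = .data[[xs]], y = .data[[ys]])) +
    ggplot2::geom_point(colour = "grey50") +
    ggplot2::labs(x = xs, y = ys)
  if (!is.null(projected))
    p <- p + ggplot2::geom_point(data = projected, colour = "firebrick")
  p
}
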