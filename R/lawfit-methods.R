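law_fit_formula <- function(x) {
  switch(x$family,
         polynomial = sprintf("1 + %.4g * r^%.4g",
                              x$params[["k"]], x$params[["d"]]),
         exponential = sprintf("1 + %.4g * (%.4g^r - 1)",
                               x$params[["a"]], x$params[["b"]]))
}

law_fit_predict <- function(x, r) {
  switch(x$family,
         polynomial = 1 + x$params[["k"]] * r^x$params[["d"]],
         exponential = 1 + x$params[["a"]] * (x$params[["b"]]^r - 1))
}

#' @export
print.law_fit <- function(x, ...) {
  cat(sprintf("Volume-law fit (%s): |B(r)| = %s\n",
              x$family, law_fit_formula(x)))
  if (x$family == "polynomial") {
    cat(sprintf("  dimension d = %.3f +/- %.3f\n",
                x$params[["d"]], x$se[["d"]]))
  }
  cat(sprintf("  window [%g, %g], %d points, weighted RSS %.4g\n",
              x$window[1], x$window[2], x$n_points, x$rss))
  invisible(x)
}

#' @export
summary.law_fit <- function(object, ...) {
  tab <- data.frame(estimate = unname(object$params),
                    std_error = unname(object$se),
                    row.names = names(object$params))
  out <- list(family = object$family, coefficients = tab,
              window = object$window, rss = object$rss,
              n_points = object$n_points,
              network_size = object$profile$network_size,
              accepted_family = object$accepted_family)
  class(out) <- "summary.law_fit"
  out
}

#' @export
print.summary.law_fit <- function(x, ...) {
  cat(sprintf("Volume-law fit, family = %s\n", x$family))
  if (!is.null(x$accepted_family) && x$accepted_family != x$family) {
    cat(sprintf("  (classification: %s)\n", x$accepted_family))
  }
  print(x$coefficients)
  cat(sprintf("Fit window [%g, %g] with %d radii; weighted RSS %.5g\n",
              x$window[1], x$window[2], x$n_points, x$rss))
  cat(sprintf("Network size (saturation ceiling): %d\n", x$network_size))
  invisible(x)
}

#' @export
coef.law_fit <- function(object, ...) object$params

#' @export
predict.law_fit <- function(object, newdata = NULL, ...) {
  r <- if (is.null(newdata)) object$r
       else if (is.list(newdata)) newdata$radius else newdata
  law_fit_predict(object, as.numeric(r))
}

#' @export
residuals.law_fit <- function(object, type = c("raw", "weighted"), ...) {
  type <- match.arg(type)
  res <- object$y - object$fitted
  if (type == "weighted") res <- res / object$sd
  res
}

#' @export
plot.law_fit <- function(x, log = "xy", ...) {
  prof <- x$profile
  keep <- if (grepl("x", log)) prof$radii > 0 else rep(TRUE, length(prof$radii))
  graphics::plot(prof$radii[keep], prof$mean[keep], log = log,
                 xlab = sprintf("radius (%s)", prof$units),
                 ylab = "mean ball volume", pch = 16, cex = 0.6, ...)
  graphics::abline(h = prof$network_size, lty = 3)
  rr <- seq(max(x$window[1], min(prof$radii[keep])), x$window[2],
            length.out = 200)
  graphics::lines(rr, law_fit_predict(x, rr), col = 2, lwd = 2)
  graphics::abline(v = x$window, lty = 2, col = "grey60")
  invisible(x)
}

#' Simulate volume profiles from a fitted law
#'
#' Draws replicate mean-volume curves on the fitted model's in-window radii:
#' the fitted curve plus Gaussian noise with the profile's per-radius
#' standard error of the mean (sd / sqrt(n_samples)). Useful for
#' parametric-bootstrap checks of the fitted dimension.
#'
#' @param object a `law_fit`.
#' @param nsim number of replicate curves.
#' @param seed integer seed.
#' @param ... unused.
#' @return A matrix with one column per replicate and one row per in-window
#'   radius.
#' @export
simulate.law_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  sem <- object$sd / sqrt(object$profile$n_samples)
  n <- length(object$r)
  out <- matrix(stats::rnorm(n * nsim, mean = object$fitted, sd = sem),
                nrow = n, ncol = nsim)
  rownames(out) <- signif(object$r, 6)
  out
}
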