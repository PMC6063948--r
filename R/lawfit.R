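#' Choose the fit window of a volume profile
#'
#' Very small and very large radii are excluded from the regression: volumes
#' in a network are discrete, so small radii deviate from the continuous
#' law, and the finiteness of the network caps volumes near saturation.
#' The default window starts at the smallest radius whose mean volume
#' reaches `min_volume` and ends at the largest radius whose mean volume is
#' at most `saturation_frac` of the network size. Both ends can be
#' overridden.
#'
#' @param profile a [volume_profile()].
#' @param r_lo,r_hi optional explicit window bounds (radius values).
#' @param min_volume lower mean-volume cutoff (default 5).
#' @param saturation_frac upper cutoff as a fraction of network size
#'   (default 0.5).
#' @param min_points minimum number of in-window radii required (default 4).
#' @return Numeric `c(r_lo, r_hi)`.
#' @export
select_window <- function(profile, r_lo = NULL, r_hi = NULL, min_volume = 5,
                          saturation_frac = 0.5, min_points = 4) {
  stopifnot(inherits(profile, "volume_profile"))
  r <- profile$radii
  mu <- profile$mean
  if (is.null(r_lo)) {
    i <- which(mu >= min_volume)
    if (length(i) == 0) {
      stop("fit window infeasible: mean volume never reaches ", min_volume,
           "; use a larger network or finer grid", call. = FALSE)
    }
    r_lo <- r[min(i)]
  }
  if (is.null(r_hi)) {
    i <- which(mu <= saturation_frac * profile$network_size)
    if (length(i) == 0) {
      stop("fit window infeasible: profile saturates immediately",
           call. = FALSE)
    }
    r_hi <- r[max(i)]
  }
  n_in <- sum(r >= r_lo & r <= r_hi)
  if (n_in < min_points) {
    stop(sprintf(paste0("fit window [%g, %g] retains only %d point(s) ",
                        "(need %d); use a larger network or finer grid"),
                 r_lo, r_hi, n_in, min_points), call. = FALSE)
  }
  c(r_lo, r_hi)
}

# Weighted nonlinear least squares on the natural scale, shared by both
# families. Parameters are optimised on the log scale (positivity), from a
# deterministic fan of 5 starts around `init`; standard errors come from
# the curvature (inverse Hessian) of the weighted objective at the optimum,
# mapped back by the delta method.
wls_fit <- function(r, y, s, model, init_log, par_names, transform,
                    model_grad = NULL) {
  obj <- function(th) {
    f <- model(th)
    if (any(!is.finite(f))) return(1e300)
    sum(((y - f) / s)^2)
  }
  grad <- if (!is.null(model_grad)) {
    function(th) {
      f <- model(th)
      if (any(!is.finite(f))) return(rep(0, length(th)))
      G <- model_grad(th)
      as.numeric(crossprod(G, 2 * (f - y) / s^2))
    }
  }
  starts <- lapply(c(0, -0.5, 0.5, -1, 1),
                   function(off) init_log + off)
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, obj, gr = grad, method = "BFGS",
                   control = list(maxit = 2000, reltol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("nonlinear fit failed to converge after restarts", call. = FALSE)
  }
  # polish + numerical Hessian at the optimum
  best <- stats::optim(best$par, obj, gr = grad, method = "BFGS",
                       hessian = TRUE,
                       control = list(maxit = 2000, reltol = 1e-15))
  params <- transform(best$par)
  se <- rep(NA_real_, length(params))
  # obj is a chi-square: cov(theta_log) = 2 * H^{-1}
  H <- best$hessian
  ok <- all(is.finite(H))
  if (ok) {
    ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) NA)
    ok <- all(is.finite(ev)) && all(ev > 0)
  }
  if (ok) {
    cov_log <- 2 * solve(H)
    # delta method for params = transform(log-scale)
    grad <- transform_jacobian(best$par, transform)
    se <- sqrt(pmax(0, diag(grad %*% cov_log %*% t(grad))))
  }
  names(params) <- par_names
  names(se) <- par_names
  list(params = params, se = se, rss = best$value,
       fitted = model(best$par), converged = best$convergence == 0)
}

transform_jacobian <- function(par, transform, eps = 1e-6) {
  p0 <- transform(par)
  J <- matrix(0, length(p0), length(par))
  for (j in seq_along(par)) {
    pp <- par; pp[j] <- pp[j] + eps
    J[, j] <- (transform(pp) - p0) / eps
  }
  J
}

prepare_fit_data <- function(profile, window) {
  if (is.null(window)) window <- select_window(profile)
  keep <- profile$radii >= window[1] & profile$radii <= window[2]
  r <- profile$radii[keep]
  y <- profile$mean[keep]
  s <- profile$sd[keep]
  # floor zero / missing sds at the smallest positive in-window sd, so
  # deterministic radii do not get infinite weight
  pos <- s[is.finite(s) & s > 0]
  s[!is.finite(s) | s <= 0] <- if (length(pos) > 0) min(pos) else 1
  if (length(r) < 3) {
    stop("too few in-window points for a nonlinear fit", call. = FALSE)
  }
  list(r = r, y = y, s = s, window = window)
}

new_law_fit <- function(family, fit, data, profile) {
  structure(list(family = family, params = fit$params, se = fit$se,
                 window = data$window, rss = fit$rss,
                 n_points = length(data$r), r = data$r, y = data$y,
                 sd = data$s, fitted = fit$fitted,
                 converged = fit$converged, profile = profile),
            class = "law_fit")
}

#' Fit the polynomial volume law
#'
#' Fits the polynomial volume law |B(r)| = 1 + k * r^d to the in-window
#' mean volumes by least squares weighted with the per-radius standard
#' deviations (weights 1/sd^2, on the natural scale). The exponent d is the
#' network's dimension. The optimiser is initialised from an ordinary
#' log-log regression of (mean - 1) on radius and restarted from a small
#' deterministic fan of perturbed starts; standard errors come from the
#' curvature of the weighted objective at the optimum.
#'
#' @param profile a [volume_profile()].
#' @param window optional `c(r_lo, r_hi)`; default [select_window()].
#' @return An object of class `law_fit` with `family = "polynomial"` and
#'   parameters `k`, `d`.
#' @export
fit_polynomial <- function(profile, window = NULL) {
  dat <- prepare_fit_data(profile, window)
  grow <- dat$y > 1 & dat$r > 0
  init <- if (sum(grow) >= 2) {
    cf <- stats::coef(stats::lm(log(dat$y[grow] - 1) ~ log(dat$r[grow])))
    c(cf[1], log(max(min(cf[2], 10), 0.05)))
  } else c(0, 0)
  model <- function(th) 1 + exp(th[1]) * dat$r^exp(th[2])
  model_grad <- function(th) {
    d <- exp(th[2])
    base <- exp(th[1]) * dat$r^d
    lr <- ifelse(dat$r > 0, log(dat$r), 0)
    cbind(base, base * lr * d)
  }
  fit <- wls_fit(dat$r, dat$y, dat$s, model, unname(init), c("k", "d"),
                 transform = function(th) exp(th),
                 model_grad = model_grad)
  new_law_fit("polynomial", fit, dat, profile)
}

#' Fit the exponential volume law
#'
#' Fits |B(r)| = 1 + a * (b^r - 1) with a > 0 and b > 1, the exponential
#' alternative used by networks without spatial locality (trees of constant
#' branching factor, sparse Erdos-Renyi graphs). The form passes through
#' volume 1 at radius 0, mirroring the structure of the polynomial law.
#' Same weighting and optimiser as [fit_polynomial()].
#'
#' @inheritParams fit_polynomial
#' @return A `law_fit` with `family = "exponential"` and parameters
#'   `a`, `b`.
#' @export
fit_exponential <- function(profile, window = NULL) {
  dat <- prepare_fit_data(profile, window)
  grow <- dat$y > 1
  init <- if (sum(grow) >= 2) {
    cf <- stats::coef(stats::lm(log(dat$y[grow] - 1) ~ dat$r[grow]))
    b0 <- max(exp(cf[2]), 1 + 1e-4)
    c(cf[1], log(b0 - 1))
  } else c(0, 0)
  model <- function(th) 1 + exp(th[1]) * ((1 + exp(th[2]))^dat$r - 1)
  model_grad <- function(th) {
    a <- exp(th[1]); b <- 1 + exp(th[2])
    cbind(a * (b^dat$r - 1),
          a * dat$r * b^(dat$r - 1) * (b - 1))
  }
  fit <- wls_fit(dat$r, dat$y, dat$s, model, unname(init), c("a", "b"),
                 transform = function(th) c(exp(th[1]), 1 + exp(th[2])),
                 model_grad = model_grad)
  new_law_fit("exponential", fit, dat, profile)
}

#' Classify which volume law a profile follows
#'
#' Fits both the polynomial and the exponential law on the same window and
#' selects the family with the smaller weighted residual sum of squares.
#' When even the better fit misses the data badly -- log-scale relative
#' RMSE over the in-window points above `neither_tol` -- the profile is
#' classified as following neither law.
#'
#' @inheritParams fit_polynomial
#' @param neither_tol tolerance on the log-scale relative RMSE of the
#'   better fit (default 0.2, i.e. about 20% typical deviation).
#' @return A list of class `law_classification` with elements `family`
#'   (`"polynomial"`, `"exponential"` or `"neither"`), `polynomial`,
#'   `exponential` (the two `law_fit`s, or `NULL` when infeasible).
#' @export
classify_law <- function(profile, window = NULL, neither_tol = 0.2) {
  if (is.null(window)) window <- select_window(profile)
  pf <- tryCatch(fit_polynomial(profile, window), error = function(e) NULL)
  ef <- tryCatch(fit_exponential(profile, window), error = function(e) NULL)
  if (is.null(pf) && is.null(ef)) {
    res <- list(family = "neither", polynomial = NULL, exponential = NULL,
                note = "both fits infeasible")
    class(res) <- "law_classification"
    return(res)
  }
  rss <- c(polynomial = if (is.null(pf)) Inf else pf$rss,
           exponential = if (is.null(ef)) Inf else ef$rss)
  winner <- names(rss)[which.min(rss)]
  best <- if (winner == "polynomial") pf else ef
  rel <- sqrt(mean(log(pmax(best$fitted, 1e-12) / best$y)^2))
  family <- if (rel > neither_tol) "neither" else winner
  res <- list(family = family, polynomial = pf, exponential = ef,
              log_rmse = rel)
  class(res) <- "law_classification"
  res
}

#' @export
print.law_classification <- function(x, ...) {
  cat("Volume-law classification:", x$family, "\n")
  if (!is.null(x$polynomial)) {
    cat(sprintf("  polynomial:  rss = %.4g, d = %.3f\n",
                x$polynomial$rss, x$polynomial$params[["d"]]))
  }
  if (!is.null(x$exponential)) {
    cat(sprintf("  exponential: rss = %.4g, b = %.3f\n",
                x$exponential$rss, x$exponential$params[["b"]]))
  }
  invisible(x)
}

#' Fit a volume law to a profile
#'
#' The package's central fitting function. With `family = "auto"` both
#' candidate laws are fitted and the better one (by weighted RSS) is
#' returned, with the full [classify_law()] result attached as attribute
#' `"classification"`; otherwise the requested family is fitted directly.
#'
#' @inheritParams fit_polynomial
#' @param family `"auto"`, `"polynomial"` or `"exponential"`.
#' @param ... passed to [classify_law()] (e.g. `neither_tol`).
#' @return A `law_fit` object; see [fit_polynomial()] for its fields and
#'   the `print`, `summary`, `coef`, `predict`, `residuals`, `plot` and
#'   `simulate` methods.
#' @examples
#' g <- build_mocnik(n = 600, dim = 2, rho = 1.8, seed = 7)
#' prof <- volume_profile(g, n_samples = 300, seed = 7,
#'                        weight_mode = "unweighted")
#' fit <- fit_volume_law(prof)
#' coef(fit)
#' @export
fit_volume_law <- function(profile, family = c("auto", "polynomial",
                                               "exponential"),
                           window = NULL, ...) {
  family <- match.arg(family)
  if (family == "polynomial") return(fit_polynomial(profile, window))
  if (family == "exponential") return(fit_exponential(profile, window))
  cls <- classify_law(profile, window, ...)
  best <- switch(cls$family,
                 polynomial = cls$polynomial,
                 exponential = cls$exponential,
                 { # neither: still return the numerically better fit
                   cand <- Filter(Negate(is.null),
                                  list(cls$polynomial, cls$exponential))
                   if (length(cand) == 0) {
                     stop("no volume law could be fitted", call. = FALSE)
                   }
                   cand[[which.min(vapply(cand, `[[`, 0, "rss"))]]
                 })
  best$accepted_family <- cls$family
  attr(best, "classification") <- cls
  best
}

#' Estimate the dimension of a network
#'
#' Convenience wrapper: volume profile of the largest connected component
#' followed by a polynomial volume-law fit. The fitted exponent d is the
#' network's dimension.
#'
#' @param g a [spatial_graph].
#' @inheritParams volume_profile
#' @param ... passed to [volume_profile()].
#' @return A `law_fit` with `family = "polynomial"`.
#' @export
network_dimension <- function(g, n_samples = 10000, seed = 1,
                              weight_mode = "unweighted", ...) {
  prof <- volume_profile(g, n_samples = n_samples, seed = seed,
                         weight_mode = weight_mode, ...)
  fit_polynomial(prof)
}
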