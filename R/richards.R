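#' Richards growth curve on the log-OD scale
#'
#' Evaluates the four-parameter Richards equation used to describe
#' log-transformed, blank-corrected optical-density curves,
#' `y(t) = A * (1 + nu * e^(1+nu) * exp((mu/A) * (1+nu)^(1+1/nu) * (lag - t)))^(-1/nu)`,
#' where `y = ln(dOD/dOD_min)`. Computed through `log1p(exp(.))` so that deep
#' pre-growth lag phases (large positive exponents) do not overflow.
#'
#' @param t time, hours. Vectorised.
#' @param mu specific growth rate, h^-1.
#' @param lag lag time, hours.
#' @param capacity carrying capacity `A` on the log scale (dimensionless);
#'   must be positive.
#' @param shape dimensionless shape factor `nu` (> 0), no biological meaning.
#' @return the curve value `y(t)` (dimensionless).
#' @examples
#' t <- seq(0, 90, 0.25)
#' y <- richards_curve(t, mu = 0.24, lag = 10, capacity = 2, shape = 1)
#' @export
richards_curve <- function(t, mu, lag, capacity, shape) {
  stopifnot(capacity > 0, shape > 0, mu >= 0, lag >= 0)
  z <- (mu / capacity) * (1 + shape)^(1 + 1 / shape) * (lag - t)
  w <- log(shape) + 1 + shape + z
  capacity * exp(-log1p_exp(w) / shape)
}

# log(1 + exp(w)) without overflow
log1p_exp <- function(w) {
  out <- numeric(length(w))
  hi <- w > 33            # exp(w) dominates; log1p(exp(w)) == w to double precision
  out[hi] <- w[hi]
  out[!hi] <- log1p(exp(w[!hi]))
  out
}

#' Fit the Richards equation to a log-transformed growth series
#'
#' Bounded Levenberg-Marquardt least-squares fit of [richards_curve()] to a
#' `log_growth` series (see [log_transform()]), or to raw `t`/`y` vectors.
#' Wells whose transformed signal never rises above `no_growth_threshold`
#' are classified as no-growth: no fit is attempted and `mu` and `capacity`
#' are reported as 0.
#'
#' Starting values are data-driven: `mu0` is the largest finite-difference
#' slope of `y`, `lag0` the first time `y` exceeds 10% of its maximum,
#' `A0 = max(y)` and `nu0 = 1`. Bounds keep `mu`, `lag`, `capacity`
#' non-negative and `nu` in `[0.05, 20]`; the equation is ill-conditioned in
#' `nu`, and bounded data-driven starts stabilise it.
#'
#' @param series a `log_growth` object, or a numeric vector of times when `y`
#'   is given separately.
#' @param y optional numeric response when `series` is a plain time vector.
#' @param no_growth_threshold log-ratio below which a well is called
#'   no-growth (default 0.05). Classification happens in two passes. A
#'   series whose total rise (`max(y) - min(y)`) stays below the threshold
#'   is no-growth outright — for clean data this is the plain
#'   `max(y) < threshold` rule, made insensitive to the common offset that
#'   anchoring `y` to a noisy first reading imprints on a whole well.
#'   Otherwise the curve is fitted, and the well is still reported as
#'   no-growth when the fitted carrying capacity stays below the threshold
#'   or the fit explains less than 20% more variance than a constant —
#'   measurement noise alone can produce excursions above the threshold,
#'   but not a sustained sigmoidal signal.
#' @param init optional named list/vector with starting values `mu`, `lag`,
#'   `capacity`, `shape` overriding the data-driven defaults.
#'
#' @return An object of class `richards_fit`: list with `mu`, `lag`,
#'   `capacity`, `shape`, `sse`, `converged`, `no_growth`, `n` and `well_id`.
#'   Optimiser non-convergence is reported through `converged = FALSE` with
#'   the best parameters found, never as an error.
#' @examples
#' t <- seq(0, 90, 0.25)
#' y <- richards_curve(t, 0.24, 10, 2, 1)
#' fit_richards(t, y)$mu
#' @export
fit_richards <- function(series, y = NULL, no_growth_threshold = 0.05,
                         init = NULL) {
  if (inherits(series, "log_growth")) {
    t <- series$t
    yv <- series$y
    well_id <- series$well_id
  } else {
    t <- series
    yv <- y
    well_id <- NA_character_
  }
  stopifnot(is.numeric(t), is.numeric(yv), length(t) == length(yv))
  if (length(t) < 8L)
    stop("at least 8 timepoints are required to fit the Richards equation",
         call. = FALSE)

  no_growth_fit <- function() {
    structure(list(mu = 0, lag = 0, capacity = 0, shape = 1,
                   sse = sum(yv^2), converged = TRUE, no_growth = TRUE,
                   n = length(t), well_id = well_id),
              class = "richards_fit")
  }
  if (max(yv) - min(yv) < no_growth_threshold) return(no_growth_fit())

  slopes <- diff(yv) / diff(t)
  mu0 <- max(slopes, 1e-3)
  lag0 <- t[which(yv > 0.1 * max(yv))[1]]
  if (is.na(lag0)) lag0 <- 0
  a0 <- max(yv)
  start <- c(mu = mu0, lag = max(lag0, 0), capacity = a0, shape = 1)
  if (!is.null(init)) {
    init <- unlist(init)
    start[names(init)] <- init
  }

  resid_fn <- function(p) {
    yv - richards_curve(t, p[["mu"]], p[["lag"]], max(p[["capacity"]], 1e-9),
                        p[["shape"]])
  }
  fit <- minpack.lm::nls.lm(
    par = start, fn = resid_fn,
    lower = c(0, 0, 1e-9, 0.05), upper = c(Inf, Inf, Inf, 20),
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-15,
                                         ptol = 1e-15, gtol = 0))
  p <- fit$par
  sse_fit <- sum(fit$fvec^2)
  sse_const <- sum((yv - mean(yv))^2)
  if (p[["capacity"]] < no_growth_threshold || sse_fit > 0.8 * sse_const)
    return(no_growth_fit())
  structure(list(mu = p[["mu"]], lag = p[["lag"]], capacity = p[["capacity"]],
                 shape = p[["shape"]], sse = sum(fit$fvec^2),
                 converged = fit$info %in% 1:4, no_growth = FALSE,
                 n = length(t), well_id = well_id),
            class = "richards_fit")
}

#' @export
print.richards_fit <- function(x, ...) {
  if (x$no_growth) {
    cat("Richards fit: no growth detected (mu = 0)\n")
  } else {
    cat(sprintf(
      "Richards fit: mu = %.4f h-1, lag = %.2f h, A = %.3f, nu = %.3f (SSE %.3g)%s\n",
      x$mu, x$lag, x$capacity, x$shape, x$sse,
      if (x$converged) "" else " [not converged]"))
  }
  invisible(x)
}
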