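#' Specify a candidate rate law for one compound
#'
#' Describes which kinetic family is fitted to the growth-rate response of a
#' single compound during model selection. Substrates admit `monod`,
#' `haldane` and `monod_toxlimit`; products admit `toxlimit` and
#' `linear_inhibition`. For butyric acid the candidate law is multiplied by a
#' fixed Monod conditioning factor in acetic acid, because growth on BA
#' cannot be decoupled from the small amount of AA needed to initiate it;
#' the conditioning half-saturation defaults to the stage-1 AA estimate
#' (4.7 mM when run standalone).
#'
#' @param compound one of `"AA"`, `"BA"`, `"HA"`, `"EtOH"`.
#' @param family one of `"monod"`, `"haldane"`, `"monod_toxlimit"`,
#'   `"toxlimit"`, `"linear_inhibition"`.
#' @param fixed named list of parameters held fixed (e.g. `list(ki = 330)`
#'   for the AA toxicity limit).
#' @param conditioning optional list `list(compound = "AA", ks = 4.7)`
#'   describing a multiplicative Monod factor on a second compound.
#' @return an object of class `rate_law_spec`.
#' @export
rate_law_spec <- function(compound, family, fixed = list(),
                          conditioning = NULL) {
  compound <- match.arg(compound, c("AA", "BA", "HA", "EtOH"))
  family <- match.arg(family, c("monod", "haldane", "monod_toxlimit",
                                "toxlimit", "linear_inhibition"))
  substrate_families <- c("monod", "haldane", "monod_toxlimit")
  product_families <- c("toxlimit", "linear_inhibition")
  role <- if (compound %in% c("AA", "EtOH")) "substrate" else "product"
  if (role == "substrate" && !family %in% substrate_families)
    stop(family, " is a product-inhibition law; not admissible for substrate ",
         compound, call. = FALSE)
  if (role == "product" && !family %in% product_families)
    stop(family, " is a substrate law; not admissible for product ",
         compound, call. = FALSE)
  pars <- switch(family,
                 monod = c("mu_max", "ks"),
                 haldane = c("mu_max", "ks", "ki"),
                 monod_toxlimit = c("mu_max", "ks", "ki"),
                 toxlimit = c("mu_max", "ki"),
                 linear_inhibition = c("mu_max", "k"))
  bad <- setdiff(names(fixed), pars)
  if (length(bad))
    stop("fixed parameter(s) not in family '", family, "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  structure(list(compound = compound, family = family, fixed = fixed,
                 free = setdiff(pars, names(fixed)),
                 conditioning = conditioning),
            class = "rate_law_spec")
}

conc_column <- function(compound) {
  switch(compound, AA = "aa0", BA = "ba0", HA = "ha0", EtOH = "etoh0")
}

rate_law_value <- function(family, s, theta) {
  switch(family,
         monod = monod(s, theta[["mu_max"]], theta[["ks"]]),
         haldane = haldane(s, theta[["mu_max"]], theta[["ks"]],
                           theta[["ki"]]),
         monod_toxlimit = monod_toxlimit(s, theta[["mu_max"]], theta[["ks"]],
                                         theta[["ki"]]),
         toxlimit = theta[["mu_max"]] * toxicity_factor(s, theta[["ki"]]),
         linear_inhibition = linear_inhibition(s, theta[["mu_max"]],
                                               theta[["k"]]))
}

predict_rate_law <- function(spec, theta, data) {
  s <- data[[conc_column(spec$compound)]]
  mu <- rate_law_value(spec$family, s, theta)
  if (!is.null(spec$conditioning)) {
    sc <- data[[conc_column(spec$conditioning$compound)]]
    mu <- mu * sc / (spec$conditioning$ks + sc)
  }
  mu
}

default_start <- function(spec, data) {
  s <- data[[conc_column(spec$compound)]]
  mu <- data$mu
  if (!is.null(spec$conditioning)) {
    # divide out the fixed conditioning factor so the starts see the
    # compound's own response
    sc <- data[[conc_column(spec$conditioning$compound)]]
    mu <- mu / pmax(sc / (spec$conditioning$ks + sc), 1e-6)
  }
  mu_top <- max(mu)
  start <- c(mu_max = max(mu_top, 0.05))
  if ("ks" %in% spec$free)
    start["ks"] <- max(stats::median(s[s > 0]) / 5, 0.5)
  if ("ki" %in% spec$free) {
    # place the toxicity threshold inside the observed drop: midway between
    # the last concentration with > half-maximal growth and the first above
    # it without, where the sigmoid actually has leverage
    hi <- s[mu > 0.5 * mu_top]
    if (length(hi) && any(s > max(hi))) {
      lo_edge <- max(hi)
      hi_edge <- min(s[s > lo_edge])
      start["ki"] <- (lo_edge + hi_edge) / 2
    } else if (length(hi)) {
      start["ki"] <- max(hi) * 1.2
    } else {
      start["ki"] <- max(s) / 2
    }
  }
  if ("k" %in% spec$free) {
    sl <- stats::coef(stats::lm(mu ~ s))
    k0 <- if (is.finite(sl[2]) && sl[2] < 0) -sl[2] / max(sl[1], 1e-6)
          else 1 / max(s)
    start["k"] <- max(k0, 1e-6)
  }
  start
}

# Nelder-Mead SSE minimisation over log-parameters (positivity by
# construction); one-dimensional problems fall back to golden-section
# search. The simplex is restarted once from the first solution — cheap
# insurance against premature collapse on the flat plateaus that threshold
# sigmoids put into the SSE surface.
minimise_sse <- function(objective, start, maxit = 5000) {
  lstart <- log(start)
  obj_log <- function(lp) objective(exp(lp))
  if (length(start) == 1L) {
    opt <- stats::optimize(function(lp) obj_log(lp),
                           interval = c(lstart - 12, lstart + 12),
                           tol = 1e-12)
    return(list(par = exp(opt$minimum), value = opt$objective,
                converged = TRUE))
  }
  ctrl <- list(maxit = maxit, reltol = 1e-14)
  opt <- stats::optim(lstart, obj_log, method = "Nelder-Mead", control = ctrl)
  opt2 <- stats::optim(opt$par, obj_log, method = "Nelder-Mead",
                       control = ctrl)
  if (opt2$value < opt$value) opt <- opt2
  list(par = stats::setNames(exp(opt$par), names(start)), value = opt$value,
       converged = opt$convergence == 0)
}

#' Fit one candidate rate law to growth-rate data
#'
#' Minimises the unstandardised sum of squared residuals (observed minus
#' model growth rate, h^-1) over the free parameters of the candidate family
#' using Nelder-Mead in log-parameter space.
#'
#' @param data a growth-rate dataset (see [validate_growth_dataset()]).
#' @param spec a [rate_law_spec()].
#' @param start optional named vector of starting values for the free
#'   parameters; defaults are data-driven.
#' @return an object of class `kin_fit`: estimates, fixed values, `sse`,
#'   `residuals`, `n_obs`, `n_free`, `converged`, and a `predict_fn(theta,
#'   data)` closure used for prediction and sensitivity analysis.
#' @export
fit_rate_law <- function(data, spec, start = NULL) {
  data <- validate_growth_dataset(data)
  stopifnot(inherits(spec, "rate_law_spec"))
  if (all(data$mu == 0))
    stop("degenerate dataset: all growth rates are zero", call. = FALSE)
  if (is.null(start)) start <- default_start(spec, data)
  start <- start[spec$free]
  if (anyNA(start))
    stop("no starting value for parameter(s): ",
         paste(spec$free[is.na(start)], collapse = ", "), call. = FALSE)
  if (nrow(data) < length(start) + 2L)
    stop("underdetermined fit: ", nrow(data), " observations for ",
         length(start), " free parameters", call. = FALSE)

  fixed <- unlist(spec$fixed)
  predict_fn <- function(theta, d) {
    predict_rate_law(spec, c(as.list(theta), as.list(fixed)), d)
  }
  objective <- function(theta) sum((data$mu - predict_fn(theta, data))^2)
  opt <- minimise_sse(objective, start)
  res <- data$mu - predict_fn(opt$par, data)
  structure(list(spec = spec, estimates = opt$par, fixed = fixed,
                 sse = opt$value, residuals = res, n_obs = nrow(data),
                 n_free = length(opt$par), converged = opt$converged,
                 predict_fn = predict_fn),
            class = c("rate_law_fit", "kin_fit"))
}

#' Select the best rate law for a compound by residual comparison
#'
#' Fits every candidate law from its default start and ranks the fits by
#' ascending residual sum of squares; ties are broken in favour of fewer
#' free parameters. Candidates whose fit fails are dropped (their error is
#' collected); if all candidates fail, an error is raised.
#'
#' @param data a growth-rate dataset.
#' @param candidates list of [rate_law_spec()] objects (at least two).
#' @return list of `kin_fit` objects, best first, with attribute `"errors"`
#'   holding messages of failed candidates.
#' @export
select_rate_law <- function(data, candidates) {
  stopifnot(length(candidates) >= 2L)
  fits <- list()
  errors <- character()
  for (cand in candidates) {
    f <- tryCatch(fit_rate_law(data, cand), error = function(e) e)
    if (inherits(f, "error")) {
      errors <- c(errors, paste0(cand$family, ": ", conditionMessage(f)))
    } else {
      fits[[length(fits) + 1L]] <- f
    }
  }
  if (length(fits) == 0L)
    stop("all candidate fits failed: ", paste(errors, collapse = "; "),
         call. = FALSE)
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  n_free <- vapply(fits, `[[`, numeric(1), "n_free")
  # SSE values indistinguishable at numerical precision count as ties,
  # resolved in favour of the more parsimonious candidate
  tol <- 1e-6 * min(sse) + 1e-10
  o <- order(sse)
  cluster <- cumsum(c(1, diff(sse[o]) > tol))[order(o)]
  ord <- order(cluster, n_free)
  structure(fits[ord], errors = errors)
}

#' Simultaneously calibrate the combined growth model
#'
#' Stage-2 calibration: one pooled, unweighted sum of squared residuals over
#' every record of the supplied datasets, minimised over the free parameters
#' of the combined multiplicative model (by default `mu_max`, `ks_aa`,
#' `ki_ba`, `k_ha`; the AA toxicity limit `ki_aa` stays fixed at 330 mM).
#' All calibration experiments share one ethanol concentration, so the
#' calibration form of [combined_mu()] (no ethanol terms) is used.
#'
#' @param data a growth-rate dataset pooling the calibration experiments.
#' @param start a [kinetic_params()] object supplying starting values and
#'   the free/fixed mask — typically the stage-1 estimates.
#' @return a `kin_fit` of class `combined_fit`; `$params` holds the updated
#'   [kinetic_params()].
#' @export
calibrate_combined <- function(data, start = kinetic_params()) {
  data <- validate_growth_dataset(data)
  stopifnot(inherits(start, "kinetic_params"))
  if (all(data$mu == 0))
    stop("degenerate dataset: all growth rates are zero", call. = FALSE)
  if (length(unique(data$experiment_id)) < 2L)
    warning("calibrating on a single experiment; parameters may be poorly ",
            "identifiable", call. = FALSE)
  free <- attr(start, "free")
  theta0 <- unlist(unclass(start))[free]
  if (nrow(data) < length(theta0) + 2L)
    stop("underdetermined fit: ", nrow(data), " observations for ",
         length(theta0), " free parameters", call. = FALSE)
  predict_fn <- function(theta, d) {
    p <- update_params(start, as.list(theta))
    combined_mu(aa = d$aa0, ba = d$ba0, ha = d$ha0, params = p)
  }
  objective <- function(theta) sum((data$mu - predict_fn(theta, data))^2)
  opt <- minimise_sse(objective, theta0)
  res <- data$mu - predict_fn(opt$par, data)
  structure(list(estimates = opt$par,
                 fixed = unlist(unclass(start))[setdiff(names(start), free)],
                 params = update_params(start, as.list(opt$par)),
                 sse = opt$value, residuals = res, n_obs = nrow(data),
                 n_free = length(opt$par), converged = opt$converged,
                 predict_fn = predict_fn),
            class = c("combined_fit", "kin_fit"))
}

#' Fisher-information confidence intervals for a fit
#'
#' Linear (asymptotic) approximation of the parameter covariance: with
#' residual variance `sigma^2 = SSE / (n - p)` and `J` the sensitivity
#' matrix of the model predictions with respect to the free parameters
#' (central differences, relative step 1e-5), the Fisher information is
#' `J'J / sigma^2` and the covariance its inverse,
#' `sigma^2 (J'J)^-1`. 95% intervals are `estimate +/- 1.96 sqrt(diag)`.
#' The parameter correlation matrix is computed from `(J'J)^-1`, which is
#' well defined even in the zero-residual limit.
#'
#' @param fit a `kin_fit` from [fit_rate_law()] or [calibrate_combined()].
#' @param data the growth-rate dataset the fit was computed on.
#' @return the fit augmented with `sigma2`, `covariance`, `ci95` (half
#'   widths) and `correlation`.
#' @export
estimate_confidence <- function(fit, data) {
  stopifnot(inherits(fit, "kin_fit"))
  if (!fit$converged)
    stop("cannot compute confidence intervals for a non-converged fit",
         call. = FALSE)
  data <- validate_growth_dataset(data)
  n <- nrow(data)
  p <- fit$n_free
  if (n - p < 1L)
    stop("no residual degrees of freedom", call. = FALSE)
  theta <- fit$estimates
  J <- matrix(0, n, p, dimnames = list(NULL, names(theta)))
  for (j in seq_len(p)) {
    h <- 1e-5 * max(abs(theta[j]), 1e-8)
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    J[, j] <- (fit$predict_fn(up, data) - fit$predict_fn(dn, data)) / (2 * h)
  }
  jtj <- crossprod(J)
  ev <- eigen(jtj, symmetric = TRUE)
  tol <- max(ev$values) * 1e-10
  if (any(ev$values <= tol)) {
    null_vecs <- ev$vectors[, ev$values <= tol, drop = FALSE]
    involved <- names(theta)[apply(abs(null_vecs) > 1e-3, 1, any)]
    stop("unidentifiable parameter set: ", paste(involved, collapse = ", "),
         call. = FALSE)
  }
  jtj_inv <- ev$vectors %*% diag(1 / ev$values, p) %*% t(ev$vectors)
  dimnames(jtj_inv) <- list(names(theta), names(theta))
  sigma2 <- fit$sse / (n - p)
  covariance <- sigma2 * jtj_inv
  fit$sigma2 <- sigma2
  fit$covariance <- covariance
  fit$ci95 <- 1.96 * sqrt(pmax(diag(covariance), 0))
  fit$correlation <- stats::cov2cor(jtj_inv)
  fit
}

#' Two-stage calibration of the combined kinetic model
#'
#' Reproduces the full calibration workflow:
#'
#' 1. *Stage 1 — per-compound model selection.* For acetic acid (experiments
#'    A and B) the candidates are Monod, Haldane and Monod x toxicity limit
#'    (toxicity limit fixed at `ki_aa`); for butyric acid (experiments E and
#'    F) toxicity limit and linear inhibition, each conditioned on a Monod
#'    factor in AA whose half-saturation is the stage-1 AA estimate; for
#'    hexanoic acid (experiment G) toxicity limit and linear inhibition.
#'    The best law per compound is chosen by residual comparison.
#' 2. *Stage 2 — simultaneous calibration.* All free parameters of the
#'    combined multiplicative model are re-estimated on the pooled records
#'    using the stage-1 estimates as starting values, followed by
#'    Fisher-information confidence intervals.
#'
#' @param data growth-rate dataset covering experiments A, B, E, F and G.
#' @param params template [kinetic_params()] supplying fixed values and the
#'   free mask.
#' @return list of class `two_stage_calibration` with elements `stage1`
#'   (per-compound ranked fits), `start` (stage-2 starting values) and
#'   `stage2` (the confidence-augmented combined fit).
#' @export
calibrate_two_stage <- function(data, params = kinetic_params()) {
  data <- validate_growth_dataset(data)
  have <- unique(data$experiment_id)
  need <- c("A", "B", "E", "F", "G")
  miss <- setdiff(need, have)
  if (length(miss))
    stop("two-stage calibration needs experiments A, B, E, F, G; missing: ",
         paste(miss, collapse = ", "), call. = FALSE)

  aa_data <- data[data$experiment_id %in% c("A", "B"), ]
  ba_data <- data[data$experiment_id %in% c("E", "F"), ]
  ha_data <- data[data$experiment_id == "G", ]

  aa_ranked <- select_rate_law(aa_data, list(
    rate_law_spec("AA", "monod"),
    rate_law_spec("AA", "haldane"),
    rate_law_spec("AA", "monod_toxlimit", fixed = list(ki = params$ki_aa))))
  aa_best <- aa_ranked[[1]]
  ks_stage1 <- if ("ks" %in% names(aa_best$estimates))
    aa_best$estimates[["ks"]] else 4.7

  cond <- list(compound = "AA", ks = ks_stage1)
  ba_ranked <- select_rate_law(ba_data, list(
    rate_law_spec("BA", "toxlimit", conditioning = cond),
    rate_law_spec("BA", "linear_inhibition", conditioning = cond)))
  ba_best <- ba_ranked[[1]]

  ha_ranked <- select_rate_law(ha_data, list(
    rate_law_spec("HA", "toxlimit"),
    rate_law_spec("HA", "linear_inhibition")))
  ha_best <- ha_ranked[[1]]

  pick <- function(fit, nm, fallback) {
    if (nm %in% names(fit$estimates)) fit$estimates[[nm]] else fallback
  }
  start <- update_params(params, list(
    mu_max = pick(aa_best, "mu_max", params$mu_max),
    ks_aa = pick(aa_best, "ks", params$ks_aa),
    ki_ba = pick(ba_best, "ki", params$ki_ba),
    k_ha = pick(ha_best, "k", params$k_ha)))

  stage2 <- calibrate_combined(data, start = start)
  stage2 <- estimate_confidence(stage2, data)

  structure(list(stage1 = list(AA = aa_ranked, BA = ba_ranked,
                               HA = ha_ranked),
                 start = start, stage2 = stage2),
            class = "two_stage_calibration")
}

#' @export
print.kin_fit <- function(x, ...) {
  what <- if (inherits(x, "combined_fit")) "Combined-model fit"
          else sprintf("Rate-law fit (%s, %s)", x$spec$compound,
                       x$spec$family)
  cat(what, "\n")
  for (nm in names(x$estimates)) {
    ci <- if (!is.null(x$ci95)) sprintf(" +/- %.3g", x$ci95[[nm]]) else ""
    cat(sprintf("  %-8s %10.5g%s\n", nm, x$estimates[[nm]], ci))
  }
  cat(sprintf("  SSE %.4g on %d obs (%d free)%s\n", x$sse, x$n_obs, x$n_free,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
print.two_stage_calibration <- function(x, ...) {
  cat("Two-stage kinetic calibration\n")
  cat("Stage 1 (best law per compound):\n")
  for (cmp in names(x$stage1)) {
    best <- x$stage1[[cmp]][[1]]
    cat(sprintf("  %-3s %s (SSE %.4g)\n", cmp, best$spec$family, best$sse))
  }
  cat("Stage 2 (simultaneous, estimates +/- 95% CI):\n")
  s2 <- x$stage2
  for (nm in names(s2$estimates)) {
    cat(sprintf("  %-8s %10.4g +/- %.3g\n", nm, s2$estimates[[nm]],
                s2$ci95[[nm]]))
  }
  invisible(x)
}
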