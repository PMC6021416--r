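#' Candidate kinetic rate laws
#'
#' The five candidate laws compared during per-compound model selection, plus
#' the shared toxicity sigmoid. All functions are vectorised over the
#' concentration argument and return specific growth rates in h^-1 (the
#' toxicity factor is dimensionless).
#'
#' * `monod()`: substrate saturation, `mu_max * s / (ks + s)`.
#' * `haldane()`: substrate inhibition, `mu_max * s / (ks + s + s^2/ki)`.
#' * `toxicity_factor()`: sigmoid threshold `1 - 1/(1 + exp(-(c - ki)))`,
#'   equal to 0.5 at `c == ki`. Concentrations enter the exponent in mM, so
#'   the transition width is a few mM and `ki` behaves as a near-threshold.
#' * `monod_toxlimit()`: Monod multiplied by the toxicity factor on the same
#'   compound.
#' * `linear_inhibition()`: `mu_max * (1 - k * p)`, clamped at zero for
#'   `p > 1/k` (a negative growth rate has no meaning in this data model).
#'
#' @param s,p,c concentration, mM (substrate, product, or either for the
#'   toxicity factor). Must be non-negative.
#' @param mu_max maximum specific growth rate, h^-1.
#' @param ks half-saturation constant, mM.
#' @param ki inhibition / toxicity-limit constant, mM.
#' @param k linear inhibition constant, mM^-1.
#'
#' @return growth rate in h^-1 (dimensionless in `(0, 1)` for
#'   `toxicity_factor`).
#' @examples
#' monod(3.8, 0.24, 3.8)            # half of mu_max
#' toxicity_factor(330, 330)        # sigmoid midpoint, 0.5
#' linear_inhibition(1 / 0.0109, 0.24, 0.0109)  # complete inhibition
#' @name rate_laws
NULL

check_conc <- function(x, what = "concentration") {
  if (any(!is.finite(x)) || any(x < 0))
    stop(what, " must be finite and non-negative", call. = FALSE)
  invisible(x)
}

#' @rdname rate_laws
#' @export
monod <- function(s, mu_max, ks) {
  check_conc(s, "substrate concentration")
  stopifnot(ks > 0, mu_max >= 0)
  mu_max * s / (ks + s)
}

#' @rdname rate_laws
#' @export
haldane <- function(s, mu_max, ks, ki) {
  check_conc(s, "substrate concentration")
  stopifnot(ks > 0, ki > 0, mu_max >= 0)
  mu_max * s / (ks + s + s^2 / ki)
}

#' @rdname rate_laws
#' @export
toxicity_factor <- function(c, ki) {
  check_conc(c, "concentration")
  stopifnot(ki > 0)
  # 1 - 1/(1 + exp(-(c - ki))) == plogis(ki - c); stable for large |c - ki|
  stats::plogis(ki - c)
}

#' @rdname rate_laws
#' @export
monod_toxlimit <- function(s, mu_max, ks, ki) {
  monod(s, mu_max, ks) * toxicity_factor(s, ki)
}

#' @rdname rate_laws
#' @export
linear_inhibition <- function(p, mu_max, k) {
  check_conc(p, "product concentration")
  stopifnot(k > 0, mu_max >= 0)
  pmax(0, mu_max * (1 - k * p))
}

#' Combined multiplicative growth model
#'
#' Multiplies the per-compound rate laws selected for an ethanol/acetate chain
#' elongator into one specific growth rate:
#' Monod in acetic acid, toxicity-limit sigmoids in acetic and butyric acid,
#' and linear inhibition by hexanoic acid. Two forms exist:
#'
#' * calibration form (`include_etoh = FALSE`, the default): omits ethanol
#'   terms entirely. All growth-rate datasets used in calibration were
#'   collected at one fixed ethanol concentration (343 mM), so an ethanol
#'   affinity factor would only rescale `mu_max`.
#' * simulation form (`include_etoh = TRUE`): adds a Monod factor in ethanol
#'   with the literature `ks_etoh`. No ethanol toxicity factor is applied
#'   (ethanol inhibition could not be characterised due to well-to-well
#'   ethanol migration in the assay format).
#'
#' @param aa,ba,ha total (acid + anion) concentrations of acetic, butyric and
#'   hexanoic acid, mM. Vectorised.
#' @param params a [kinetic_params()] object.
#' @param etoh ethanol concentration, mM; required when `include_etoh = TRUE`.
#' @param include_etoh include the ethanol Monod affinity factor?
#'
#' @return specific growth rate, h^-1, in `[0, mu_max]`.
#' @examples
#' combined_mu(aa = 80, ba = 0, ha = 0, params = kinetic_params())
#' @export
combined_mu <- function(aa, ba, ha, params, etoh = NULL,
                        include_etoh = FALSE) {
  stopifnot(inherits(params, "kinetic_params"))
  mu <- monod(aa, params$mu_max, params$ks_aa) *
    toxicity_factor(aa, params$ki_aa) *
    toxicity_factor(ba, params$ki_ba) *
    pmax(0, 1 - params$k_ha * ha)
  if (include_etoh) {
    if (is.null(etoh)) stop("etoh required when include_etoh = TRUE",
                            call. = FALSE)
    mu <- mu * monod(etoh, 1, params$ks_etoh)
  }
  mu
}
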