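#' Kinetic parameter set for the combined growth model
#'
#' Container for the parameters of the combined multiplicative growth model of
#' an ethanol/acetate chain elongator. Defaults are the calibrated estimates
#' for *Clostridium kluyveri* grown on ethanol + acetate at 343 mM ethanol:
#' `mu_max` 0.24 h^-1, `ks_aa` 3.8 mM, `ki_ba` 124.7 mM and
#' `k_ha` 1.09e-2 mM^-1, together with the fixed acetic-acid toxicity limit
#' `ki_aa` 330 mM and the literature half-saturation constants for butyrate
#' (`ks_ba` 3.5 mM) and ethanol (`ks_etoh` 11.8 mM) used only by the dynamic
#' simulation model.
#'
#' @param mu_max maximum specific growth rate, h^-1.
#' @param ks_aa half-saturation constant for total acetic acid (acid + anion), mM.
#' @param ki_aa acetic-acid toxicity limit (sigmoid midpoint), mM. Fixed by
#'   default: it acts as a near-threshold and is poorly identifiable from
#'   coarse concentration grids.
#' @param ki_ba butyric-acid toxicity limit, mM.
#' @param k_ha linear inhibition constant for hexanoic acid, mM^-1. Growth
#'   stops completely at `1/k_ha` mM total hexanoic acid.
#' @param ks_ba butyrate half-saturation constant (literature value), mM.
#' @param ks_etoh ethanol half-saturation constant (literature value), mM.
#' @param free character vector naming the parameters that are free during
#'   calibration. The default frees the four parameters estimated from the
#'   growth-rate datasets.
#'
#' @return An object of class `kinetic_params`: a named list of positive
#'   scalars plus a `free` attribute.
#' @examples
#' p <- kinetic_params()
#' p$mu_max
#' @export
kinetic_params <- function(mu_max = 0.24,
                           ks_aa = 3.8,
                           ki_aa = 330,
                           ki_ba = 124.7,
                           k_ha = 10.9e-3,
                           ks_ba = 3.5,
                           ks_etoh = 11.8,
                           free = c("mu_max", "ks_aa", "ki_ba", "k_ha")) {
  p <- list(mu_max = mu_max, ks_aa = ks_aa, ki_aa = ki_aa, ki_ba = ki_ba,
            k_ha = k_ha, ks_ba = ks_ba, ks_etoh = ks_etoh)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("kinetic parameter '", nm, "' must be a single positive number",
           call. = FALSE)
  }
  bad <- setdiff(free, names(p))
  if (length(bad))
    stop("unknown free parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(p, free = free, class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  free <- attr(x, "free")
  cat("Combined-model kinetic parameters\n")
  for (nm in names(x)) {
    tag <- if (nm %in% free) "free" else "fixed"
    cat(sprintf("  %-8s %12.5g  (%s)\n", nm, x[[nm]], tag))
  }
  invisible(x)
}

#' Update parameters in a kinetic_params object
#'
#' @param params a [kinetic_params()] object.
#' @param updates named numeric vector or list of replacement values.
#' @return the updated `kinetic_params` object.
#' @export
update_params <- function(params, updates) {
  stopifnot(inherits(params, "kinetic_params"))
  updates <- as.list(updates)
  args <- utils::modifyList(unclass(params), updates)
  do.call(kinetic_params, c(args, list(free = attr(params, "free"))))
}

#' @export
as.data.frame.kinetic_params <- function(x, ...) {
  data.frame(parameter = names(x),
             value = unlist(x, use.names = FALSE),
             free = names(x) %in% attr(x, "free"))
}
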