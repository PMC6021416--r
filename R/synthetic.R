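#' Noise model for synthetic data
#'
#' Additive Gaussian noise magnitudes for synthetic growth-rate records and
#' optical-density readings. Replicate-to-replicate variance of the original
#' assays is unpublished; the defaults (0.01 h^-1 on mu, 0.005 AU on OD) are
#' assumptions recorded here, not measured quantities.
#'
#' @param mu_sd standard deviation of growth-rate noise, h^-1.
#' @param od_sd standard deviation of OD noise, absorbance units.
#' @param seed optional integer seed; when given, generators are pure
#'   functions of (design, truth, seed).
#' @return an object of class `noise_model`.
#' @export
noise_model <- function(mu_sd = 0.01, od_sd = 0.005, seed = NULL) {
  stopifnot(mu_sd >= 0, od_sd >= 0)
  structure(list(mu_sd = mu_sd, od_sd = od_sd, seed = seed),
            class = "noise_model")
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Registry of the high-throughput experimental designs
#'
#' The nine anaerobic 96-well plate experiments used to characterise the
#' kinetics of an ethanol/acetate chain elongator. Designs A-G vary one
#' compound over a printed concentration range at fixed co-substrate levels
#' (ethanol fixed at 343 mM except in C); H and I are the two
#' product-formation (validation) conditions. The ranges are sampled with
#' `n_levels` uniform levels (the study reports ranges, not level lists).
#' Design C (ethanol inhibition) suffered well-to-well ethanol migration and
#' is excluded from fitting; design D (butyrate without acetate) yielded no
#' growth. Both carry `fit_eligible = FALSE`, as do H and I.
#'
#' @param n_levels number of uniform concentration levels per varied
#'   compound (default 12).
#' @param replicates replicate wells per level (default 3).
#' @return named list of `experiment_design` objects with fields
#'   `experiment_id`, `description`, `fixed` (named mM vector), `varied`
#'   (`NULL` or `list(compound, levels)`), `replicates`, `fit_eligible`.
#' @examples
#' designs <- table2_designs()
#' range(designs$B$varied$levels)  # 0 to 750 mM AA
#' @export
table2_designs <- function(n_levels = 12, replicates = 3) {
  mk <- function(id, description, fixed, varied = NULL,
                 fit_eligible = TRUE) {
    structure(list(experiment_id = id, description = description,
                   fixed = fixed, varied = varied, replicates = replicates,
                   fit_eligible = fit_eligible),
              class = "experiment_design")
  }
  lev <- function(lo, hi) seq(lo, hi, length.out = n_levels)
  list(
    A = mk("A", "low acetic acid",
           c(etoh = 343, aa = NA, ba = 0, ha = 0),
           list(compound = "aa", levels = lev(0, 257))),
    B = mk("B", "high acetic acid",
           c(etoh = 343, aa = NA, ba = 0, ha = 0),
           list(compound = "aa", levels = lev(0, 750))),
    C = mk("C", "ethanol inhibition (excluded: ethanol migration)",
           c(etoh = NA, aa = 60, ba = 0, ha = 0),
           list(compound = "etoh", levels = lev(168, 1764)),
           fit_eligible = FALSE),
    D = mk("D", "butyric acid without acetic acid (no growth)",
           c(etoh = 343, aa = 0, ba = NA, ha = 0),
           list(compound = "ba", levels = lev(0, 113)),
           fit_eligible = FALSE),
    E = mk("E", "butyric acid with 1.6 mM acetic acid",
           c(etoh = 343, aa = 1.6, ba = NA, ha = 0),
           list(compound = "ba", levels = lev(0.4, 128))),
    F = mk("F", "butyric acid with 6 mM acetic acid",
           c(etoh = 343, aa = 6, ba = NA, ha = 0),
           list(compound = "ba", levels = lev(0, 160))),
    G = mk("G", "hexanoic acid inhibition",
           c(etoh = 343, aa = 80, ba = 0, ha = NA),
           list(compound = "ha", levels = lev(5, 184))),
    H = mk("H", "product formation, high acetic acid",
           c(etoh = 343, aa = 80, ba = 1.8, ha = 7.6),
           fit_eligible = FALSE),
    I = mk("I", "product formation, low acetic acid",
           c(etoh = 343, aa = 34, ba = 1.7, ha = 7.4),
           fit_eligible = FALSE))
}

#' @export
print.experiment_design <- function(x, ...) {
  cat(sprintf("Experiment %s: %s\n", x$experiment_id, x$description))
  fx <- x$fixed[!is.na(x$fixed)]
  cat("  fixed:", paste(sprintf("%s=%g mM", names(fx), fx), collapse = ", "),
      "\n")
  if (!is.null(x$varied))
    cat(sprintf("  varied: %s over %g-%g mM (%d levels x %d reps)\n",
                x$varied$compound, min(x$varied$levels),
                max(x$varied$levels), length(x$varied$levels),
                x$replicates))
  invisible(x)
}

design_conditions <- function(design) {
  fx <- design$fixed
  if (is.null(design$varied)) {
    grid <- tibble::tibble(etoh0 = fx[["etoh"]], aa0 = fx[["aa"]],
                           ba0 = fx[["ba"]], ha0 = fx[["ha"]])
    grid$condition_id <- paste0(design$experiment_id, "1")
    return(grid)
  }
  lv <- design$varied$levels
  grid <- tibble::tibble(
    etoh0 = rep(fx[["etoh"]], length(lv)),
    aa0 = rep(fx[["aa"]], length(lv)),
    ba0 = rep(fx[["ba"]], length(lv)),
    ha0 = rep(fx[["ha"]], length(lv)))
  grid[[paste0(design$varied$compound, "0")]] <- lv
  grid$condition_id <- sprintf("%s%02d", design$experiment_id,
                               seq_along(lv))
  grid
}

#' Generate a synthetic growth-rate dataset for one design
#'
#' Stands in for the unfitted raw growth-rate data of a plate experiment:
#' for each concentration level and replicate, the growth rate is the
#' combined-model value (calibration form) at the level's concentrations
#' plus Gaussian noise, truncated at zero. Deterministic given the noise
#' model's seed.
#'
#' @param design an `experiment_design` from [table2_designs()].
#' @param truth a [kinetic_params()] object used as the generating truth.
#' @param noise a [noise_model()].
#' @return a growth-rate dataset tibble (see [validate_growth_dataset()]).
#' @export
synth_mu_dataset <- function(design, truth, noise = noise_model()) {
  stopifnot(inherits(design, "experiment_design"),
            inherits(truth, "kinetic_params"))
  grid <- design_conditions(design)
  reps <- design$replicates
  idx <- rep(seq_len(nrow(grid)), each = reps)
  d <- grid[idx, ]
  d$replicate <- rep(seq_len(reps), times = nrow(grid))
  mu_model <- combined_mu(aa = d$aa0, ba = d$ba0, ha = d$ha0, params = truth)
  mu <- with_seed(noise$seed,
                  pmax(0, mu_model + stats::rnorm(nrow(d), 0, noise$mu_sd)))
  tibble::tibble(
    experiment_id = design$experiment_id,
    etoh0 = d$etoh0, aa0 = d$aa0, ba0 = d$ba0, ha0 = d$ha0,
    mu = mu, replicate = d$replicate,
    well_id = sprintf("syn%s-%s-r%d", design$experiment_id, d$condition_id,
                      d$replicate))
}

#' Generate synthetic growth-rate datasets for the calibration experiments
#'
#' Convenience wrapper producing one pooled dataset over the five designs
#' used for calibration (A, B, E, F, G), each with its own noise draw under
#' a single seed.
#'
#' @inheritParams synth_mu_dataset
#' @param n_levels,replicates forwarded to [table2_designs()].
#' @return pooled growth-rate dataset tibble.
#' @export
synth_calibration_dataset <- function(truth = kinetic_params(),
                                      noise = noise_model(),
                                      n_levels = 12, replicates = 3) {
  designs <- table2_designs(n_levels = n_levels, replicates = replicates)
  ids <- c("A", "B", "E", "F", "G")
  inner_noise <- noise_model(mu_sd = noise$mu_sd, od_sd = noise$od_sd,
                             seed = NULL)
  with_seed(noise$seed, {
    parts <- lapply(ids, function(id)
      synth_mu_dataset(designs[[id]], truth, inner_noise))
    do.call(rbind, parts)
  })
}

#' Generate a synthetic 96-well plate for one design
#'
#' Emulates the anaerobic plate assay: a 0-90 h OD time series at 0.25 h
#' cadence for each sample well, with the outer ring as evaporation buffer
#' and all unused interior wells as uninoculated blanks. Per sample well
#' the blank-corrected signal follows a Richards curve whose growth rate is
#' the combined-model value at that well's condition; the OD is
#' `baseline + dod0 * exp(y(t)) + noise` with `dod0 = dod_max / exp(A)` so
#' the realised dOD saturates near `dod_max`. Blank wells carry baseline +
#' noise only.
#'
#' @param design an `experiment_design` (at most 19 levels with triplicates:
#'   sample wells plus at least 3 blanks must fit the 60 interior wells).
#' @param truth a [kinetic_params()] generating truth.
#' @param curve Richards shape defaults: list with `lag` (h), `capacity`,
#'   `shape`, `baseline` (AU) and `dod_max` (AU).
#' @param noise a [noise_model()].
#' @return list with `plate` (wide OD tibble) and `layout` (annotated plate
#'   layout tibble).
#' @export
synth_plate <- function(design, truth,
                        curve = list(lag = 10, capacity = 2, shape = 1,
                                     baseline = 0.05, dod_max = 0.5),
                        noise = noise_model()) {
  stopifnot(inherits(design, "experiment_design"))
  grid <- design_conditions(design)
  reps <- design$replicates
  n_samples <- nrow(grid) * reps
  layout <- default_plate_layout()
  interior <- which(is.na(layout$role))
  if (n_samples + 3L > length(interior))
    stop("design too large: ", n_samples, " sample wells plus 3 blanks ",
         "exceed the ", length(interior), " interior wells", call. = FALSE)

  layout$experiment_id <- NA_character_
  layout$condition_id <- NA_character_
  layout$etoh0 <- layout$aa0 <- layout$ba0 <- layout$ha0 <- NA_real_
  layout$replicate <- NA_integer_

  sample_idx <- interior[seq_len(n_samples)]
  cond_of <- rep(seq_len(nrow(grid)), each = reps)
  layout$role[sample_idx] <- "sample"
  layout$experiment_id[sample_idx] <- design$experiment_id
  layout$condition_id[sample_idx] <- grid$condition_id[cond_of]
  layout$etoh0[sample_idx] <- grid$etoh0[cond_of]
  layout$aa0[sample_idx] <- grid$aa0[cond_of]
  layout$ba0[sample_idx] <- grid$ba0[cond_of]
  layout$ha0[sample_idx] <- grid$ha0[cond_of]
  layout$replicate[sample_idx] <- rep(seq_len(reps), times = nrow(grid))
  layout$role[interior[-seq_len(n_samples)]] <- "uninoculated_blank"

  t <- seq(0, 90, by = 0.25)
  dod0 <- curve$dod_max / exp(curve$capacity)
  mu_by_cond <- combined_mu(aa = grid$aa0, ba = grid$ba0, ha = grid$ha0,
                            params = truth)
  plate <- with_seed(noise$seed, {
    out <- tibble::tibble(time = t)
    for (i in seq_len(nrow(layout))) {
      w <- layout$well[i]
      role <- layout$role[i]
      if (role == "sample") {
        mu <- mu_by_cond[match(layout$condition_id[i], grid$condition_id)]
        y <- richards_curve(t, mu, curve$lag, curve$capacity, curve$shape)
        out[[w]] <- curve$baseline + dod0 * exp(y) +
          stats::rnorm(length(t), 0, noise$od_sd)
      } else {
        out[[w]] <- curve$baseline + stats::rnorm(length(t), 0, noise$od_sd)
      }
    }
    out
  })
  list(plate = plate, layout = layout)
}

#' Simulate the two product-formation validation scenarios
#'
#' Runs the dynamic mass-balance model for the two tracked conditions —
#' high acetate (308 mM EtOH, 83 mM AA after lag removal) and low acetate
#' (220 mM EtOH, 30 mM AA) — and returns the noiseless trajectories plus a
#' 10-timepoint subsample emulating the destructive well-sampling scheme of
#' the product-formation experiments.
#'
#' @param config a [sim_config()]; defaults use the calibrated parameters
#'   and literature half-saturation constants.
#' @return named list (`high_aa`, `low_aa`); each element holds `initial`,
#'   `trajectory` and `samples` (10 rows of the trajectory).
#' @export
synth_validation_runs <- function(config = sim_config()) {
  scenarios <- list(
    high_aa = sim_state(etoh = 308, aa = 83, ba = 0, ha = 0, x = config$x0),
    low_aa = sim_state(etoh = 220, aa = 30, ba = 0, ha = 0, x = config$x0))
  lapply(scenarios, function(init) {
    traj <- simulate_chain_elongation(init, config)
    keep <- round(seq(1, nrow(traj), length.out = 10))
    list(initial = init, trajectory = traj, samples = traj[keep, ])
  })
}
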