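#' 96-well plate layouts
#'
#' A plate layout is a tibble with one row per well and columns `well`,
#' `row`, `col`, `role` (one of `"sample"`, `"evaporation_buffer"`,
#' `"uninoculated_blank"`), `experiment_id`, `condition_id`,
#' `etoh0`, `aa0`, `ba0`, `ha0` (initial totals, mM) and `replicate`.
#' The default anaerobic assay layout fills the outer ring (rows A and H,
#' columns 1 and 12) with substrate-free medium as an evaporation buffer;
#' only the 60 interior wells carry cultures or blanks.
#'
#' @param n_rows,n_cols plate geometry (default 8 x 12).
#' @return a tibble with `well`, `row`, `col` and `role` columns; interior
#'   wells have role `NA` until assigned by the caller (or by
#'   [synth_plate()]).
#' @export
default_plate_layout <- function(n_rows = 8, n_cols = 12) {
  rows <- LETTERS[seq_len(n_rows)]
  grid <- expand.grid(col = seq_len(n_cols), row = rows,
                      stringsAsFactors = FALSE)
  outer <- grid$row %in% c(rows[1], rows[n_rows]) |
    grid$col %in% c(1L, n_cols)
  tibble::tibble(
    well = paste0(grid$row, grid$col),
    row = grid$row, col = grid$col,
    role = ifelse(outer, "evaporation_buffer", NA_character_))
}

validate_layout <- function(layout) {
  need <- c("well", "role")
  miss <- setdiff(need, names(layout))
  if (length(miss))
    stop("layout is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(layout$well))
    stop("layout contains duplicated well ids", call. = FALSE)
  ok <- layout$role %in% c("sample", "evaporation_buffer",
                           "uninoculated_blank") | is.na(layout$role)
  if (!all(ok))
    stop("unknown layout role(s): ",
         paste(unique(layout$role[!ok]), collapse = ", "), call. = FALSE)
  invisible(layout)
}

#' Read and write wide plate-reader tables
#'
#' Plate-reader exports are delimited text in wide format: column 1 is time
#' (hours or minutes), remaining columns are well ids `A1`..`H12`. Times are
#' converted to hours on ingest; the nominal cadence of the assay is 0.25 h
#' but is not enforced.
#'
#' @param path file path of a delimited text table.
#' @param layout optional plate layout tibble; wells absent from the layout
#'   are rejected.
#' @param time_unit unit of the time column, `"hours"` or `"minutes"`.
#' @param sep field separator (default `","`).
#' @return a tibble with a `time` column (hours) followed by one numeric
#'   column per well.
#' @export
read_plate_table <- function(path, layout = NULL,
                             time_unit = c("hours", "minutes"), sep = ",") {
  time_unit <- match.arg(time_unit)
  if (!file.exists(path)) stop("plate file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("empty or malformed plate table: ", path, call. = FALSE)
  time <- as.numeric(raw[[1]])
  if (any(is.na(time)))
    stop("non-numeric time value at row ", which(is.na(time))[1], call. = FALSE)
  if (any(diff(time) <= 0)) {
    bad <- which(diff(time) <= 0)[1] + 1L
    stop("non-monotonic time at row ", bad, call. = FALSE)
  }
  if (time_unit == "minutes") time <- time / 60
  wells <- names(raw)[-1]
  bad_id <- wells[!grepl("^[A-H](1[0-2]|[1-9])$", wells)]
  if (length(bad_id))
    stop("unknown well id(s): ", paste(bad_id, collapse = ", "), call. = FALSE)
  if (!is.null(layout)) {
    validate_layout(layout)
    extra <- setdiff(wells, layout$well)
    if (length(extra))
      stop("well(s) not present in layout: ", paste(extra, collapse = ", "),
           call. = FALSE)
  }
  out <- tibble::as_tibble(raw)
  names(out)[1] <- "time"
  out$time <- time
  out
}

#' @rdname read_plate_table
#' @param plate a plate tibble as returned by [read_plate_table()] or
#'   [synth_plate()].
#' @export
write_plate_table <- function(plate, path) {
  stopifnot(names(plate)[1] == "time")
  utils::write.csv(plate, path, row.names = FALSE)
  invisible(path)
}

#' Blank-correct a plate
#'
#' Subtracts, at each timepoint, the mean optical density of the
#' uninoculated blank wells from every sample well, yielding the
#' blank-corrected signal dOD. Blank and buffer wells are dropped from the
#' output.
#'
#' @param plate wide plate tibble (`time` + well columns).
#' @param layout plate layout tibble assigning a role to every well.
#' @return wide tibble of dOD with only the sample wells.
#' @export
blank_correct <- function(plate, layout) {
  validate_layout(layout)
  wells <- setdiff(names(plate), "time")
  roles <- layout$role[match(wells, layout$well)]
  blanks <- wells[!is.na(roles) & roles == "uninoculated_blank"]
  samples <- wells[!is.na(roles) & roles == "sample"]
  if (length(blanks) == 0L)
    stop("no uninoculated controls on this plate", call. = FALSE)
  blank_mean <- rowMeans(as.matrix(plate[blanks]))
  out <- plate[c("time", samples)]
  for (w in samples) out[[w]] <- plate[[w]] - blank_mean
  out
}

#' Log-transform a blank-corrected well series
#'
#' Computes `y = ln(dOD / dOD_min)` with `dOD_min` the initial
#' blank-corrected OD of the well — the transform under which the Richards
#' equation is fitted. Non-positive dOD values (possible after blank
#' subtraction of pre-growth noise) are floored at `floor` before the
#' division, so the transform is always defined; `dOD_min` is the floored
#' initial value and `y[1] == 0` by construction. A warning is issued when
#' flooring triggers.
#'
#' @param t time, hours.
#' @param dod blank-corrected OD values of one well.
#' @param floor positive absorbance floor (default 1e-3 AU).
#' @param well_id optional well identifier carried through to the fit.
#' @return an object of class `log_growth`: list with `t`, `y`,
#'   `delta_od_min`, `well_id` and `n_floored`.
#' @export
log_transform <- function(t, dod, floor = 1e-3, well_id = NA_character_) {
  stopifnot(length(t) == length(dod), floor > 0)
  n_floored <- sum(dod < floor)
  if (n_floored > 0L)
    warning(sprintf("%d dOD value(s) below floor %.3g floored%s",
                    n_floored, floor,
                    if (!is.na(well_id)) paste0(" in well ", well_id) else ""),
            call. = FALSE)
  dod_f <- pmax(dod, floor)
  dod_min <- dod_f[1]
  structure(list(well_id = well_id, t = t, y = log(dod_f / dod_min),
                 delta_od_min = dod_min, n_floored = n_floored),
            class = "log_growth")
}

#' Fit growth rates for every sample well of a plate
#'
#' Full per-well pipeline: blank correction, log transform and Richards fit,
#' followed by the join against the layout's condition annotation. Each well
#' is fitted separately; replicate curves are never averaged.
#'
#' @param plate wide plate tibble (raw OD).
#' @param layout plate layout tibble with condition columns (`experiment_id`,
#'   `etoh0`, `aa0`, `ba0`, `ha0`, `replicate`).
#' @param floor dOD floor passed to [log_transform()].
#' @param no_growth_threshold passed to [fit_richards()].
#' @return list with `fits` (tibble of per-well Richards diagnostics) and
#'   `dataset` (growth-rate dataset tibble, see
#'   [build_growth_rate_dataset()]).
#' @export
fit_growth_rates <- function(plate, layout, floor = 1e-3,
                             no_growth_threshold = 0.05) {
  dod <- blank_correct(plate, layout)
  wells <- setdiff(names(dod), "time")
  fits <- lapply(wells, function(w) {
    lg <- suppressWarnings(
      log_transform(dod$time, dod[[w]], floor = floor, well_id = w))
    fit_richards(lg, no_growth_threshold = no_growth_threshold)
  })
  fits_tbl <- tibble::tibble(
    well_id = wells,
    mu = vapply(fits, `[[`, numeric(1), "mu"),
    lag = vapply(fits, `[[`, numeric(1), "lag"),
    capacity = vapply(fits, `[[`, numeric(1), "capacity"),
    shape = vapply(fits, `[[`, numeric(1), "shape"),
    sse = vapply(fits, `[[`, numeric(1), "sse"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    no_growth = vapply(fits, `[[`, logical(1), "no_growth"))
  list(fits = fits_tbl,
       dataset = build_growth_rate_dataset(fits_tbl, layout))
}

#' Assemble a growth-rate dataset from per-well fits
#'
#' Joins per-well Richards fits to the layout's experimental conditions,
#' producing the calibration currency of the package: one record per sample
#' well with the fitted `mu` and the initial total acid concentrations.
#' No-growth wells contribute `mu = 0`.
#'
#' @param fits tibble with at least `well_id` and `mu` columns.
#' @param layout plate layout tibble carrying condition columns.
#' @return a growth-rate dataset tibble with columns `experiment_id`,
#'   `etoh0`, `aa0`, `ba0`, `ha0`, `mu`, `replicate`, `well_id`.
#' @export
build_growth_rate_dataset <- function(fits, layout) {
  validate_layout(layout)
  need <- c("experiment_id", "etoh0", "aa0", "ba0", "ha0", "replicate")
  miss <- setdiff(need, names(layout))
  if (length(miss))
    stop("layout lacks condition column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  idx <- match(fits$well_id, layout$well)
  if (anyNA(idx))
    stop("fitted well(s) missing from layout: ",
         paste(fits$well_id[is.na(idx)], collapse = ", "), call. = FALSE)
  lay <- layout[idx, ]
  keep <- !is.na(lay$role) & lay$role == "sample"
  lay <- lay[keep, ]
  fits <- fits[keep, ]
  if (anyNA(lay$experiment_id) || anyNA(lay$aa0))
    stop("sample well(s) without an experimental condition: ",
         paste(lay$well[is.na(lay$experiment_id) | is.na(lay$aa0)],
               collapse = ", "), call. = FALSE)
  out <- tibble::tibble(
    experiment_id = lay$experiment_id,
    etoh0 = lay$etoh0, aa0 = lay$aa0, ba0 = lay$ba0, ha0 = lay$ha0,
    mu = fits$mu, replicate = lay$replicate, well_id = fits$well_id)
  validate_growth_dataset(out)
}

#' Validate a growth-rate dataset
#'
#' @param data a data frame of growth-rate records.
#' @return the data as a tibble, invisibly checked.
#' @export
validate_growth_dataset <- function(data) {
  need <- c("experiment_id", "etoh0", "aa0", "ba0", "ha0", "mu", "replicate")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("growth-rate dataset is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(data) == 0L)
    stop("growth-rate dataset is empty", call. = FALSE)
  num <- c("etoh0", "aa0", "ba0", "ha0", "mu")
  for (nm in num) {
    if (any(!is.finite(data[[nm]])) || any(data[[nm]] < 0))
      stop("column '", nm, "' must be finite and non-negative", call. = FALSE)
  }
  tibble::as_tibble(data)
}
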