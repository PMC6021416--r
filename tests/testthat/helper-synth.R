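# shared fixtures, built in code

table1_truth <- function() kinetic_params()

# tiny 3-timepoint, 2-well plate written to a temp CSV (times in minutes)
toy_plate_csv <- function(path = tempfile(fileext = ".csv")) {
  utils::write.csv(
    data.frame(time = c(0, 15, 30), B2 = c(0.10, 0.12, 0.15),
               B3 = c(0.05, 0.05, 0.05), check.names = FALSE),
    path, row.names = FALSE)
  path
}

toy_layout <- function() {
  tibble::tibble(
    well = c("B2", "B3"),
    role = c("sample", "uninoculated_blank"),
    experiment_id = c("A", NA), condition_id = c("A01", NA),
    etoh0 = c(343, NA), aa0 = c(80, NA), ba0 = c(0, NA), ha0 = c(0, NA),
    replicate = c(1L, NA))
}

# pure-rate-law synthetic dataset on an arbitrary concentration grid
grid_dataset <- function(compound, s, mu, reps = 1) {
  col <- switch(compound, AA = "aa0", BA = "ba0", HA = "ha0",
                EtOH = "etoh0")
  d <- tibble::tibble(experiment_id = "A", etoh0 = 343, aa0 = 0, ba0 = 0,
                      ha0 = 0)
  d <- d[rep(1, length(s) * reps), ]
  d[[col]] <- rep(s, each = reps)
  d$mu <- rep(mu, each = reps)
  d$replicate <- rep(seq_len(reps), times = length(s))
  d$well_id <- sprintf("w%03d", seq_len(nrow(d)))
  d
}
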