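# shared fixture builders: everything is constructed in code, no stored data
# beyond the packaged assessment-table CSV

table1_path <- function() {
  system.file("extdata", "table1_trap_seasons.csv", package = "lampreysmr")
}

table1_assessment <- function(...) {
  assess_table(read_trap_seasons(table1_path()), ...)
}

# tiny 2-stream, 3-year dataset with 4 observations per stream-year,
# deterministic contents (used by the log-posterior dual oracle)
tiny_recruitment_data <- function() {
  surveys <- expand.grid(site = 1:4, year = 2018:2020,
                         stream = c("A", "B"), stringsAsFactors = FALSE)
  surveys$month <- 6
  surveys$site <- paste0("s", surveys$site)
  # fixed, irregular densities incl. zeros
  surveys$density_per_m2 <- c(0.012, 0, 0.250, 0.031,
                              0.020, 0.100, 0, 0.004,
                              0.300, 0.150, 0.090, 0.010,
                              0.001, 0, 0, 0.055,
                              0.500, 0.020, 0.070, 0.330,
                              0.040, 0.060, 0.008, 0)
  releases <- expand.grid(spawning_year = 2017:2019, stream = c("A", "B"),
                          stringsAsFactors = FALSE)
  releases$sterile_released <- c(0, 1000, 1425, 0, 500, 0)
  recruitment_data(surveys, releases)
}

# matching parameter list for tiny_recruitment_data()
tiny_params <- function() {
  d <- tiny_recruitment_data()
  list(a = c(A = 3.2, B = 2.8),
       a_dev = stats::setNames(c(0.1, -0.4, 0.3, 0.0, 0.25, -0.15),
                               d$groups$group),
       sigma_a = 0.6,
       q = c(A = 0.9, B = 0.4),
       theta = 0.7)
}
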