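# Deterministic toy fixtures used across test files.

toy_centroids <- function() {
  data.frame(
    zip = c("00001", "00002", "00003", "00004", "00005"),
    lat = c(40.0, 40.5, 41.0, 40.2, 40.8),
    lon = c(-74.0, -74.5, -73.5, -74.2, -73.8),
    state = c("SA", "SA", "SB", "SA", "SB"),
    stringsAsFactors = FALSE)
}

toy_hospitals <- function() {
  data.frame(
    hospital_id = c("H1", "H2", "H3"),
    zip = c("00001", "00003", "00005"),
    state = c("SA", "SB", "SB"),
    med_school = c(TRUE, FALSE, TRUE),
    rural = c(FALSE, TRUE, FALSE),
    coc = c(TRUE, TRUE, FALSE),
    centralized = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

toy_patients <- function() {
  data.frame(
    patient_id = sprintf("P%02d", 1:6),
    home_zip = c("00001", "00002", "00002", "00003", "00005", "00004"),
    hospital_id = c("H1", "H1", "H1", "H2", "H3", "H1"),
    state = c("SA", "SA", "SA", "SB", "SB", "SA"),
    age = c(70, 55, 63, 81, 47, 66),
    sex = c("male", "female", "male", "female", "male", "female"),
    race_ethnicity = c("nh_white", "black", "hispanic", "nh_white", "other",
                       "nh_white"),
    rural_urban = c("major_metro", "small_metro", "major_metro",
                    "micropolitan_rural", "major_metro", "small_metro"),
    payer = c("medicare", "private", "medicare", "medicare", "medicaid",
              "other"),
    sdi = c(40, 65, 22, 90, 55, 10),
    died_in_hospital = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# A random market small enough for fast tests but with real structure.
small_config <- function(seed, ...) {
  args <- list(n_zips = 30, n_hospitals = 8, n_patients = 3000,
               n_states = 2, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}

# Independent great-circle oracle: spherical law of cosines, same radius.
oracle_gc_miles <- function(lat1, lon1, lat2, lon2, R = 3958.7613) {
  p <- pi / 180
  c0 <- sin(lat1 * p) * sin(lat2 * p) +
    cos(lat1 * p) * cos(lat2 * p) * cos((lon2 - lon1) * p)
  R * acos(pmin(1, pmax(-1, c0)))
}

# Dummy-variable OLS oracle for the two-way within estimator.
oracle_twoway_slope <- function(y, x, origin, destination) {
  unname(coef(lm(y ~ x + factor(origin) + factor(destination)))["x"])
}

# Random unbalanced origin x destination panel with additive effects.
random_panel <- function(n_origins = 20, n_destinations = 10,
                         fill = 0.6, beta = -1.5) {
  repeat {
    keep <- which(runif(n_origins * n_destinations) < fill)
    o <- ((keep - 1) %% n_origins) + 1
    d <- ((keep - 1) %/% n_origins) + 1
    if (length(unique(o)) == n_origins && length(unique(d)) == n_destinations)
      break
  }
  a <- rnorm(n_origins); b <- rnorm(n_destinations)
  x <- rnorm(length(keep))
  y <- a[o] + b[d] + beta * x + rnorm(length(keep), 0, 0.3)
  data.frame(y = y, x = x, origin = paste0("O", o),
             destination = paste0("D", d))
}
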