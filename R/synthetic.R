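#' Configuration for the synthetic patient-flow generator
#'
#' The generator emulates the statistical structure the gravity analysis
#' assumes: patients distributed over ZIP centroids with heavy-tailed
#' populations, hospitals with heterogeneous latent attractiveness, and
#' hospital choices drawn from an in-state multinomial logit whose
#' utility decays with log distance and rises with log attractiveness.
#' Defaults describe a two-state market of 100 ZIPs, 15 hospitals and
#' 20,000 patients with distance elasticity -1.5 and attractiveness
#' elasticity 1.0.
#'
#' @param n_zips,n_hospitals,n_patients,n_states Market size.
#' @param grid_extent Side length of the square study region, in degrees
#'   (default 6: two state blocks roughly 200 miles across, a plausible
#'   within-state travel scale for large US states).
#' @param theta_distance True distance coefficient in choice utility
#'   (negative in any realistic market).
#' @param theta_volume True coefficient on log latent attractiveness.
#' @param theta_covariates Four true utility contributions of the binary
#'   hospital characteristics (med_school, rural, coc, centralized);
#'   they enter utility through latent attractiveness.
#' @param covariate_prevalences Bernoulli prevalences of the four
#'   characteristics across hospitals.
#' @param population_concentration Dirichlet concentration for ZIP
#'   population weights; values below 1 give the heavy-tailed mix of a
#'   few dense and many sparse ZIPs seen in real geographies.
#' @param attractiveness_dispersion SD of the log-normal base of latent
#'   attractiveness; 1.25 spreads realized hospital volumes over more
#'   than an order of magnitude, as real complex-surgery cohorts show.
#' @param seed Mandatory integer master seed; each generation stage uses
#'   a sub-stream derived from it.
#' @return Validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_zips = 100, n_hospitals = 15,
                             n_patients = 20000, n_states = 2,
                             grid_extent = 6,
                             theta_distance = -1.5, theta_volume = 1.0,
                             theta_covariates = c(med_school = 0.4,
                                                  rural = -0.3,
                                                  coc = 0.3,
                                                  centralized = 0.2),
                             covariate_prevalences = c(med_school = 0.5,
                                                       rural = 0.15,
                                                       coc = 0.6,
                                                       centralized = 0.4),
                             population_concentration = 0.5,
                             attractiveness_dispersion = 1.25,
                             seed) {
  if (missing(seed) || is.null(seed)) stop("a seed is mandatory")
  stopifnot(n_zips >= 1, n_hospitals >= 1, n_patients >= 1, n_states >= 1,
            grid_extent > 0, length(theta_covariates) == 4,
            length(covariate_prevalences) == 4,
            all(covariate_prevalences >= 0 & covariate_prevalences <= 1),
            population_concentration > 0, attractiveness_dispersion >= 0)
  if (n_states > n_zips) stop("n_states cannot exceed n_zips")
  if (n_states > n_hospitals) stop("n_states cannot exceed n_hospitals")
  cfg <- list(n_zips = n_zips, n_hospitals = n_hospitals,
              n_patients = n_patients, n_states = n_states,
              grid_extent = grid_extent,
              theta_distance = theta_distance, theta_volume = theta_volume,
              theta_covariates = stats::setNames(theta_covariates,
                c("med_school", "rural", "coc", "centralized")),
              covariate_prevalences = stats::setNames(covariate_prevalences,
                c("med_school", "rural", "coc", "centralized")),
              population_concentration = population_concentration,
              attractiveness_dispersion = attractiveness_dispersion,
              seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate ZIP-centroid geography with contiguous state blocks
#'
#' ZIP centroids are sampled uniformly on a mid-latitude square of side
#' `grid_extent` degrees; states are contiguous longitude blocks of
#' near-equal ZIP counts. Each ZIP gets a Dirichlet population weight.
#'
#' @param config A [synthetic_config()].
#' @return Data frame `zip, lat, lon, state, pop_weight`.
#' @export
generate_geography <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed + 1L, {
    n <- config$n_zips
    lon <- stats::runif(n, 0, config$grid_extent)
    lat <- 36 + stats::runif(n, 0, config$grid_extent)
    ord <- order(lon)
    sizes <- diff(round(seq(0, n, length.out = config$n_states + 1)))
    state <- character(n)
    state[ord] <- rep(paste0("S", LETTERS[seq_len(config$n_states)]),
                      times = sizes)
    w <- stats::rgamma(n, shape = config$population_concentration)
    w <- w / sum(w)
    data.frame(zip = sprintf("%05d", seq_len(n)), lat = lat, lon = lon,
               state = state, pop_weight = w, stringsAsFactors = FALSE)
  })
}

#' Generate hospitals with latent attractiveness
#'
#' Hospitals are allocated to states in proportion to state population
#' (at least one per state) and placed in population-weighted ZIPs, so
#' hospitals concentrate where patients live. The four binary
#' characteristics are Bernoulli draws at the configured prevalences.
#' Latent log attractiveness is a log-normal base plus the covariate
#' utility contributions, so the characteristics genuinely shift where
#' patients go.
#'
#' @param config A [synthetic_config()].
#' @param geography Output of [generate_geography()].
#' @return Data frame `hospital_id, zip, state, med_school, rural, coc,
#'   centralized, log_attractiveness`.
#' @export
generate_hospitals <- function(config, geography) {
  stopifnot(inherits(config, "synthetic_config"))
  with_local_seed(config$seed + 2L, {
    states <- sort(unique(geography$state))
    pop <- vapply(split(geography$pop_weight, geography$state), sum, 0)[states]
    n_h <- config$n_hospitals
    alloc <- stats::setNames(pmax(1L, floor(n_h * pop / sum(pop))), states)
    while (sum(alloc) < n_h) {
      i <- which.max(pop / alloc)
      alloc[i] <- alloc[i] + 1L
    }
    while (sum(alloc) > n_h) {
      i <- which(alloc > 1)[which.min((pop / alloc)[alloc > 1])]
      alloc[i] <- alloc[i] - 1L
    }
    zips <- unlist(lapply(states, function(st) {
      gz <- geography[geography$state == st, , drop = FALSE]
      gz$zip[sample.int(nrow(gz), alloc[st], replace = TRUE,
                        prob = gz$pop_weight + 1e-12)]
    }))
    x <- vapply(config$covariate_prevalences,
                function(p) stats::rbinom(n_h, 1, p) == 1,
                logical(n_h))
    if (n_h == 1) x <- matrix(x, nrow = 1,
                              dimnames = list(NULL, names(config$covariate_prevalences)))
    base <- stats::rnorm(n_h, 0, config$attractiveness_dispersion)
    log_attr <- base + drop(x %*% config$theta_covariates)
    data.frame(hospital_id = sprintf("H%03d", seq_len(n_h)),
               zip = zips,
               state = geography$state[match(zips, geography$zip)],
               med_school = x[, "med_school"], rural = x[, "rural"],
               coc = x[, "coc"], centralized = x[, "centralized"],
               log_attractiveness = log_attr, stringsAsFactors = FALSE)
  })
}

#' Generate patient records by multinomial-logit hospital choice
#'
#' Home ZIPs are drawn by population weight. Each patient chooses among
#' the hospitals of their own state with log-odds
#' `theta_distance * log d + theta_volume * log A` (the Gumbel-noise
#' random-utility model), where d is the floored centroid distance and
#' log A the latent attractiveness (which carries the covariate
#' contributions). Demographics, payer and deprivation are drawn from
#' fixed marginals typical of an elderly complex-surgery population.
#' In-hospital death is drawn from a logistic model that declines with
#' the chosen hospital's attractiveness, so volume-outcome associations
#' exist in the synthetic data.
#'
#' @param config A [synthetic_config()].
#' @param geography Output of [generate_geography()].
#' @param hospitals Output of [generate_hospitals()].
#' @param floor_miles Distance floor passed to [build_distance_matrix()].
#' @return Patient data frame matching [read_patients()]'s schema.
#' @export
generate_patients <- function(config, geography, hospitals,
                              floor_miles = 0.5) {
  stopifnot(inherits(config, "synthetic_config"))
  states_with_hosp <- unique(hospitals$state)
  if (!all(unique(geography$state) %in% states_with_hosp)) {
    stop("ZIPs in state(s) without any hospital: ",
         paste(setdiff(unique(geography$state), states_with_hosp),
               collapse = ", "))
  }
  distmat <- build_distance_matrix(geography, geography$zip, hospitals,
                                   floor_miles = floor_miles)
  with_local_seed(config$seed + 3L, {
    n <- config$n_patients
    home_idx <- sample.int(nrow(geography), n, replace = TRUE,
                           prob = geography$pop_weight)
    home_zip <- geography$zip[home_idx]
    state <- geography$state[home_idx]

    choice <- character(n)
    for (z in sort(unique(home_zip))) {
      st <- geography$state[match(z, geography$zip)]
      cand <- which(hospitals$state == st)
      u <- config$theta_distance * log(distmat[z, cand]) +
        config$theta_volume * hospitals$log_attractiveness[cand]
      pr <- exp(u - max(u)); pr <- pr / sum(pr)
      rows <- which(home_zip == z)
      pick <- cand[sample.int(length(cand), length(rows), replace = TRUE,
                              prob = pr)]
      choice[rows] <- hospitals$hospital_id[pick]
    }

    draw <- function(levels, probs) {
      levels[sample.int(length(levels), n, replace = TRUE, prob = probs)]
    }
    age <- pmax(19, round(stats::rnorm(n, 65.6, 12.3)))
    sdi <- pmin(100, pmax(0, stats::rnorm(n, 50, 29)))
    la <- hospitals$log_attractiveness[match(choice, hospitals$hospital_id)]
    la_z <- if (stats::sd(la) > 0) (la - mean(la)) / stats::sd(la) else la * 0
    p_die <- stats::plogis(stats::qlogis(0.025) - 0.5 * la_z)

    data.frame(
      patient_id = sprintf("P%06d", seq_len(n)),
      home_zip = home_zip, hospital_id = choice, state = state,
      age = age,
      sex = draw(c("male", "female"), c(0.53, 0.47)),
      race_ethnicity = draw(c("nh_white", "black", "hispanic", "other"),
                            c(0.655, 0.094, 0.129, 0.122)),
      rural_urban = draw(c("major_metro", "small_metro", "micropolitan_rural"),
                         c(0.725, 0.234, 0.041)),
      payer = draw(c("medicare", "medicaid", "private", "other"),
                   c(0.55, 0.102, 0.31, 0.038)),
      sdi = sdi,
      died_in_hospital = stats::runif(n) < p_die,
      stringsAsFactors = FALSE)
  })
}

#' Record of the generator's true parameters
#'
#' @param config A [synthetic_config()].
#' @return Data frame `parameter, value` echoing every configured truth,
#'   plus the generator version.
#' @export
truth_report <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  vals <- c(generator_version = 1,
            n_zips = config$n_zips, n_hospitals = config$n_hospitals,
            n_patients = config$n_patients, n_states = config$n_states,
            grid_extent = config$grid_extent,
            theta_distance = config$theta_distance,
            theta_volume = config$theta_volume,
            stats::setNames(config$theta_covariates,
              paste0("theta_", names(config$theta_covariates))),
            stats::setNames(config$covariate_prevalences,
              paste0("prevalence_", names(config$covariate_prevalences))),
            population_concentration = config$population_concentration,
            attractiveness_dispersion = config$attractiveness_dispersion,
            seed = config$seed)
  data.frame(parameter = names(vals), value = unname(vals),
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic market
#'
#' Runs all generation stages and returns the three input tables the
#' analysis pipeline consumes, plus the truth report.
#'
#' @param config A [synthetic_config()].
#' @param floor_miles Distance floor used during choice generation.
#' @return List `centroids, hospitals, patients, truth, config`.
#' @export
simulate_market <- function(config, floor_miles = 0.5) {
  geo <- generate_geography(config)
  hosp <- generate_hospitals(config, geo)
  pat <- generate_patients(config, geo, hosp, floor_miles = floor_miles)
  list(centroids = geo, hospitals = hosp, patients = pat,
       truth = truth_report(config), config = config)
}
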