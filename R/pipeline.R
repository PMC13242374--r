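#' End-to-end analysis run from input tables to evaluation artifacts
#'
#' Orchestrates ingest, exclusions, volume derivation, distance matrix,
#' flow aggregation, gravity fits (overall and per state), per-spec
#' prediction, and the full evaluation battery. All artifacts are written
#' as plain delimited text, with a manifest recording the configuration,
#' seeds and package version so a rerun with identical inputs reproduces
#' identical outputs.
#'
#' @param config List with elements `patients`, `hospitals`, `centroids`
#'   (input file paths), `out` (output directory), and optionally
#'   `valid_states` (default: all states in the hospital table),
#'   `specs` (default `1:3`), `ks` (default `c(1, 2, 3)`),
#'   `seed` (tie-break seed, default 20160101),
#'   `floor_miles` (default 0.5), `demeaning_tol` (default 1e-10),
#'   `demeaning_max_iter` (default 10000),
#'   `use_residual_effects` (default `FALSE`).
#' @return Invisibly, a list with every computed object (exclusion log,
#'   volumes, flows, fits, predictions, accuracy, sufficiency, travel
#'   bias, subgroup tables, mortality comparison).
#' @export
run_analysis <- function(config) {
  for (p in c("patients", "hospitals", "centroids")) {
    if (is.null(config[[p]])) stop("config is missing input path '", p, "'")
    if (!file.exists(config[[p]])) {
      stop("stage ingest: input file does not exist: ", config[[p]])
    }
  }
  if (is.null(config$out)) stop("config is missing the output directory 'out'")
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  specs <- config$specs %||% 1:3
  ks <- config$ks %||% c(1, 2, 3)
  seed <- config$seed %||% 20160101
  floor_miles <- config$floor_miles %||% 0.5
  tol <- config$demeaning_tol %||% 1e-10
  max_iter <- config$demeaning_max_iter %||% 10000
  use_res <- isTRUE(config$use_residual_effects)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  patients <- stage("ingest", read_patients(config$patients))
  hospitals <- stage("ingest", read_hospitals(config$hospitals))
  centroids <- stage("ingest", read_centroids(config$centroids))
  valid_states <- config$valid_states %||% sort(unique(hospitals$state))

  excl <- stage("exclusions",
                apply_exclusions(patients, hospitals, centroids, valid_states))
  cohort <- excl$included
  if (nrow(cohort) == 0) stop("stage exclusions failed: no patients left")

  volumes <- stage("volume", compute_hospital_volume(cohort))
  hospitals <- hospitals[hospitals$hospital_id %in% names(volumes), ,
                         drop = FALSE]
  hospitals$volume <- volumes[hospitals$hospital_id]

  distmat <- stage("distances",
                   build_distance_matrix(centroids, unique(cohort$home_zip),
                                         hospitals, floor_miles = floor_miles))
  flows <- stage("flows", aggregate_flows(cohort))
  fits <- stage("fit", fit_all(flows, distmat, hospitals, centroids,
                               specs = specs, tol = tol,
                               max_iter = max_iter))

  preds <- list(); acc <- list(); bias <- list(); hits1 <- list()
  for (s in specs) {
    f <- fits[["overall"]][[paste0("spec", s)]]
    pr <- stage("predict",
                predict_topk(f, cohort, hospitals, distmat, k = max(ks),
                             seed = seed, use_residual_effects = use_res))
    preds[[paste0("spec", s)]] <- pr
    a <- stage("evaluate", topk_accuracy(pr, cohort, ks = ks))
    a$model_spec <- s
    acc[[paste0("spec", s)]] <- a
    b <- stage("evaluate", travel_bias(pr, cohort, distmat))
    b$model_spec <- s
    bias[[paste0("spec", s)]] <- b
    hits1[[paste0("spec", s)]] <- hit_at_k(pr, cohort, 1)
  }
  accuracy <- do.call(rbind, acc)
  travel <- do.call(rbind, bias)

  suff <- subgroup <- subgroup_any <- mortality <- NULL
  if (all(c(1, 2, 3) %in% specs)) {
    sf <- classify_sufficiency(hits1$spec1, hits1$spec2, hits1$spec3)
    suff <- data.frame(patient_id = cohort$patient_id,
                       class = as.character(sf$class),
                       model1_sufficient = sf$model1_sufficient,
                       stringsAsFactors = FALSE)
    g23 <- ifelse(sf$model1_sufficient, "model1",
                  ifelse(sf$class == "model2or3_only", "model2or3_only", NA))
    subgroup <- stage("evaluate", subgroup_table(cohort, g23))
    any_correct <- hits1$spec1 | hits1$spec2 | hits1$spec3
    g_any <- ifelse(any_correct, "any_model", "no_model")
    subgroup_any <- stage("evaluate", subgroup_table(cohort, g_any))
    mortality <- stage("evaluate",
                       mortality_comparison(cohort$died_in_hospital, g_any))
  }

  wcsv <- function(x, f) utils::write.csv(x, file.path(out, f),
                                          row.names = FALSE, quote = FALSE)
  wcsv(excl$log, "exclusions.csv")
  wcsv(data.frame(hospital_id = names(volumes), volume = unname(volumes)),
       "volumes.csv")
  write_flows(flows, file.path(out, "flows.csv"))
  wcsv(tidy_fits(fits), "fits.csv")
  for (nm in names(preds)) wcsv(preds[[nm]], paste0("predictions_", nm, ".csv"))
  wcsv(accuracy, "accuracy.csv")
  wcsv(travel, "travel_bias.csv")
  if (!is.null(suff)) {
    wcsv(suff, "sufficiency.csv")
    utils::write.csv(subgroup, file.path(out, "subgroup_m1_vs_m23.csv"),
                     row.names = FALSE)
    utils::write.csv(subgroup_any, file.path(out, "subgroup_any_vs_none.csv"),
                     row.names = FALSE)
    wcsv(mortality, "mortality.csv")
  }
  writeLines(format_accuracy_table(accuracy), file.path(out, "accuracy.txt"))

  manifest <- c(
    sprintf("package_version: %s",
            as.character(utils::packageVersion("hospflow"))),
    sprintf("r_version: %s", R.version.string),
    sprintf("config_hash: %s", config_hash(config)),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("floor_miles: %g", floor_miles),
    sprintf("specs: %s", paste(specs, collapse = ",")),
    sprintf("ks: %s", paste(ks, collapse = ",")),
    sprintf("valid_states: %s", paste(valid_states, collapse = ",")),
    sprintf("use_residual_effects: %s", use_res),
    sprintf("n_floored_distances: %d", attr(distmat, "n_floored")))
  writeLines(manifest, file.path(out, "manifest.txt"))

  invisible(list(exclusion_log = excl$log, cohort = cohort,
                 volumes = volumes, hospitals = hospitals, flows = flows,
                 distmat = distmat, fits = fits, predictions = preds,
                 accuracy = accuracy, travel_bias = travel,
                 sufficiency = suff, subgroup_m1_vs_m23 = subgroup,
                 subgroup_any_vs_none = subgroup_any,
                 mortality = mortality))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Polynomial rolling hash of the deparsed config, for the run manifest.
config_hash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Format an accuracy report as a fixed-width text table
#'
#' One row per model specification, one column block per k, mirroring the
#' usual accuracy-table layout (n and percentage per stratum).
#'
#' @param accuracy Data frame from [run_analysis()]'s accuracy component
#'   (stacked [topk_accuracy()] outputs with a `model_spec` column).
#' @return Character vector of lines.
#' @export
format_accuracy_table <- function(accuracy) {
  lines <- c(sprintf("%-8s %-10s %3s %9s %9s %9s", "model", "stratum", "k",
                     "correct", "total", "pct"))
  for (i in seq_len(nrow(accuracy))) {
    r <- accuracy[i, ]
    lines <- c(lines, sprintf("%-8s %-10s %3d %9d %9d %8.1f%%",
                              paste0("spec", r$model_spec), r$stratum, r$k,
                              r$n_correct, r$n_total, 100 * r$accuracy))
  }
  lines
}

#' Parameter-recovery harness on a synthetic market
#'
#' Simulates a market with known parameters, runs the full pipeline
#' in memory (exclusions, volumes, flows, fits, predictions, accuracy),
#' and tabulates true versus estimated parameters together with the
#' spec-1 versus spec-2 top-1 accuracy comparison.
#'
#' @param syn_config A [synthetic_config()].
#' @param specs Model specifications to fit (default `1:3`).
#' @param ks Ranking depths (default `c(1, 2, 3)`).
#' @param predict_seed Tie-break seed (default derived from the config seed).
#' @return List: `estimates` (parameter, truth, estimate, error),
#'   `accuracy` (per spec and k, overall stratum),
#'   `spec2_minus_spec1` (top-1 accuracy gap, percentage points),
#'   `fits`, `market`.
#' @export
run_end_to_end_recovery <- function(syn_config, specs = 1:3, ks = c(1, 2, 3),
                                    predict_seed = NULL) {
  mkt <- simulate_market(syn_config)
  seed <- predict_seed %||% ((syn_config$seed + 7L) %% 2147483647L)
  excl <- apply_exclusions(mkt$patients, mkt$hospitals, mkt$centroids,
                           sort(unique(mkt$hospitals$state)))
  cohort <- excl$included
  volumes <- compute_hospital_volume(cohort)
  hosp <- mkt$hospitals[mkt$hospitals$hospital_id %in% names(volumes), ,
                        drop = FALSE]
  hosp$volume <- volumes[hosp$hospital_id]
  distmat <- build_distance_matrix(mkt$centroids, unique(cohort$home_zip),
                                   hosp)
  flows <- aggregate_flows(cohort)
  fits <- fit_all(flows, distmat, hosp, mkt$centroids, specs = specs)

  acc <- list()
  for (s in specs) {
    f <- fits[["overall"]][[paste0("spec", s)]]
    pr <- predict_topk(f, cohort, hosp, distmat, k = max(ks), seed = seed)
    a <- topk_accuracy(pr, cohort, ks = ks)
    a$model_spec <- s
    acc[[paste0("spec", s)]] <- a
  }
  accuracy <- do.call(rbind, acc)

  est <- data.frame(parameter = "theta_distance",
                    truth = syn_config$theta_distance,
                    estimate = NA_real_, stringsAsFactors = FALSE)
  ref_spec <- if (2 %in% specs) "spec2" else paste0("spec", specs[1])
  est$estimate <- fits[["overall"]][[ref_spec]]$beta_distance
  if (2 %in% specs) {
    est <- rbind(est, data.frame(parameter = "theta_volume",
                                 truth = syn_config$theta_volume,
                                 estimate = fits[["overall"]]$spec2$beta_log_volume))
  }
  est$error <- est$estimate - est$truth

  gap <- NA_real_
  if (all(c(1, 2) %in% specs)) {
    a1 <- accuracy[accuracy$model_spec == 1 & accuracy$stratum == "overall" &
                     accuracy$k == 1, "accuracy"]
    a2 <- accuracy[accuracy$model_spec == 2 & accuracy$stratum == "overall" &
                     accuracy$k == 1, "accuracy"]
    gap <- 100 * (a2 - a1)
  }

  list(estimates = est, accuracy = accuracy, spec2_minus_spec1 = gap,
       fits = fits, market = mkt)
}
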