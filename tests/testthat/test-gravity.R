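test_that("double-demeaning zeroes an additively separable balanced grid", {
  y <- c(1, 2, 3, 4)  # y = row + col effects exactly
  o <- c("a", "a", "b", "b")
  d <- c("x", "y", "x", "y")
  dd <- double_demean(y, o, d)
  expect_equal(as.vector(dd$values), rep(0, 4), tolerance = 1e-12)
  # reconstruction identity
  rec <- dd$values + dd$origin_means[o, ] + dd$destination_means[d, ]
  expect_equal(as.vector(rec), y, tolerance = 1e-10)
})

test_that("a constant variable demeans to zero and is flagged", {
  o <- rep(c("a", "b", "c"), each = 2)
  d <- rep(c("x", "y"), 3)
  expect_warning(dd <- double_demean(rep(7, 6), o, d), "degenerate")
  expect_equal(as.vector(dd$values), rep(0, 6), tolerance = 1e-12)
})

test_that("within-estimator slope equals dummy-variable OLS on unbalanced panels", {
  set.seed(41)
  for (i in 1:5) {
    p <- random_panel()
    dd <- double_demean(cbind(y = p$y, x = p$x), p$origin, p$destination)
    slope <- sum(dd$values[, "x"] * dd$values[, "y"]) / sum(dd$values[, "x"]^2)
    expect_lt(abs(slope - oracle_twoway_slope(p$y, p$x, p$origin,
                                              p$destination)), 1e-6)
  }
})

test_that("demeaning requires two groups per dimension and reports non-convergence", {
  expect_error(double_demean(1:4, rep("a", 4), c("x", "y", "x", "y")),
               "2 distinct origins")
  set.seed(40)
  p <- random_panel()
  expect_error(double_demean(p$y, p$origin, p$destination, max_iter = 1),
               "converge")
})

test_that("distance elasticity is recovered from self-consistently generated flows", {
  set.seed(42)
  n_o <- 40; n_h <- 10
  cen <- data.frame(zip = sprintf("%05d", 1:n_o),
                    lat = runif(n_o, 38, 42), lon = runif(n_o, -78, -74),
                    state = "SA", stringsAsFactors = FALSE)
  hos <- data.frame(hospital_id = paste0("H", 1:n_h),
                    zip = cen$zip[sample(n_o, n_h)],
                    stringsAsFactors = FALSE)
  dm <- build_distance_matrix(cen, cen$zip, hos)
  a <- runif(n_o, 4, 6); b <- runif(n_h, 4, 6)
  tij <- round(exp(outer(a, b, "+") - 1.5 * log(dm)))
  keep <- which(tij >= 1, arr.ind = TRUE)
  fl <- data.frame(origin_zip = cen$zip[keep[, 1]],
                   hospital_id = hos$hospital_id[keep[, 2]],
                   count = tij[keep], stringsAsFactors = FALSE)
  fit <- fit_gravity(fl, dm, hos, model_spec = 1)
  expect_equal(fit$beta_distance, -1.5, tolerance = 0.02)
  expect_true(fit$converged)

  # flows independent of distance: elasticity ~ 0
  tij0 <- round(exp(outer(a, b, "+") - 8))
  keep0 <- which(tij0 >= 1, arr.ind = TRUE)
  fl0 <- data.frame(origin_zip = cen$zip[keep0[, 1]],
                    hospital_id = hos$hospital_id[keep0[, 2]],
                    count = tij0[keep0], stringsAsFactors = FALSE)
  fit0 <- fit_gravity(fl0, dm, hos, model_spec = 1)
  expect_lt(abs(fit0$beta_distance), 0.1)
})

test_that("distance elasticity is invariant to rescaling all distances", {
  set.seed(43)
  mkt <- simulate_market(small_config(43))
  vol <- compute_hospital_volume(mkt$patients)
  hos <- mkt$hospitals
  hos$volume <- vol[hos$hospital_id]
  dm <- build_distance_matrix(mkt$centroids, unique(mkt$patients$home_zip), hos)
  fl <- aggregate_flows(mkt$patients)
  f1 <- fit_gravity(fl, dm, hos, model_spec = 1)
  dm2 <- dm * 3.7
  attr(dm2, "floor_miles") <- attr(dm, "floor_miles") * 3.7
  f2 <- fit_gravity(fl, dm2, hos, model_spec = 1)
  expect_equal(f1$beta_distance, f2$beta_distance, tolerance = 1e-9)
})

test_that("stage 2 recovers volume and covariate effects with orthogonal residuals", {
  set.seed(44)
  cfg <- small_config(44, n_hospitals = 12,
                      covariate_prevalences = c(0.5, 0.5, 0.5, 0.5))
  mkt <- simulate_market(cfg)
  vol <- compute_hospital_volume(mkt$patients)
  hos <- mkt$hospitals
  hos$volume <- vol[hos$hospital_id]
  dm <- build_distance_matrix(mkt$centroids, unique(mkt$patients$home_zip), hos)
  fl <- aggregate_flows(mkt$patients)

  f2 <- fit_gravity(fl, dm, hos, model_spec = 2)
  expect_gt(f2$beta_log_volume, 0)
  f3 <- fit_gravity(fl, dm, hos, model_spec = 3)
  expect_length(f3$gamma, 4)

  # weighted stage-2 residuals orthogonal to the regressors
  hid <- names(f2$destination_effects)
  w <- as.vector(table(factor(fl$hospital_id, levels = hid)))
  r <- f2$stage2_residuals[hid]
  X <- cbind(1, log(hos$volume[match(hid, hos$hospital_id)]))
  expect_lt(max(abs(crossprod(X, w * r))), 1e-8)
})

test_that("degenerate and collinear stage-2 designs are rejected by name", {
  set.seed(45)
  mkt <- simulate_market(small_config(45))
  vol <- compute_hospital_volume(mkt$patients)
  hos <- mkt$hospitals
  hos$volume <- vol[hos$hospital_id]
  dm <- build_distance_matrix(mkt$centroids, unique(mkt$patients$home_zip), hos)
  fl <- aggregate_flows(mkt$patients)

  hos_flat <- hos
  hos_flat$med_school <- FALSE
  hos_flat$rural <- FALSE
  hos_flat$coc <- FALSE
  hos_flat$centralized <- FALSE
  expect_error(fit_gravity(fl, dm, hos_flat, model_spec = 3), "degenerate")

  hos_col <- hos
  hos_col$rural <- hos_col$med_school
  hos_col$coc <- hos_col$centralized
  err <- tryCatch(fit_gravity(fl, dm, hos_col, model_spec = 3),
                  error = function(e) conditionMessage(e))
  expect_match(err, "collinear|degenerate")
})

test_that("stratified fits produce one fit per stratum and spec", {
  set.seed(46)
  cfg <- small_config(46, n_hospitals = 10,
                      covariate_prevalences = c(0.5, 0.5, 0.5, 0.5))
  mkt <- simulate_market(cfg)
  vol <- compute_hospital_volume(mkt$patients)
  hos <- mkt$hospitals
  hos$volume <- vol[hos$hospital_id]
  dm <- build_distance_matrix(mkt$centroids, unique(mkt$patients$home_zip), hos)
  fl <- aggregate_flows(mkt$patients)

  fits <- fit_all(fl, dm, hos, mkt$centroids, specs = 1:2)
  expect_setequal(names(fits), c("overall", "SA", "SB"))
  expect_equal(lengths(fits), c(overall = 2L, SA = 2L, SB = 2L))

  # single-state input: overall fit coincides with that state's fit
  pa <- mkt$patients[mkt$patients$state == "SA", ]
  fla <- aggregate_flows(pa)
  fits_a <- fit_all(fla, dm, hos, mkt$centroids, specs = 1)
  expect_equal(fits_a$overall$spec1$beta_distance,
               fits_a$SA$spec1$beta_distance)
})

test_that("state-stratified fits recover state-specific distance elasticities", {
  cfg_strong <- small_config(47, n_states = 1, n_zips = 40, n_hospitals = 6,
                             n_patients = 8000, theta_distance = -2.5)
  cfg_weak <- small_config(48, n_states = 1, n_zips = 40, n_hospitals = 6,
                           n_patients = 8000, theta_distance = -0.6)
  run_one <- function(cfg) {
    mkt <- simulate_market(cfg)
    vol <- compute_hospital_volume(mkt$patients)
    hos <- mkt$hospitals; hos$volume <- vol[hos$hospital_id]
    dm <- build_distance_matrix(mkt$centroids, unique(mkt$patients$home_zip),
                                hos)
    fit_gravity(aggregate_flows(mkt$patients), dm, hos, 1)$beta_distance
  }
  b_strong <- run_one(cfg_strong)
  b_weak <- run_one(cfg_weak)
  expect_lt(b_strong, b_weak)   # steeper truth estimated steeper
  expect_lt(b_weak, 0)
})

test_that("tidy_fits exports one labelled row per coefficient", {
  set.seed(49)
  cfg <- small_config(49, n_hospitals = 12,
                      covariate_prevalences = c(0.5, 0.5, 0.5, 0.5))
  mkt <- simulate_market(cfg)
  vol <- compute_hospital_volume(mkt$patients)
  hos <- mkt$hospitals; hos$volume <- vol[hos$hospital_id]
  dm <- build_distance_matrix(mkt$centroids, unique(mkt$patients$home_zip),
                              hos)
  fl <- aggregate_flows(mkt$patients)
  fits <- list(overall = list(spec1 = fit_gravity(fl, dm, hos, 1),
                              spec2 = fit_gravity(fl, dm, hos, 2),
                              spec3 = fit_gravity(fl, dm, hos, 3)))
  td <- tidy_fits(fits)
  expect_equal(sum(td$stratum == "overall"), 1 + 2 + 6)
  expect_true(all(is.finite(td$estimate)))
})
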