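## Build a prediction table directly from per-patient ranked lists.
pred_from_lists <- function(ids, rankings) {
  do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(patient_id = ids[i], rank = seq_along(rankings[[i]]),
               hospital_id = rankings[[i]], score = 0, probability = 0,
               stringsAsFactors = FALSE)
  }))
}

test_that("accuracy is 1 when predictions equal observations and 0 when absent", {
  pat <- toy_patients()
  perfect <- pred_from_lists(pat$patient_id, as.list(pat$hospital_id))
  acc <- topk_accuracy(perfect, pat, ks = 1)
  expect_true(all(acc$accuracy[acc$n_total > 0] == 1))

  never <- pred_from_lists(pat$patient_id,
                           rep(list(c("HX", "HY", "HZ")), nrow(pat)))
  acc0 <- topk_accuracy(never, pat, ks = c(1, 3))
  expect_true(all(acc0$accuracy[acc0$n_total > 0] == 0))
})

test_that("accuracy fractions match per-patient membership checks", {
  set.seed(61)
  n <- 50
  hosp_ids <- paste0("H", 1:6)
  pat <- toy_patients()[rep(1, n), ]
  pat$patient_id <- sprintf("P%03d", 1:n)
  pat$hospital_id <- sample(hosp_ids, n, TRUE)
  pat$state <- sample(c("SA", "SB"), n, TRUE)
  pat$payer <- sample(c("medicare", "private"), n, TRUE)
  rankings <- replicate(n, sample(hosp_ids, 3), simplify = FALSE)
  pr <- pred_from_lists(pat$patient_id, rankings)

  acc <- topk_accuracy(pr, pat, ks = c(1, 2, 3))
  for (k in 1:3) {
    hit <- vapply(seq_len(n),
                  function(i) pat$hospital_id[i] %in% rankings[[i]][1:k],
                  NA)
    expect_equal(acc$n_correct[acc$stratum == "overall" & acc$k == k],
                 sum(hit))
    for (st in c("SA", "SB")) {
      expect_equal(acc$n_correct[acc$stratum == st & acc$k == k],
                   sum(hit[pat$state == st]))
    }
    expect_equal(acc$n_correct[acc$stratum == "medicare" & acc$k == k],
                 sum(hit[pat$payer == "medicare"]))
  }
  # state strata partition the cohort
  for (k in 1:3) {
    sub <- acc[acc$k == k, ]
    expect_equal(sub$n_correct[sub$stratum == "overall"],
                 sum(sub$n_correct[sub$stratum %in% c("SA", "SB")]))
  }
  # monotone in k
  for (st in unique(acc$stratum)) {
    a <- acc$accuracy[acc$stratum == st][order(acc$k[acc$stratum == st])]
    expect_true(all(diff(a) >= 0))
  }
})

test_that("missing predictions are an error, not a silent drop", {
  pat <- toy_patients()
  pr <- pred_from_lists(pat$patient_id[-1], as.list(pat$hospital_id[-1]))
  expect_error(topk_accuracy(pr, pat, ks = 1), "without predictions")
})

test_that("sufficiency classes match the truth table and partition N", {
  combos <- expand.grid(m1 = c(TRUE, FALSE), m2 = c(TRUE, FALSE),
                        m3 = c(TRUE, FALSE))
  got <- classify_sufficiency(combos$m1, combos$m2, combos$m3)
  want <- character(8)
  for (i in 1:8) {
    want[i] <- with(combos[i, ],
      if (m1 && m2 && m3) "all_correct"
      else if (m1) "model1_not_all"
      else if (m2 || m3) "model2or3_only"
      else "none_correct")
  }
  expect_equal(as.character(got$class), want)
  expect_equal(got$model1_sufficient, combos$m1)
  expect_equal(sum(table(got$class)), 8)

  set.seed(62)
  m <- matrix(runif(3000) < 0.4, ncol = 3)
  cls <- classify_sufficiency(m[, 1], m[, 2], m[, 3])
  expect_equal(sum(table(cls$class)), 1000)
  expect_false(anyNA(cls$class))
})

test_that("travel bias is zero for perfect prediction and matches closed forms", {
  m_cen <- toy_centroids()
  hos <- toy_hospitals()
  dm <- build_distance_matrix(m_cen, m_cen$zip, hos)
  pat <- toy_patients()
  perfect <- pred_from_lists(pat$patient_id, as.list(pat$hospital_id))
  tb <- travel_bias(perfect, pat, dm)
  expect_equal(tb$mean_bias, rep(0, nrow(tb)))
  expect_equal(tb$sd_bias, rep(0, nrow(tb)))
})

test_that("travel bias mean and SD match direct recomputation", {
  set.seed(63)
  mkt <- simulate_market(small_config(63))
  pat <- mkt$patients[1:100, ]
  vol <- compute_hospital_volume(mkt$patients)
  hos <- mkt$hospitals; hos$volume <- vol[hos$hospital_id]
  dm <- build_distance_matrix(mkt$centroids, unique(pat$home_zip), hos)
  pred_h <- vapply(pat$state, function(st) {
    sample(hos$hospital_id[hos$state == st], 1)
  }, "")
  pr <- pred_from_lists(pat$patient_id, as.list(unname(pred_h)))
  tb <- travel_bias(pr, pat, dm)
  diff <- dm[cbind(pat$home_zip, pat$hospital_id)] -
    dm[cbind(pat$home_zip, pred_h)]
  expect_equal(tb$mean_bias[tb$stratum == "overall"], mean(diff))
  expect_equal(tb$sd_bias[tb$stratum == "overall"], sd(diff))
  # two-point closed form: differences +10 and -10
  expect_equal(sd(c(10, -10)), sqrt(200))
})

test_that("identical comparison groups give p-values of 1", {
  pat <- toy_patients()[rep(1:6, 2), ]
  g <- rep(c("g1", "g2"), each = 6)
  tab <- subgroup_table(pat, g, continuous = "age",
                        categorical = c("sex", "payer"))
  expect_true(all(abs(tab$p_value - 1) < 1e-12))
})

test_that("chi-squared matches the closed-form Pearson statistic on a 2x2 table", {
  pat <- toy_patients()[rep(1, 60), ]
  pat$sex <- rep(c("male", "female", "male", "female"), c(20, 10, 10, 20))
  g <- rep(c("g1", "g2"), each = 30)
  tab <- subgroup_table(pat, g, continuous = character(0),
                        categorical = "sex")
  # n(ad-bc)^2 / (row and column margins)
  stat <- 60 * (20 * 20 - 10 * 10)^2 / (30 * 30 * 30 * 30)
  expect_equal(unique(tab$p_value), pchisq(stat, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("a 10-SD group separation in a continuous variable is detected", {
  pat <- toy_patients()[rep(1:6, 10), ]
  g <- rep(c("g1", "g2"), 30)
  pat$age <- rnorm(60, 60, 1) + ifelse(g == "g2", 10, 0)
  tab <- subgroup_table(pat, g, continuous = "age",
                        categorical = character(0))
  expect_lt(tab$p_value, 1e-6)
})

test_that("sparse cells are flagged and empty groups rejected", {
  pat <- toy_patients()[rep(1:6, 3), ]
  pat$race_ethnicity[1] <- "other"
  pat$race_ethnicity[-1] <- "nh_white"
  g <- rep(c("g1", "g2"), 9)
  tab <- suppressWarnings(subgroup_table(pat, g, continuous = character(0),
                                         categorical = "race_ethnicity"))
  expect_true(any(tab$flag == "expected_count_lt_1"))
  expect_error(subgroup_table(pat, rep("g1", 18)), "2 non-missing levels")
})

test_that("mortality comparison reproduces the two-proportion chi-squared test", {
  set.seed(64)
  died <- runif(200) < 0.1
  g <- rep(c("a", "b"), 100)
  mc <- mortality_comparison(died, g)
  want <- suppressWarnings(chisq.test(table(died, g), correct = FALSE))
  expect_equal(unique(mc$p_value), want$p.value)
  expect_equal(sum(mc$deaths), sum(died))
  expect_equal(mc$mortality, mc$deaths / mc$n)
})
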