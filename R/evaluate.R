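#' Per-patient top-k hit indicators
#'
#' @param predictions Long prediction table from [predict_topk()].
#' @param patients Patient data frame whose `hospital_id` is the observed
#'   hospital; every patient must appear in `predictions`.
#' @param k Ranking depth.
#' @return Logical vector aligned with `patients`: observed hospital among
#'   the top k predicted.
#' @export
hit_at_k <- function(predictions, patients, k) {
  stopifnot(k >= 1)
  sub <- predictions[predictions$rank <= k, , drop = FALSE]
  key <- paste(sub$patient_id, sub$hospital_id)
  covered <- patients$patient_id %in% predictions$patient_id
  if (!all(covered)) {
    stop("patients without predictions: ",
         paste(utils::head(patients$patient_id[!covered], 5), collapse = ", "))
  }
  paste(patients$patient_id, patients$hospital_id) %in% key
}

#' Top-k prediction accuracy by stratum
#'
#' Accuracy is the number of patients whose observed hospital is among
#' the k highest-scoring predicted hospitals, divided by the stratum
#' size. Reported for the pooled cohort, each state, and the
#' Medicare-only subset (whose insurance is presumed accepted by all
#' hospitals, removing one unmodeled constraint on choice).
#'
#' @param predictions Long prediction table from [predict_topk()].
#' @param patients Patient data frame (observed hospital, state, payer).
#' @param ks Ranking depths to evaluate (default `c(1, 2, 3)`).
#' @return Data frame `stratum, k, n_correct, n_total, accuracy`.
#' @export
topk_accuracy <- function(predictions, patients, ks = c(1, 2, 3)) {
  strata <- c(list(overall = rep(TRUE, nrow(patients))),
              lapply(split(seq_len(nrow(patients)), patients$state),
                     function(ix) seq_len(nrow(patients)) %in% ix),
              list(medicare = patients$payer == "medicare"))
  rows <- list()
  for (k in ks) {
    hit <- hit_at_k(predictions, patients, k)
    for (st in names(strata)) {
      sel <- strata[[st]]
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, k = k, n_correct = sum(hit[sel]), n_total = sum(sel),
        accuracy = if (sum(sel)) sum(hit[sel]) / sum(sel) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Model-sufficiency classification per patient
#'
#' Given per-patient correctness under the three model specifications at
#' a fixed k, assigns each patient to exactly one of four exclusive
#' classes, and separately reports the model-1 margin (all patients the
#' distance-alone model classified correctly, regardless of the other
#' models — the two readings of "model 1 sufficient" are kept distinct).
#'
#' @param correct_m1,correct_m2,correct_m3 Logical vectors.
#' @return List with `class` (factor with levels `all_correct`,
#'   `model1_not_all`, `model2or3_only`, `none_correct`) and
#'   `model1_sufficient` (logical margin, identical to `correct_m1`).
#' @export
classify_sufficiency <- function(correct_m1, correct_m2, correct_m3) {
  stopifnot(length(correct_m1) == length(correct_m2),
            length(correct_m2) == length(correct_m3))
  cls <- ifelse(correct_m1 & correct_m2 & correct_m3, "all_correct",
         ifelse(correct_m1, "model1_not_all",
         ifelse(correct_m2 | correct_m3, "model2or3_only", "none_correct")))
  list(class = factor(cls, levels = c("all_correct", "model1_not_all",
                                      "model2or3_only", "none_correct")),
       model1_sufficient = correct_m1)
}

#' Travel-distance bias of top-1 predictions
#'
#' For each patient, the signed difference between observed travel
#' distance (home ZIP to observed hospital) and predicted travel distance
#' (home ZIP to the top predicted hospital). A positive mean says the
#' model underestimates how far patients actually travel.
#'
#' @param predictions Long prediction table; rank-1 rows are used.
#' @param patients Patient data frame.
#' @param distmat Distance matrix covering all patient ZIPs and hospitals.
#' @return Data frame `stratum, n, mean_bias, sd_bias` (miles), pooled and
#'   per state.
#' @export
travel_bias <- function(predictions, patients, distmat) {
  top1 <- predictions[predictions$rank == 1, , drop = FALSE]
  pred_h <- top1$hospital_id[match(patients$patient_id, top1$patient_id)]
  if (anyNA(pred_h)) stop("patients without a top-1 prediction")
  d_obs <- distmat[cbind(patients$home_zip, patients$hospital_id)]
  d_pred <- distmat[cbind(patients$home_zip, pred_h)]
  diff <- d_obs - d_pred
  groups <- c(list(overall = seq_along(diff)),
              split(seq_along(diff), patients$state))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    x <- diff[groups[[g]]]
    data.frame(stratum = g, n = length(x), mean_bias = mean(x),
               sd_bias = if (length(x) > 1) stats::sd(x) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Descriptive two-group comparison table
#'
#' Compares patient characteristics between two groups: continuous
#' variables as mean +/- SD with a Welch two-sample t-test, categorical
#' variables as n (%) per level with a Pearson chi-squared test (no
#' continuity correction). Cells whose expected count falls below 1 get
#' a warning flag.
#'
#' @param patients Patient data frame.
#' @param grouping Factor (or vector) with exactly 2 used levels; `NA`
#'   rows are excluded from the comparison.
#' @param continuous Character vector of numeric column names.
#' @param categorical Character vector of categorical column names.
#' @return Data frame `variable, level, group1, group2, p_value, test, flag`.
#' @export
subgroup_table <- function(patients, grouping,
                           continuous = c("age", "sdi"),
                           categorical = c("sex", "race_ethnicity",
                                           "rural_urban", "payer")) {
  keep <- !is.na(grouping)
  g <- factor(as.character(grouping[keep]))
  if (nlevels(g) != 2) stop("grouping must have exactly 2 non-missing levels")
  dat <- patients[keep, , drop = FALSE]
  n_g <- table(g)
  if (any(n_g == 0)) stop("a comparison group is empty")
  rows <- list()
  fmt <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))

  for (v in continuous) {
    x1 <- dat[[v]][g == levels(g)[1]]
    x2 <- dat[[v]][g == levels(g)[2]]
    p <- if (length(x1) > 1 && length(x2) > 1)
      stats::t.test(x1, x2)$p.value else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = "", group1 = fmt(x1), group2 = fmt(x2),
      p_value = p, test = "welch_t", flag = "", stringsAsFactors = FALSE)
  }
  for (v in categorical) {
    tab <- table(dat[[v]], g)
    flag <- ""
    p <- NA_real_
    if (nrow(tab) > 1) {
      exp_cnt <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(exp_cnt < 1)) flag <- "expected_count_lt_1"
      p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
    }
    for (lv in rownames(tab)) {
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lv,
        group1 = sprintf("%d (%.1f)", tab[lv, 1], 100 * tab[lv, 1] / n_g[1]),
        group2 = sprintf("%d (%.1f)", tab[lv, 2], 100 * tab[lv, 2] / n_g[2]),
        p_value = p, test = "pearson_chisq", flag = flag,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-proportion mortality comparison
#'
#' Compares in-hospital mortality between two patient groups with a
#' Pearson chi-squared test on the 2x2 table (no continuity correction).
#'
#' @param died Logical vector of in-hospital deaths.
#' @param grouping Two-level grouping; `NA` rows excluded.
#' @return Data frame with per-group deaths, rates, and the p-value.
#' @export
mortality_comparison <- function(died, grouping) {
  keep <- !is.na(grouping)
  g <- factor(as.character(grouping[keep]))
  if (nlevels(g) != 2) stop("grouping must have exactly 2 non-missing levels")
  d <- died[keep]
  tab <- table(factor(d, levels = c(FALSE, TRUE)), g)
  p <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  data.frame(group = levels(g),
             n = as.vector(colSums(tab)),
             deaths = as.vector(tab["TRUE", ]),
             mortality = as.vector(tab["TRUE", ] / colSums(tab)),
             p_value = p, stringsAsFactors = FALSE)
}
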