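## Run code with a temporary RNG state so prediction tie-breaking never
## perturbs (or is perturbed by) the caller's random stream.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Linear-predictor scores for one patient's candidate hospitals
#'
#' The score of hospital j for a patient living in ZIP i is the
#' destination-varying part of the fitted model: spec 1 uses
#' beta_d log d_ij; spec 2 adds beta_v log V_j; spec 3 adds the four
#' hospital-characteristic effects. Origin effects are constant within a
#' patient and cannot change the ranking, so they are omitted. With
#' `use_residual_effects = TRUE` the stage-2 residual of the recovered
#' destination effect is added (specs 2-3), which makes the score the full
#' recovered destination effect; by default only the named regressors are
#' used so that the three specifications genuinely differ in what they
#' know about each hospital.
#'
#' @param fit A [fit_gravity()] object.
#' @param patient_zip Single origin ZIP code.
#' @param hospitals Candidate hospital data frame (with `volume` and, for
#'   spec 3, the four characteristic columns).
#' @param distmat Distance matrix containing `patient_zip`'s row.
#' @param use_residual_effects Add stage-2 residual destination effects.
#' @return Named numeric vector of scores, one per candidate hospital.
#' @export
score_pairs <- function(fit, patient_zip, hospitals, distmat,
                        use_residual_effects = FALSE) {
  hid <- as.character(hospitals$hospital_id)
  d <- distmat[patient_zip, hid]
  if (anyNA(d)) stop("missing distances for patient ZIP ", patient_zip)
  s <- fit$beta_distance * log(d)
  if (fit$model_spec >= 2) {
    s <- s + fit$beta_log_volume * log(hospitals$volume)
  }
  if (fit$model_spec == 3) {
    X <- as.matrix(hospitals[, names(fit$gamma)]) * 1
    s <- s + drop(X %*% fit$gamma)
  }
  if (use_residual_effects && fit$model_spec >= 2) {
    r <- fit$stage2_residuals[hid]
    if (anyNA(r)) {
      warning("hospitals without a recovered destination effect scored without residual: ",
              paste(hid[is.na(r)], collapse = ", "))
      r[is.na(r)] <- 0
    }
    s <- s + r
  }
  stats::setNames(as.numeric(s), hid)
}

#' Choice probabilities from scores
#'
#' Softmax over the candidate set: exp(score - max score), normalized.
#' Any strictly monotone transform leaves the ranking (and thus accuracy)
#' unchanged; softmax gives a proper probability vector over the
#' candidates.
#'
#' @param scores Named numeric vector of finite scores.
#' @return Probabilities summing to 1, in the same order.
#' @export
softmax_probabilities <- function(scores) {
  if (length(scores) == 0) stop("empty score set")
  if (any(!is.finite(scores))) stop("scores must be finite")
  e <- exp(scores - max(scores))
  e / sum(e)
}

#' Rank hospitals by score with seeded random tie-breaking
#'
#' Descending by score; hospitals with exactly equal scores are ordered by
#' a uniform random permutation drawn from a generator seeded with `seed`,
#' so the ranking is reproducible. With all-distinct scores the result is
#' the plain argsort.
#'
#' @param scores Named numeric vector.
#' @param seed Integer tie-breaking seed.
#' @return List: `ranking` (hospital ids, best first), `tie_groups`
#'   (list of id sets with equal scores, only groups of size > 1), `seed`.
#' @export
rank_hospitals <- function(scores, seed = 20160101) {
  stopifnot(all(is.finite(scores)))
  key <- with_local_seed(seed, stats::runif(length(scores)))
  ord <- order(-scores, key)
  ranking <- names(scores)[ord]
  dup <- duplicated(scores) | duplicated(scores, fromLast = TRUE)
  tie_groups <- if (any(dup)) {
    unname(split(names(scores)[dup], match(scores[dup], scores)))
  } else list()
  list(ranking = ranking, tie_groups = tie_groups, seed = seed)
}

#' Top-k predicted hospitals for every patient
#'
#' Scores all candidate hospitals for each patient under a fitted model,
#' converts scores to softmax probabilities, ranks with seeded
#' tie-breaking, and keeps the top k. The candidate set for each patient
#' is every cohort hospital in the patient's state (choices never cross
#' state lines in the data the model is fit to). Tie-break draws come
#' from one stream seeded per patient (derived from `seed` and the
#' patient's position), so changing `k` or the set of patients scored
#' earlier never perturbs another patient's ranking.
#'
#' @param fit A [fit_gravity()] object.
#' @param patients Included patient data frame.
#' @param hospitals Hospital data frame with `state` and `volume`.
#' @param distmat Distance matrix covering all patient ZIPs and hospitals.
#' @param k Number of ranked hospitals to keep per patient (default 3).
#' @param seed Master tie-breaking seed (default 20160101, always recorded).
#' @param use_residual_effects See [score_pairs()].
#' @return Data frame `patient_id, rank, hospital_id, score, probability`
#'   with attribute `seed`. Rows are ordered by patient then rank.
#' @export
predict_topk <- function(fit, patients, hospitals, distmat, k = 3,
                         seed = 20160101, use_residual_effects = FALSE) {
  stopifnot(k >= 1)
  hospitals <- hospitals[order(hospitals$hospital_id), , drop = FALSE]
  by_state <- split(seq_len(nrow(hospitals)), hospitals$state)
  used <- intersect(names(by_state), unique(patients$state))
  if (length(used) && k > min(lengths(by_state[used]))) {
    warning("k exceeds the number of candidate hospitals in some state; rankings truncated")
  }

  ## scores are identical for all patients sharing (home ZIP, state):
  ## compute once per key, re-break ties per patient only where ties exist
  zkey <- paste(patients$home_zip, patients$state)
  keys <- unique(zkey)
  cache <- vector("list", length(keys))
  names(cache) <- keys
  for (kx in keys) {
    i <- match(kx, zkey)
    st <- patients$state[i]
    cand <- hospitals[by_state[[st]], , drop = FALSE]
    if (is.null(cand) || nrow(cand) == 0) {
      stop("no candidate hospitals in state ", st)
    }
    s <- score_pairs(fit, patients$home_zip[i], cand, distmat,
                     use_residual_effects)
    p <- softmax_probabilities(s)
    has_tie <- anyDuplicated(s) > 0
    kk <- min(as.integer(k), length(s))
    top <- if (has_tie) NULL else names(s)[order(-s)][seq_len(kk)]
    cache[[kx]] <- list(s = s, p = p, kk = kk, has_tie = has_tie, top = top)
  }

  n <- nrow(patients)
  kks <- vapply(cache, `[[`, 0L, "kk")[zkey]
  tot <- sum(kks)
  hosp_col <- character(tot); score_col <- numeric(tot); prob_col <- numeric(tot)
  pos <- cumsum(c(0L, kks[-n]))
  for (i in seq_len(n)) {
    cc <- cache[[zkey[i]]]
    top <- if (cc$has_tie) {
      rank_hospitals(cc$s, seed = (seed + i) %% 2147483647L)$ranking[seq_len(cc$kk)]
    } else cc$top
    at <- pos[i] + seq_len(cc$kk)
    hosp_col[at] <- top
    score_col[at] <- cc$s[top]
    prob_col[at] <- cc$p[top]
  }
  res <- data.frame(patient_id = rep(patients$patient_id, times = kks),
                    rank = sequence(kks), hospital_id = hosp_col,
                    score = score_col, probability = prob_col,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res, seed = seed, model_spec = fit$model_spec)
}
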