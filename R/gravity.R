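#' Two-way within transformation by iterated double-demeaning
#'
#' Alternately subtracts origin-group means and destination-group means
#' from each column of `values` until every group mean is below `tol` in
#' absolute value. On a complete balanced grid a single pass suffices; on
#' unbalanced panels the alternation converges geometrically provided the
#' origin-destination incidence graph is connected. The accumulated
#' subtractions are returned as the recovered per-group means, so
#' `values = demeaned + origin_means[origin] + destination_means[destination]`
#' up to `tol`.
#'
#' @param values Numeric vector or matrix (observations in rows).
#' @param origin,destination Group labels, one per observation.
#' @param tol Convergence tolerance on the largest absolute group mean.
#' @param max_iter Maximum number of alternating passes.
#' @return List with `values` (demeaned, same shape), `origin_means`,
#'   `destination_means` (matrices with one row per group), `iterations`,
#'   and `converged` (always `TRUE`; non-convergence is an error).
#' @export
double_demean <- function(values, origin, destination,
                          tol = 1e-10, max_iter = 10000) {
  v <- as.matrix(values)
  storage.mode(v) <- "double"
  origin <- as.character(origin)
  destination <- as.character(destination)
  stopifnot(length(origin) == nrow(v), length(destination) == nrow(v))
  if (length(unique(origin)) < 2 || length(unique(destination)) < 2) {
    stop("double_demean needs at least 2 distinct origins and 2 distinct destinations")
  }
  const <- apply(v, 2, function(x) max(x) - min(x) == 0)
  if (any(const)) {
    warning("degenerate variable(s) constant within the estimation sample: column ",
            paste(which(const), collapse = ", "), call. = FALSE)
  }

  fo <- factor(origin); fd <- factor(destination)
  n_o <- as.vector(table(fo)); n_d <- as.vector(table(fd))
  alpha <- matrix(0, nlevels(fo), ncol(v),
                  dimnames = list(levels(fo), colnames(v)))
  delta <- matrix(0, nlevels(fd), ncol(v),
                  dimnames = list(levels(fd), colnames(v)))
  io <- as.integer(fo); id <- as.integer(fd)

  iter <- 0L
  repeat {
    iter <- iter + 1L
    mo <- rowsum(v, io, reorder = TRUE) / n_o
    v <- v - mo[io, , drop = FALSE]
    alpha <- alpha + mo
    md <- rowsum(v, id, reorder = TRUE) / n_d
    v <- v - md[id, , drop = FALSE]
    delta <- delta + md
    mo2 <- rowsum(v, io, reorder = TRUE) / n_o
    if (max(abs(mo2), abs(md)) < tol) break
    if (iter >= max_iter) {
      stop(sprintf(
        "double-demeaning did not converge in %d iterations (largest group mean %.3e); is the origin-destination graph connected?",
        max_iter, max(abs(mo2), abs(md))))
    }
  }
  list(values = v, origin_means = alpha, destination_means = delta,
       iterations = iter, converged = TRUE)
}

## Decompose r_ij into additive origin + destination effects by alternating
## group means (origin first, so the overall level lands in the origin
## effects). Used to recover fixed effects after the slope is estimated.
additive_decompose <- function(r, origin, destination, tol = 1e-10,
                               max_iter = 10000) {
  dd <- double_demean(r, origin, destination, tol = tol, max_iter = max_iter)
  list(origin_effects = drop(dd$origin_means),
       destination_effects = drop(dd$destination_means),
       residual = drop(dd$values), iterations = dd$iterations)
}

#' Fit one gravity-model specification to a flow table
#'
#' Two-stage estimation. Stage 1 regresses log T_ij on log d_ij after
#' double-demeaning both over origins and destinations, giving the
#' distance elasticity free of origin and destination fixed effects; the
#' destination effects delta_j are then recovered from the residual
#' log T_ij - beta_d log d_ij by additive decomposition. Stage 2 (model
#' specs 2 and 3 only) regresses delta_j on log hospital volume (spec 2)
#' or on log volume plus the four binary hospital characteristics
#' (spec 3) by least squares weighted by each destination's number of
#' positive-flow cells. Destination-invariant regressors cannot survive
#' destination demeaning, so this decomposition is how volume and
#' hospital-characteristic elasticities are identified.
#'
#' @param flows Flow table from [aggregate_flows()] (positive counts only).
#' @param distmat Distance matrix from [build_distance_matrix()].
#' @param hospitals Hospital data frame with `hospital_id`, `volume`, and
#'   for spec 3 the logical columns `med_school`, `rural`, `coc`,
#'   `centralized`.
#' @param model_spec 1 (distance only), 2 (+ log volume), or
#'   3 (+ log volume + four hospital characteristics).
#' @param tol,max_iter Demeaning convergence controls.
#' @return Object of class `gravity_fit`: coefficients, recovered fixed
#'   effects, stage-2 residuals, and fit diagnostics.
#' @export
fit_gravity <- function(flows, distmat, hospitals, model_spec = 2,
                        tol = 1e-10, max_iter = 10000) {
  stopifnot(model_spec %in% 1:3, nrow(flows) > 0)
  if (any(flows$count < 1)) stop("flow table must contain positive counts only")
  d <- distmat[cbind(flows$origin_zip, flows$hospital_id)]
  if (anyNA(d)) stop("distance matrix is missing entries for some flows")
  y <- log(flows$count)
  x <- log(d)

  dd <- double_demean(cbind(y = y, x = x), flows$origin_zip,
                      flows$hospital_id, tol = tol, max_iter = max_iter)
  yd <- dd$values[, "y"]; xd <- dd$values[, "x"]
  sxx <- sum(xd^2)
  if (sxx < 1e-12) stop("log distance has no within variation; cannot identify the distance elasticity")
  beta_d <- sum(xd * yd) / sxx
  res1 <- yd - beta_d * xd
  n_o <- length(unique(flows$origin_zip))
  n_h <- length(unique(flows$hospital_id))
  df1 <- max(1L, nrow(flows) - n_o - n_h)
  sigma1 <- sqrt(sum(res1^2) / df1)
  beta_d_se <- sigma1 / sqrt(sxx)

  fe <- additive_decompose(y - beta_d * x, flows$origin_zip,
                           flows$hospital_id, tol = tol, max_iter = max_iter)
  delta <- fe$destination_effects

  beta_v <- NULL; beta_v_se <- NULL
  gamma <- NULL; gamma_se <- NULL
  stage2_residuals <- NULL
  if (model_spec >= 2) {
    hid <- names(delta)
    hrow <- match(hid, hospitals$hospital_id)
    if (anyNA(hrow)) {
      stop("hospitals absent from the attribute table: ",
           paste(hid[is.na(hrow)], collapse = ", "))
    }
    vol <- hospitals$volume[hrow]
    if (any(!is.finite(vol)) || any(vol < 1)) {
      stop("every destination needs a volume >= 1 for the log-volume regressor")
    }
    X <- cbind(`(Intercept)` = 1, log_volume = log(vol))
    if (model_spec == 3) {
      covs <- as.matrix(hospitals[hrow, c("med_school", "rural", "coc",
                                          "centralized")]) * 1
      const <- apply(covs, 2, function(z) max(z) - min(z) == 0)
      if (any(const)) {
        stop("degenerate covariates (constant across hospitals): ",
             paste(colnames(covs)[const], collapse = ", "))
      }
      X <- cbind(X, covs)
    }
    if (length(delta) < ncol(X)) {
      stop(sprintf("stage 2 needs at least %d destinations, got %d",
                   ncol(X), length(delta)))
    }
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      stop("collinear stage-2 regressors: ",
           paste(colnames(X)[qx$pivot[seq_len(ncol(X)) > qx$rank]],
                 collapse = ", "))
    }
    w <- as.vector(table(factor(flows$hospital_id, levels = hid)))
    fit2 <- stats::lm.wfit(X, delta, w)
    cf <- fit2$coefficients
    r2 <- fit2$residuals
    df2 <- max(1L, length(delta) - ncol(X))
    sigma2sq <- sum(w * r2^2) / df2
    XtWX_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
    ses <- sqrt(diag(XtWX_inv) * sigma2sq)
    names(ses) <- colnames(X)
    beta_v <- unname(cf["log_volume"]); beta_v_se <- unname(ses["log_volume"])
    if (model_spec == 3) {
      gamma <- cf[c("med_school", "rural", "coc", "centralized")]
      gamma_se <- ses[c("med_school", "rural", "coc", "centralized")]
    }
    stage2_residuals <- stats::setNames(r2, hid)
  }

  structure(list(
    model_spec = model_spec,
    beta_distance = beta_d, beta_distance_se = beta_d_se,
    beta_log_volume = beta_v, beta_log_volume_se = beta_v_se,
    gamma = gamma, gamma_se = gamma_se,
    origin_effects = fe$origin_effects,
    destination_effects = delta,
    stage2_residuals = stage2_residuals,
    n_obs = nrow(flows), n_origins = n_o, n_destinations = n_h,
    residual_sd = sigma1,
    demeaning_iterations = dd$iterations,
    converged = TRUE
  ), class = "gravity_fit")
}

#' @export
print.gravity_fit <- function(x, ...) {
  cat(sprintf("Gravity model spec %d: %d flows, %d origins, %d destinations\n",
              x$model_spec, x$n_obs, x$n_origins, x$n_destinations))
  cat(sprintf("  distance elasticity  %8.4f (se %.4f)\n",
              x$beta_distance, x$beta_distance_se))
  if (!is.null(x$beta_log_volume)) {
    cat(sprintf("  log-volume elasticity %7.4f (se %.4f)\n",
                x$beta_log_volume, x$beta_log_volume_se))
  }
  if (!is.null(x$gamma)) {
    for (nm in names(x$gamma)) {
      cat(sprintf("  %-20s %8.4f (se %.4f)\n", nm, x$gamma[nm], x$gamma_se[nm]))
    }
  }
  invisible(x)
}

#' Fit all model specifications for the pooled cohort and per state
#'
#' Fits each requested specification once on all flows pooled ("overall",
#' shared coefficients across states) and once per state, restricting both
#' origins and hospitals to the state. States with no flows are skipped
#' with a warning.
#'
#' @param flows Flow table.
#' @param distmat Distance matrix covering all flows.
#' @param hospitals Hospital data frame with `state` and `volume`.
#' @param centroids Centroid table giving each origin ZIP's state.
#' @param specs Model specifications to fit (default `1:3`).
#' @param ... Passed to [fit_gravity()].
#' @return Nested list: `fits[[stratum]][[paste0("spec", s)]]`.
#' @export
fit_all <- function(flows, distmat, hospitals, centroids, specs = 1:3, ...) {
  origin_state <- centroids$state[match(flows$origin_zip, centroids$zip)]
  if (anyNA(origin_state)) stop("flow origins missing from centroid table")
  strata <- c("overall", sort(unique(origin_state)))
  out <- list()
  for (st in strata) {
    fl <- if (st == "overall") flows else flows[origin_state == st, , drop = FALSE]
    if (nrow(fl) == 0) {
      warning("stratum '", st, "' has no flows; skipped")
      next
    }
    out[[st]] <- lapply(stats::setNames(specs, paste0("spec", specs)),
                        function(s) {
      tryCatch(fit_gravity(fl, distmat, hospitals, model_spec = s, ...),
               error = function(e) {
                 stop(sprintf("fit failed for stratum '%s', spec %d: %s",
                              st, s, conditionMessage(e)), call. = FALSE)
               })
    })
  }
  out
}

#' Export fitted coefficients as a long table
#'
#' @param fits Nested list from [fit_all()].
#' @return Data frame `stratum, model_spec, parameter, estimate, se`.
#' @export
tidy_fits <- function(fits) {
  rows <- list()
  for (st in names(fits)) {
    for (sp in names(fits[[st]])) {
      f <- fits[[st]][[sp]]
      est <- c(log_distance = f$beta_distance)
      se <- c(log_distance = f$beta_distance_se)
      if (!is.null(f$beta_log_volume)) {
        est <- c(est, log_volume = f$beta_log_volume)
        se <- c(se, log_volume = f$beta_log_volume_se)
      }
      if (!is.null(f$gamma)) {
        est <- c(est, f$gamma)
        se <- c(se, f$gamma_se)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = st, model_spec = f$model_spec, parameter = names(est),
        estimate = unname(est), se = unname(se), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
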