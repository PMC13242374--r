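#' Aggregate patients into origin-destination flow counts
#'
#' Builds the flow table T_ij: the number of cohort patients living in ZIP
#' code i who were treated at hospital j. Only observed (positive) flows
#' are stored; the log-linear gravity model is defined on positive flows
#' only, while prediction later scores every patient-hospital pair.
#'
#' @param included Included patient data frame (post-exclusion).
#' @return Data frame with columns `origin_zip`, `hospital_id`, `count`;
#'   counts sum to `nrow(included)`.
#' @export
aggregate_flows <- function(included) {
  if (nrow(included) == 0) stop("empty cohort: no flows to aggregate")
  key <- paste(included$home_zip, included$hospital_id, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(origin_zip = vapply(parts, `[`, "", 1L),
                    hospital_id = vapply(parts, `[`, "", 2L),
                    count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(out$origin_zip, out$hospital_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read a flow table as delimited text
#'
#' @param flows Flow table from [aggregate_flows()].
#' @param path File path.
#' @export
write_flows <- function(flows, path) {
  utils::write.csv(flows, path, row.names = FALSE, quote = FALSE)
}

#' @rdname write_flows
#' @export
read_flows <- function(path) {
  x <- utils::read.csv(path, colClasses = c(origin_zip = "character",
                                            hospital_id = "character"))
  x$count <- as.integer(x$count)
  x
}
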