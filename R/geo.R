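#' Great-circle distance between points, in miles
#'
#' Haversine distance on a sphere of radius 3958.7613 miles (mean Earth
#' radius). ZIP-centroid coordinates carry far more positional error than
#' the difference between spherical and ellipsoidal geodesics, so a fixed
#' spherical radius keeps results reproducible.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#'   Vectorized; arguments are recycled to a common length.
#' @return Numeric vector of distances in miles.
#' @examples
#' haversine_miles(40.7128, -74.0060, 42.6526, -73.7562) # NYC to Albany
#' @export
haversine_miles <- function(lat1, lon1, lat2, lon2) {
  check_coords(lat1, "lat1", 90)
  check_coords(lat2, "lat2", 90)
  check_coords(lon1, "lon1", 180)
  check_coords(lon2, "lon2", 180)
  p <- pi / 180
  dlat <- (lat2 - lat1) * p / 2
  dlon <- (lon2 - lon1) * p / 2
  a <- sin(dlat)^2 + cos(lat1 * p) * cos(lat2 * p) * sin(dlon)^2
  2 * EARTH_RADIUS_MILES * asin(pmin(1, sqrt(a)))
}

#' Mean Earth radius in miles used for all geodesic computations
#' @keywords internal
EARTH_RADIUS_MILES <- 3958.7613

check_coords <- function(x, name, limit) {
  if (!is.numeric(x) || anyNA(x) || any(abs(x) > limit)) {
    stop(sprintf("'%s' must be numeric within [-%d, %d] degrees", name, limit, limit),
         call. = FALSE)
  }
  invisible(x)
}

#' Patient-ZIP by hospital distance matrix
#'
#' Computes the geodesic distance from every origin ZIP centroid to every
#' hospital's ZIP centroid. Distances below `floor_miles` (including the
#' zero distance of same-ZIP pairs) are replaced by `floor_miles` so that
#' the log-distance regressor is always defined; intra-ZIP travel is not
#' actually zero.
#'
#' @param centroids Data frame with columns `zip`, `lat`, `lon`
#'   (see [read_centroids()]).
#' @param origin_zips Character vector of origin ZIP codes (deduplicated
#'   internally, order of first appearance kept).
#' @param hospitals Data frame with columns `hospital_id` and `zip`.
#' @param floor_miles Minimum distance in miles (default 0.5).
#' @return Numeric matrix, rows named by origin ZIP and columns by
#'   hospital id, with attributes `floor_miles` and `n_floored` (number of
#'   entries raised to the floor).
#' @export
build_distance_matrix <- function(centroids, origin_zips, hospitals,
                                  floor_miles = 0.5) {
  stopifnot(is.data.frame(centroids), floor_miles > 0)
  origin_zips <- unique(as.character(origin_zips))
  hosp_ids <- as.character(hospitals$hospital_id)
  hosp_zips <- as.character(hospitals$zip)

  idx <- match(origin_zips, centroids$zip)
  hdx <- match(hosp_zips, centroids$zip)
  missing <- c(origin_zips[is.na(idx)], hosp_zips[is.na(hdx)])
  if (length(missing)) {
    stop("ZIP codes absent from the centroid table: ",
         paste(unique(missing), collapse = ", "), call. = FALSE)
  }

  olat <- centroids$lat[idx]; olon <- centroids$lon[idx]
  hlat <- centroids$lat[hdx]; hlon <- centroids$lon[hdx]
  n_o <- length(origin_zips); n_h <- length(hosp_ids)
  d <- haversine_miles(rep(olat, times = n_h), rep(olon, times = n_h),
                       rep(hlat, each = n_o), rep(hlon, each = n_o))
  d <- matrix(d, nrow = n_o, ncol = n_h,
              dimnames = list(origin_zips, hosp_ids))
  n_floored <- sum(d < floor_miles)
  d[d < floor_miles] <- floor_miles
  structure(d, floor_miles = floor_miles, n_floored = n_floored)
}

#' Read a ZIP-centroid table
#'
#' Expects delimited text with header `zip,lat,lon,state`; ZIP codes are
#' read as character so leading zeros survive.
#'
#' @param path File path.
#' @param sep Field separator (default comma).
#' @return Data frame with columns `zip`, `lat`, `lon`, `state`.
#' @export
read_centroids <- function(path, sep = ",") {
  x <- utils::read.table(path, header = TRUE, sep = sep,
                         colClasses = c(zip = "character", state = "character"),
                         stringsAsFactors = FALSE)
  need <- c("zip", "lat", "lon", "state")
  if (!all(need %in% names(x))) {
    stop("centroid table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(x$zip)) stop("duplicate ZIP codes in centroid table")
  check_coords(x$lat, "lat", 90)
  check_coords(x$lon, "lon", 180)
  x[need]
}
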