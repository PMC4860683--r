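#' @importFrom methods new validObject is slot
#' @importFrom stats kmeans ks.test median rgamma runif sd setNames
#' @importFrom utils read.csv read.table write.csv head
NULL

EARTH_RADIUS_KM <- 6371.0

.checkLat <- function(lat) {
  bad <- !is.finite(lat) | lat < -90 | lat > 90
  if (any(bad))
    stop("latitude out of range [-90, 90]: ", paste(lat[bad], collapse = ", "))
  invisible(lat)
}

.checkLon <- function(lon) {
  bad <- !is.finite(lon) | lon <= -180 | lon > 180
  if (any(bad))
    stop("longitude out of range (-180, 180]: ", paste(lon[bad], collapse = ", "))
  invisible(lon)
}

#' Great-circle distance in kilometres
#'
#' Haversine distance on a spherical Earth of radius 6371.0 km. All arguments
#' are recycled to a common length, so the function works on single points as
#' well as vectors of coordinates.
#'
#' @param lat1,lon1 Coordinates of the first point(s), decimal degrees.
#' @param lat2,lon2 Coordinates of the second point(s), decimal degrees.
#' @return Numeric vector of distances in km.
#' @examples
#' geodesicKm(0, 0, 0, 1)   # one degree of longitude at the equator
#' @export
geodesicKm <- function(lat1, lon1, lat2, lon2) {
  .checkLat(c(lat1, lat2)); .checkLon(c(lon1, lon2))
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM * 1000) / 1000
}

## lat/lon (degrees) -> unit-sphere 3-vectors, rows are points
.ll2xyz <- function(lat, lon) {
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
}

.xyz2ll <- function(v) {
  v <- v / sqrt(sum(v^2))
  c(lat = asin(pmin(1, pmax(-1, v[3]))) * 180 / pi,
    lon = atan2(v[2], v[1]) * 180 / pi)
}

## Minimum great-circle distance (km) from a point to the arc a--b.
## Exact segment geometry on the sphere: distance to the great circle through
## a and b when the perpendicular foot falls inside the arc, otherwise the
## nearer endpoint.
.arcDistKm <- function(p, a, b) {
  axb <- c(a[2] * b[3] - a[3] * b[2],
           a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1])
  nn <- sqrt(sum(axb^2))
  da <- acos(pmin(1, pmax(-1, sum(p * a))))
  db <- acos(pmin(1, pmax(-1, sum(p * b))))
  if (nn < 1e-12) return(EARTH_RADIUS_KM * min(da, db))  # degenerate segment
  nhat <- axb / nn
  comp <- sum(p * nhat)
  foot <- p - comp * nhat
  fn <- sqrt(sum(foot^2))
  if (fn < 1e-12) return(EARTH_RADIUS_KM * min(da, db))
  foot <- foot / fn
  ab <- acos(pmin(1, pmax(-1, sum(a * b))))
  af <- acos(pmin(1, pmax(-1, sum(a * foot))))
  bf <- acos(pmin(1, pmax(-1, sum(b * foot))))
  if (af + bf <= ab + 1e-9) {
    EARTH_RADIUS_KM * asin(pmin(1, abs(comp)))
  } else {
    EARTH_RADIUS_KM * min(da, db)
  }
}

#' Parse degree-minute coordinate strings
#'
#' Converts strings such as `"40°9'N"` or `"37°39'E"` to decimal
#' degrees (minutes divided by 60; S/W negated). Plain numeric strings pass
#' through unchanged.
#'
#' @param x Character vector of coordinate strings.
#' @return Numeric vector of decimal degrees.
#' @export
parseDMS <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  todo <- which(is.na(out) & !is.na(x))
  for (i in todo) {
    s <- trimws(x[i])
    m <- regmatches(s, regexec(
      "^([0-9]+(?:\\.[0-9]+)?)\\D+?([0-9]+(?:\\.[0-9]+)?)?\\D*?([NSEWnsew])?$",
      s, perl = TRUE))[[1]]
    if (length(m) == 0 || m[2] == "")
      stop("cannot parse coordinate string: ", s)
    deg <- as.numeric(m[2])
    minutes <- if (m[3] != "") as.numeric(m[3]) else 0
    val <- deg + minutes / 60
    if (m[4] %in% c("S", "s", "W", "w")) val <- -val
    out[i] <- val
  }
  out
}

## --- simplex helpers -------------------------------------------------------

.renormRows <- function(Q) Q / rowSums(Q)

## Validate raw proportion rows: non-negative, sums within 1 +/- tol.
## Returns the renormalized matrix; errors name offending rows.
.validateProportions <- function(Q, sumTol = 1e-4, rowLabels = NULL) {
  if (is.null(rowLabels)) rowLabels <- seq_len(nrow(Q))
  neg <- which(apply(Q, 1, function(r) any(r < 0)))
  if (length(neg))
    stop("negative admixture proportion in row(s): ",
         paste(rowLabels[neg], collapse = ", "))
  s <- rowSums(Q)
  bad <- which(abs(s - 1) > sumTol)
  if (length(bad))
    stop("admixture proportions do not sum to 1 (tolerance ", sumTol,
         ") in row(s): ", paste(rowLabels[bad], collapse = ", "))
  .renormRows(Q)
}

## Dirichlet sampler (gamma construction); alpha is a vector of shape
## parameters. Zero shapes yield structural zeros.
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(0, n, k)
  pos <- alpha > 0
  g[, pos] <- matrix(rgamma(n * sum(pos), shape = rep(alpha[pos], each = n)),
                     n, sum(pos))
  .renormRows(g)
}

## Derive independent stream seeds from one master seed (kept below 2^31).
.streamSeed <- function(seed, i) {
  (as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483629
}

## --- polygon helpers -------------------------------------------------------

## ring: numeric matrix, columns lon, lat, closed (first row == last row)
.pointInRing <- function(lat, lon, ring) {
  pracma::inpolygon(lon, lat, ring[, 1], ring[, 2], boundary = TRUE)
}

## polygon: list of rings; first is the outer boundary, the rest are holes
.pointInPolygon <- function(lat, lon, polygon) {
  if (!.pointInRing(lat, lon, polygon[[1]])) return(FALSE)
  if (length(polygon) > 1) {
    for (h in polygon[-1]) {
      if (.pointInRing(lat, lon, h)) return(FALSE)
    }
  }
  TRUE
}

.pointInAnyPolygon <- function(lat, lon, polygons) {
  for (p in polygons) if (.pointInPolygon(lat, lon, p)) return(TRUE)
  FALSE
}
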