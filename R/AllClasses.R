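#' @import methods
#' @importClassesFrom S4Vectors DataFrame
NULL

setClassUnion("DataFrameOrNull", c("DFrame", "NULL"))

#' AdmixtureSet: individuals with admixture proportion vectors
#'
#' Container for a set of individuals, each carrying a K-component admixture
#' proportion vector (a point on the simplex) plus per-sample metadata:
#' population label, optional cohort label and optional geographic origin.
#' Rows of the proportion matrix are renormalized to sum exactly to 1 at
#' construction.
#'
#' @slot proportions Numeric matrix, samples x K; rownames are sample IDs,
#'   colnames are component names.
#' @slot info `S4Vectors::DataFrame` with columns `population`, `cohort`,
#'   `lat`, `lon` (NA allowed except `population`), one row per sample.
#' @export
setClass("AdmixtureSet",
         representation(proportions = "matrix", info = "DFrame"))

setValidity("AdmixtureSet", function(object) {
  Q <- object@proportions
  info <- object@info
  msg <- character()
  if (nrow(Q) > 0 && is.null(rownames(Q)))
    msg <- c(msg, "proportions must have sample IDs as rownames")
  else if (anyDuplicated(rownames(Q))) msg <- c(msg, "sample IDs must be unique")
  if (nrow(info) != nrow(Q)) msg <- c(msg, "info must have one row per sample")
  if (!all(c("population", "cohort", "lat", "lon") %in% colnames(info)))
    msg <- c(msg, "info must have columns population, cohort, lat, lon")
  if (nrow(Q) > 0) {
    if (any(Q < 0)) msg <- c(msg, "proportions must be non-negative")
    if (any(abs(rowSums(Q) - 1) > 1e-6))
      msg <- c(msg, "proportion rows must sum to 1 (renormalized at construction)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AdmixtureSet
#'
#' @param proportions Numeric matrix (samples x K) of raw admixture
#'   proportions. Row sums must lie within `1 +/- sumTol`; rows are then
#'   renormalized to sum exactly to 1.
#' @param sampleID Character vector of unique sample IDs (defaults to
#'   rownames of `proportions`).
#' @param population Character vector of population labels (recycled).
#' @param cohort Optional character vector of cohort labels.
#' @param lat,lon Optional numeric vectors with the geographic origin of each
#'   sample, decimal degrees.
#' @param sumTol Tolerance on raw row sums (default 1e-4, absorbing printed
#'   rounding in upstream admixture output without masking corrupt rows).
#' @return An [AdmixtureSet-class] object.
#' @export
AdmixtureSet <- function(proportions, sampleID = rownames(proportions),
                         population = NA_character_, cohort = NA_character_,
                         lat = NA_real_, lon = NA_real_, sumTol = 1e-4) {
  proportions <- as.matrix(proportions)
  storage.mode(proportions) <- "double"
  n <- nrow(proportions)
  if (is.null(sampleID)) sampleID <- sprintf("sample%04d", seq_len(n))
  rownames(proportions) <- as.character(sampleID)
  if (is.null(colnames(proportions)))
    colnames(proportions) <- paste0("C", seq_len(ncol(proportions)))
  if (n > 0)
    proportions <- .validateProportions(proportions, sumTol, rowLabels = sampleID)
  okLat <- !is.na(lat); okLon <- !is.na(lon)
  if (any(okLat)) .checkLat(lat[okLat])
  if (any(okLon)) .checkLon(lon[okLon])
  info <- S4Vectors::DataFrame(
    population = rep_len(as.character(population), n),
    cohort = rep_len(as.character(cohort), n),
    lat = rep_len(as.numeric(lat), n),
    lon = rep_len(as.numeric(lon), n),
    row.names = rownames(proportions))
  new("AdmixtureSet", proportions = proportions, info = info)
}

#' ReferencePanel: reference populations with mean signatures and centroids
#'
#' A set of named reference populations. Each population has a geographic
#' centroid and a mean admixture signature, computed as the renormalized
#' arithmetic mean of its members' vectors.
#'
#' @slot members [AdmixtureSet-class] of all member individuals; the
#'   `population` column assigns members to populations.
#' @slot means Numeric matrix, populations x K, of mean admixture signatures.
#' @slot coords Numeric matrix, populations x 2 (`lat`, `lon`).
#' @export
setClass("ReferencePanel",
         representation(members = "AdmixtureSet", means = "matrix",
                        coords = "matrix"))

setValidity("ReferencePanel", function(object) {
  msg <- character()
  pops <- rownames(object@means)
  if (is.null(pops) || anyDuplicated(pops))
    msg <- c(msg, "population names must be present and unique")
  if (!identical(rownames(object@coords), pops))
    msg <- c(msg, "means and coords must describe the same populations")
  if (ncol(object@coords) != 2)
    msg <- c(msg, "coords must have columns lat, lon")
  if (ncol(object@means) != ncol(object@members@proportions))
    msg <- c(msg, "means and member vectors must share K")
  mpop <- object@members@info$population
  if (!all(mpop %in% pops))
    msg <- c(msg, "every member must belong to a named population")
  if (any(!pops %in% mpop))
    msg <- c(msg, "every population needs at least one member")
  if (length(msg)) msg else TRUE
})

#' Construct a ReferencePanel
#'
#' Groups the members of an [AdmixtureSet-class] by their `population` label,
#' computes each population's mean admixture signature (renormalized
#' arithmetic mean) and attaches geographic centroids.
#'
#' @param members [AdmixtureSet-class] whose `population` column is set.
#' @param coords Optional data frame or matrix with columns
#'   `population`, `lat`, `lon` (coordinates may be degree-minute strings).
#'   When omitted, each population's centroid is the mean of its members'
#'   origin coordinates, which must then be present.
#' @return A [ReferencePanel-class] object.
#' @export
ReferencePanel <- function(members, coords = NULL) {
  stopifnot(is(members, "AdmixtureSet"))
  pop <- members@info$population
  if (anyNA(pop)) stop("all members must carry a population label")
  pops <- unique(pop)
  Q <- members@proportions
  means <- do.call(rbind, lapply(pops, function(p) {
    .renormRows(matrix(colMeans(Q[pop == p, , drop = FALSE]), 1))
  }))
  dimnames(means) <- list(pops, colnames(Q))
  if (is.null(coords)) {
    la <- members@info$lat; lo <- members@info$lon
    if (anyNA(la) || anyNA(lo))
      stop("coords omitted but some members lack origin coordinates")
    cm <- cbind(lat = tapply(la, pop, mean)[pops],
                lon = tapply(lo, pop, mean)[pops])
  } else {
    coords <- as.data.frame(coords)
    if (anyDuplicated(coords$population))
      stop("duplicate population name in coordinates: ",
           paste(unique(coords$population[duplicated(coords$population)]),
                 collapse = ", "))
    missing <- setdiff(pops, coords$population)
    if (length(missing))
      stop("population(s) without coordinates: ", paste(missing, collapse = ", "))
    idx <- match(pops, coords$population)
    cm <- cbind(lat = parseDMS(coords$lat[idx]), lon = parseDMS(coords$lon[idx]))
  }
  rownames(cm) <- pops
  .checkLat(cm[, "lat"]); .checkLon(cm[, "lon"])
  new("ReferencePanel", members = members, means = means, coords = cm)
}

#' RegionSet: named boundary polygons
#'
#' Maps region names to lists of polygons. Each polygon is a list of closed
#' rings (numeric matrices with columns `lon`, `lat`; first ring is the outer
#' boundary, later rings are holes), following GeoJSON semantics.
#'
#' @slot regions Named list: region name -> list of polygons.
#' @export
setClass("RegionSet", representation(regions = "list"))

setValidity("RegionSet", function(object) {
  msg <- character()
  nm <- names(object@regions)
  if (length(object@regions) && (is.null(nm) || any(nm == "") || anyDuplicated(nm)))
    msg <- c(msg, "regions must have unique non-empty names")
  for (r in object@regions) {
    if (!length(r)) { msg <- c(msg, "each region needs at least one polygon"); break }
    for (poly in r) for (ring in poly) {
      if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 4) {
        msg <- c(msg, "rings must be matrices (lon, lat) with >= 4 rows"); break
      }
      if (any(ring[1, ] != ring[nrow(ring), ])) {
        msg <- c(msg, "rings must be closed (first vertex == last vertex)"); break
      }
    }
  }
  if (length(msg)) unique(msg) else TRUE
})

#' @rdname RegionSet-class
#' @param regions Named list of polygons (see class description); a bare ring
#'   matrix or a single polygon is promoted to the nested form.
#' @return A [RegionSet-class] object.
#' @export
RegionSet <- function(regions) {
  regions <- lapply(regions, function(r) {
    if (is.matrix(r)) r <- list(list(r))                 # bare ring
    else if (is.matrix(r[[1]])) r <- list(r)             # single polygon
    lapply(r, function(poly) lapply(poly, function(ring) {
      ring <- as.matrix(ring)
      colnames(ring) <- c("lon", "lat")
      if (any(ring[1, ] != ring[nrow(ring), ])) ring <- rbind(ring, ring[1, ])
      ring
    }))
  })
  new("RegionSet", regions = regions)
}

#' HaplogroupTable: cohort-labelled mtDNA / Y haplogroup calls
#'
#' One row per individual: sample ID, mtDNA haplogroup string, optional
#' Y-chromosome haplogroup string (absent for females), cohort label.
#'
#' @slot data `S4Vectors::DataFrame` with columns `sample_id`,
#'   `mt_haplogroup`, `y_haplogroup`, `cohort`.
#' @export
setClass("HaplogroupTable", representation(data = "DFrame"))

setValidity("HaplogroupTable", function(object) {
  d <- object@data
  msg <- character()
  need <- c("sample_id", "mt_haplogroup", "y_haplogroup", "cohort")
  if (!all(need %in% colnames(d)))
    msg <- c(msg, paste("columns required:", paste(need, collapse = ", ")))
  else {
    if (anyDuplicated(d$sample_id)) msg <- c(msg, "sample IDs must be unique")
    mt <- d$mt_haplogroup
    if (any(is.na(mt) | !nzchar(mt)))
      msg <- c(msg, "mt_haplogroup must be non-empty for every row")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname HaplogroupTable-class
#' @param data Data frame with columns `sample_id`, `mt_haplogroup`,
#'   `y_haplogroup` (NA or "" allowed), `cohort`.
#' @return A [HaplogroupTable-class] object.
#' @export
HaplogroupTable <- function(data) {
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"y_haplogroup" %in% colnames(data)) data$y_haplogroup <- NA_character_
  y <- as.character(data$y_haplogroup)
  y[!is.na(y) & !nzchar(trimws(y))] <- NA_character_
  d <- S4Vectors::DataFrame(sample_id = as.character(data$sample_id),
                            mt_haplogroup = trimws(as.character(data$mt_haplogroup)),
                            y_haplogroup = y,
                            cohort = as.character(data$cohort))
  new("HaplogroupTable", data = d)
}

#' AdmixtureField: spatial interpolation of admixture signatures
#'
#' Piecewise-linear interpolant of reference-population admixture signatures
#' over the plate-carree plane (x = longitude, y = latitude): a Delaunay
#' triangulation of the population centroids with per-vertex admixture
#' vectors, interpolated componentwise by barycentric weights.
#'
#' @slot points Numeric matrix, vertices x 2 (`lon`, `lat`).
#' @slot values Numeric matrix, vertices x K, of vertex admixture vectors.
#' @slot triangles Integer matrix, triangles x 3, rows indexing `points`.
#' @slot hull Integer vector: indices of the convex-hull vertices, in order.
#' @export
setClass("AdmixtureField",
         representation(points = "matrix", values = "matrix",
                        triangles = "matrix", hull = "integer"))

#' SyntheticWorld: generative model for spatially structured admixture
#'
#' Defines K ancestral sources on the map, each with an exponential
#' distance-decay length; the expected admixture vector at any point is the
#' normalized vector of decays. Population sites sample individuals from a
#' Dirichlet centred on the local expectation.
#'
#' @slot sources Numeric matrix, K x 2 (`lat`, `lon`): ancestral source
#'   locations.
#' @slot lambda Numeric vector of K decay lengths, km.
#' @slot extent Named numeric: `latMin`, `latMax`, `lonMin`, `lonMax`.
#' @slot sites Data frame: `name`, `lat`, `lon`, `n` (samples per site).
#' @slot alpha Dirichlet concentration (total mass multiplying the expected
#'   vector); larger means less within-population noise.
#' @slot seed Master seed; all sampling streams derive from it.
#' @export
setClass("SyntheticWorld",
         representation(sources = "matrix", lambda = "numeric",
                        extent = "numeric", sites = "data.frame",
                        alpha = "numeric", seed = "numeric"))

setValidity("SyntheticWorld", function(object) {
  msg <- character()
  if (nrow(object@sources) < 2) msg <- c(msg, "need K >= 2 sources")
  if (length(object@lambda) != nrow(object@sources) || any(object@lambda <= 0))
    msg <- c(msg, "lambda must be positive, one per source")
  if (object@alpha <= 0) msg <- c(msg, "alpha must be positive")
  e <- object@extent
  if (!all(c("latMin", "latMax", "lonMin", "lonMax") %in% names(e)))
    msg <- c(msg, "extent must name latMin, latMax, lonMin, lonMax")
  else {
    s <- object@sites
    if (any(s$lat < e["latMin"] - 1e-9 | s$lat > e["latMax"] + 1e-9 |
            s$lon < e["lonMin"] - 1e-9 | s$lon > e["lonMax"] + 1e-9))
      msg <- c(msg, "all sites must lie inside the extent")
  }
  if (length(msg)) msg else TRUE
})
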