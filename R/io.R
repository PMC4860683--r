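## File input/output: admixture tables (Q-matrix or CSV), reference-panel
## coordinates, GeoJSON region polygons, haplogroup tables, prediction CSVs.

.META_COLS <- c("sample_id", "population", "cohort", "lat", "lon")

#' Read an admixture proportion table
#'
#' Two layouts are supported. `"csv"`: a header row naming `sample_id`,
#' `population`, the K component columns and optionally `cohort`, `lat`,
#' `lon`. `"qmatrix"`: the whitespace-delimited numeric matrix written by
#' admixture-estimation software (one row per individual, one column per
#' component, no header), with a companion file listing one sample ID per
#' line (`idFile`; optionally a second column with population labels).
#'
#' Every row must be non-negative and sum to 1 within `sumTol`; rows are
#' renormalized to sum exactly to 1. Offending rows are reported by number.
#'
#' @param path Path to the admixture table.
#' @param format `"csv"` or `"qmatrix"`.
#' @param idFile Companion sample-ID file (qmatrix format only).
#' @param sumTol Tolerance on raw row sums.
#' @return An [AdmixtureSet-class]; row order is preserved.
#' @export
readAdmixtureTable <- function(path, format = c("csv", "qmatrix"),
                               idFile = NULL, sumTol = 1e-4) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    if (!"sample_id" %in% colnames(df))
      stop("csv admixture table requires a sample_id column")
    compCols <- setdiff(colnames(df), .META_COLS)
    if (!length(compCols)) stop("no admixture component columns found")
    Q <- as.matrix(df[, compCols, drop = FALSE])
    if (!is.numeric(Q)) stop("component columns must be numeric")
    AdmixtureSet(Q, sampleID = df$sample_id,
                 population = if ("population" %in% colnames(df)) df$population else NA,
                 cohort = if ("cohort" %in% colnames(df)) df$cohort else NA,
                 lat = if ("lat" %in% colnames(df)) parseDMS(df$lat) else NA,
                 lon = if ("lon" %in% colnames(df)) parseDMS(df$lon) else NA,
                 sumTol = sumTol)
  } else {
    Q <- tryCatch(as.matrix(read.table(path, header = FALSE)),
                  error = function(e)
                    stop("cannot parse Q-matrix (inconsistent K across rows?): ",
                         conditionMessage(e)))
    if (!is.numeric(Q)) stop("Q-matrix must be numeric")
    if (is.null(idFile)) stop("qmatrix format requires a companion idFile")
    ids <- read.table(idFile, header = FALSE, stringsAsFactors = FALSE)
    if (nrow(ids) != nrow(Q))
      stop("idFile has ", nrow(ids), " IDs but Q-matrix has ", nrow(Q), " rows")
    colnames(Q) <- paste0("C", seq_len(ncol(Q)))
    AdmixtureSet(Q, sampleID = ids[[1]],
                 population = if (ncol(ids) >= 2) ids[[2]] else NA,
                 sumTol = sumTol)
  }
}

#' Read a reference panel from an admixture table plus a coordinates file
#'
#' The coordinates file is a CSV mapping `population` to `lat`, `lon`
#' (decimal degrees or degree-minute strings). Populations present in the
#' admixture table but absent from the coordinates file are an error.
#'
#' @inheritParams readAdmixtureTable
#' @param coordsPath CSV with columns `population`, `lat`, `lon`.
#' @return A [ReferencePanel-class] with per-population mean signatures.
#' @export
readReferencePanel <- function(path, coordsPath, format = c("csv", "qmatrix"),
                               idFile = NULL, sumTol = 1e-4) {
  members <- readAdmixtureTable(path, format = format, idFile = idFile,
                                sumTol = sumTol)
  coords <- read.csv(coordsPath, stringsAsFactors = FALSE)
  if (!all(c("population", "lat", "lon") %in% colnames(coords)))
    stop("coordinates file must have columns population, lat, lon")
  ReferencePanel(members, coords)
}

#' Read region boundary polygons from GeoJSON
#'
#' Accepts an RFC 7946 FeatureCollection whose features are Polygon or
#' MultiPolygon geometries carrying a `name` property. MultiPolygon parts
#' become several polygons under one region name.
#'
#' @param path Path to a GeoJSON file.
#' @return A [RegionSet-class].
#' @export
readRegions <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  regions <- list()
  for (feat in gj$features) {
    nm <- feat$properties$name
    if (is.null(nm) || !nzchar(nm)) stop("feature without a name property")
    geom <- feat$geometry
    ringMat <- function(ring)
      do.call(rbind, lapply(ring, function(pt) c(lon = pt[[1]], lat = pt[[2]])))
    polys <- switch(geom$type,
      Polygon = list(lapply(geom$coordinates, ringMat)),
      MultiPolygon = lapply(geom$coordinates, function(p) lapply(p, ringMat)),
      stop("unsupported geometry type for region '", nm, "': ", geom$type))
    regions[[nm]] <- c(regions[[nm]], polys)
  }
  RegionSet(regions)
}

#' Write a RegionSet as GeoJSON
#'
#' @param regions A [RegionSet-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRegions <- function(regions, path) {
  stopifnot(is(regions, "RegionSet"))
  feats <- lapply(names(regions@regions), function(nm) {
    polys <- regions@regions[[nm]]
    coords <- lapply(polys, function(poly)
      lapply(poly, function(ring)
        lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))))
    geom <- if (length(coords) == 1)
      list(type = "Polygon", coordinates = coords[[1]])
    else list(type = "MultiPolygon", coordinates = coords)
    list(type = "Feature", properties = list(name = nm), geometry = geom)
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a haplogroup table
#'
#' CSV with columns `sample_id`, `mt_haplogroup`, `y_haplogroup` (may be
#' empty), `cohort`, mirroring the structure of study supplementary tables.
#'
#' @param path Path to the CSV file.
#' @return A [HaplogroupTable-class].
#' @export
readHaplogroupTable <- function(path) {
  HaplogroupTable(read.csv(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", "")))
}

#' Write predicted origins to CSV
#'
#' Columns: `sample_id`, `lat`, `lon` (full precision, so coordinates
#' round-trip to at least 1e-6 degrees), `best_population` and `d_best`, the
#' genetic distance to the best-matching population in percent, 2 decimals.
#'
#' @param predictions Data frame as returned by [predictOrigins()] or
#'   [leaveOneOut()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writePredictions <- function(predictions, path) {
  df <- as.data.frame(predictions)
  out <- data.frame(sample_id = df$sample_id,
                    lat = df$lat, lon = df$lon,
                    best_population = df$best_population,
                    d_best = sprintf("%.2f", 100 * df$d_best))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a predictions CSV written by [writePredictions()]
#'
#' @param path Path to the CSV file.
#' @return Data frame with `d_best` back on the fractional scale.
#' @export
readPredictions <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$d_best <- df$d_best / 100
  df
}
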