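## Geographic origin prediction from admixture signatures, leave-one-out
## evaluation, and accuracy against region boundary polygons.

#' Predict the geographic origin of one admixture vector
#'
#' The query's genetic distance to every reference population's mean
#' signature is computed; the M genetically nearest populations are selected
#' (ties broken by panel order, stable). If the best distance is exactly 0
#' the best population's centroid is returned. Otherwise each selected
#' population i receives weight `(d_1/d_i)^exponent` (normalized to sum 1)
#' and the predicted point is the spherical weighted centroid of the
#' selected population centroids: the weighted mean of their unit-sphere
#' 3-vectors, renormalized and converted back to latitude/longitude. The
#' weighting is scale-free in d, exact at panel vertices, and confines
#' predictions near the best-matching populations.
#'
#' @param query Numeric admixture vector or single-sample
#'   [AdmixtureSet-class].
#' @param panel A [ReferencePanel-class].
#' @param M Number of nearest reference populations used (default 10,
#'   capped at the panel size).
#' @param exponent Weight exponent (default 2, inverse-square relative
#'   weighting).
#' @return List with `lat`, `lon`, `best_population`, and `gen_distances`: a
#'   data frame (`population`, `d`) of the M used populations sorted by
#'   ascending d.
#' @export
predictOrigin <- function(query, panel, M = 10, exponent = 2) {
  stopifnot(is(panel, "ReferencePanel"))
  if (nPopulations(panel) < 1) stop("panel has no populations")
  q <- drop(.asQ(query))
  if (length(q) != nComponents(panel))
    stop("query K (", length(q), ") does not match panel K (",
         nComponents(panel), ")")
  means <- panelMeans(panel)
  d <- sqrt(colSums((t(means) - q)^2))
  M <- min(M, length(d))
  ord <- order(d, seq_along(d))[seq_len(M)]   # stable tie-break by panel order
  dM <- d[ord]
  coords <- panelCoords(panel)[ord, , drop = FALSE]
  gen <- data.frame(population = rownames(means)[ord], d = unname(dM),
                    stringsAsFactors = FALSE)
  if (dM[1] == 0 || M == 1) {
    pt <- c(lat = coords[1, "lat"], lon = coords[1, "lon"])
  } else {
    w <- (dM[1] / dM)^exponent
    w <- w / sum(w)
    v <- colSums(.ll2xyz(coords[, "lat"], coords[, "lon"]) * w)
    pt <- .xyz2ll(v)
  }
  list(lat = unname(pt["lat"]), lon = unname(pt["lon"]),
       best_population = gen$population[1], gen_distances = gen)
}

#' Predict origins for every sample of an AdmixtureSet
#'
#' @param x [AdmixtureSet-class] of query individuals.
#' @param panel A [ReferencePanel-class].
#' @inheritParams predictOrigin
#' @return Data frame with one row per sample: `sample_id`, `lat`, `lon`,
#'   `best_population`, `d_best` (fraction). The per-sample distance tables
#'   are attached as the `genDistances` attribute (a named list).
#' @export
predictOrigins <- function(x, panel, M = 10, exponent = 2) {
  Q <- .asQ(x)
  preds <- lapply(seq_len(nrow(Q)), function(i)
    predictOrigin(Q[i, ], panel, M = M, exponent = exponent))
  out <- data.frame(
    sample_id = rownames(Q),
    lat = vapply(preds, `[[`, numeric(1), "lat"),
    lon = vapply(preds, `[[`, numeric(1), "lon"),
    best_population = vapply(preds, `[[`, character(1), "best_population"),
    d_best = vapply(preds, function(p) p$gen_distances$d[1], numeric(1)),
    stringsAsFactors = FALSE)
  if (is(x, "AdmixtureSet")) out$population <- unname(populations(x))
  attr(out, "genDistances") <- setNames(lapply(preds, `[[`, "gen_distances"),
                                        rownames(Q))
  out
}

#' Leave-one-out origin prediction at the population level
#'
#' Each member individual is predicted against a panel from which its entire
#' population (all members and the centroid) has been removed. This is more
#' rigorous than leaving out single individuals and is the evaluation scheme
#' used for panel curation.
#'
#' @param panel A [ReferencePanel-class] with at least 2 populations.
#' @inheritParams predictOrigin
#' @return Data frame as in [predictOrigins()], with a `population` column
#'   giving each sample's own (excluded) population.
#' @export
leaveOneOut <- function(panel, M = 10, exponent = 2) {
  stopifnot(is(panel, "ReferencePanel"))
  if (nPopulations(panel) < 2) stop("leave-one-out requires >= 2 populations")
  members <- panelMembers(panel)
  pop <- unname(populations(members))
  res <- lapply(populationNames(panel), function(p) {
    reduced <- removePopulations(panel, p)
    predictOrigins(members[pop == p], reduced, M = M, exponent = exponent)
  })
  gd <- do.call(c, lapply(res, attr, "genDistances"))
  out <- do.call(rbind, res)
  ord <- match(sampleIDs(members), out$sample_id)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "genDistances") <- gd[out$sample_id]
  out
}

#' Remove populations from a reference panel
#'
#' @param panel A [ReferencePanel-class].
#' @param names Population names to drop (members included).
#' @return The reduced [ReferencePanel-class].
#' @export
removePopulations <- function(panel, names) {
  stopifnot(is(panel, "ReferencePanel"))
  keepPops <- setdiff(populationNames(panel), names)
  if (!length(keepPops)) stop("cannot remove every population")
  members <- panelMembers(panel)
  keep <- unname(populations(members)) %in% keepPops
  coords <- panelCoords(panel)[keepPops, , drop = FALSE]
  ReferencePanel(members[keep],
                 coords = data.frame(population = keepPops,
                                     lat = coords[, "lat"],
                                     lon = coords[, "lon"]))
}

#' Distance from a point to a named region
#'
#' Zero when the point lies inside (or on the boundary of) any of the
#' region's polygons; otherwise the minimum great-circle distance to the
#' region boundary, computed exactly against every boundary arc on the
#' spherical Earth model.
#'
#' @param lat,lon Query point, decimal degrees.
#' @param regions A [RegionSet-class].
#' @param region Region name.
#' @return Distance in km (0 if inside).
#' @export
distanceToRegion <- function(lat, lon, regions, region) {
  polys <- regionPolygons(regions, region)
  .checkLat(lat); .checkLon(lon)
  if (.pointInAnyPolygon(lat, lon, polys)) return(0)
  p <- drop(.ll2xyz(lat, lon))
  best <- Inf
  for (poly in polys) for (ring in poly) {
    V <- .ll2xyz(ring[, 2], ring[, 1])
    for (i in seq_len(nrow(V) - 1)) {
      best <- min(best, .arcDistKm(p, V[i, ], V[i + 1, ]))
    }
  }
  best
}

#' Assignment accuracy of predictions against home regions
#'
#' For each distance threshold T, the fraction of individuals whose
#' predicted coordinates lie within T km of their home region's boundary
#' (inside counts as 0 km), overall and per population.
#'
#' @param predictions Data frame with `sample_id`, `lat`, `lon` and
#'   optionally `population` (from [leaveOneOut()] / [predictOrigins()]).
#' @param regions A [RegionSet-class] with the home region polygons.
#' @param home Named character vector mapping `sample_id` to region name.
#' @param thresholds Distance thresholds in km (default 250 and 500).
#' @return List of class `accuracyReport`: `overall` (data frame
#'   `threshold_km`, `fraction`, `n`), `perPopulation`, and `distances`
#'   (named per-sample km to home region).
#' @export
assignmentAccuracy <- function(predictions, regions, home,
                               thresholds = c(250, 500)) {
  df <- as.data.frame(predictions)
  if (nrow(df) == 0) stop("no predictions given")
  miss <- setdiff(df$sample_id, names(home))
  if (length(miss))
    stop("sample(s) with no home region: ", paste(miss, collapse = ", "))
  dkm <- vapply(seq_len(nrow(df)), function(i)
    distanceToRegion(df$lat[i], df$lon[i], regions, home[[df$sample_id[i]]]),
    numeric(1))
  names(dkm) <- df$sample_id
  thresholds <- sort(thresholds)
  overall <- data.frame(threshold_km = thresholds,
                        fraction = vapply(thresholds,
                                          function(t) mean(dkm <= t), numeric(1)),
                        n = nrow(df))
  pops <- if ("population" %in% colnames(df)) df$population else
    rep("all", nrow(df))
  pp <- do.call(rbind, lapply(unique(pops), function(p) {
    sel <- pops == p
    data.frame(population = p, threshold_km = thresholds,
               fraction = vapply(thresholds,
                                 function(t) mean(dkm[sel] <= t), numeric(1)),
               n = sum(sel))
  }))
  structure(list(overall = overall, perPopulation = pp, distances = dkm),
            class = "accuracyReport")
}

#' @export
print.accuracyReport <- function(x, ...) {
  cat("Assignment accuracy (", x$overall$n[1], " individuals)\n", sep = "")
  for (i in seq_len(nrow(x$overall)))
    cat(sprintf("  within %g km: %.1f%%\n", x$overall$threshold_km[i],
                100 * x$overall$fraction[i]))
  invisible(x)
}
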