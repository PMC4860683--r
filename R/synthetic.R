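## Synthetic-data generator: spatially structured admixture with known
## ground truth. K ancestral sources with exponential distance decay define
## a smooth expected-admixture surface; population sites draw members from a
## Dirichlet centred on the local expectation; square home regions around
## each site stand in for country boundaries; a companion sampler produces
## cohort-labelled haplogroup tables.

#' Construct a synthetic world from explicit components
#'
#' Lower-level companion to [syntheticWorld()] for fully custom geometries.
#'
#' @param sources Numeric matrix, K x 2 (`lat`, `lon`) of ancestral sources.
#' @param lambda Decay length(s), km, recycled to K.
#' @param extent Named numeric `latMin`, `latMax`, `lonMin`, `lonMax`.
#' @param sites Data frame `name`, `lat`, `lon`, `n`.
#' @param alpha Dirichlet concentration.
#' @param seed Master seed.
#' @return A [SyntheticWorld-class].
#' @export
SyntheticWorld <- function(sources, lambda, extent, sites, alpha = 200,
                           seed = 1) {
  sources <- as.matrix(sources)
  colnames(sources) <- c("lat", "lon")
  if (is.null(rownames(sources)))
    rownames(sources) <- paste0("source", seq_len(nrow(sources)))
  new("SyntheticWorld", sources = sources,
      lambda = rep_len(lambda, nrow(sources)), extent = extent,
      sites = as.data.frame(sites), alpha = alpha, seed = seed)
}

#' Construct a synthetic world
#'
#' The default geometry emulates a continental-scale reference panel:
#' 25 population sites on a jittered 5x5 grid across a West-Eurasian-sized
#' window (about 400-500 km between neighbouring sites, comparable to the
#' spacing of a curated reference panel), K = 9 ancestral sources on a 3x3
#' grid over a slightly wider box so that each component peaks in a
#' different part of the map, decay length 1500 km producing smooth
#' admixture clines, and Dirichlet concentration 200 for within-population
#' noise.
#'
#' @param K Number of ancestral sources/components (default 9).
#' @param nSites Number of population sites (default 25; a perfect square
#'   is laid out as a jittered grid, otherwise sites are placed uniformly).
#' @param perSite Samples per site (default 16).
#' @param lambda Decay length(s) in km, recycled to K (default 1500).
#' @param alpha Dirichlet concentration (default 200).
#' @param seed Master seed; every sampling stream derives from it.
#' @param extent Named numeric: `latMin`, `latMax`, `lonMin`, `lonMax`.
#' @param jitterDeg Site jitter, degrees (default 0.5).
#' @return A [SyntheticWorld-class].
#' @export
syntheticWorld <- function(K = 9, nSites = 25, perSite = 16, lambda = 1500,
                           alpha = 200, seed = 1,
                           extent = c(latMin = 36, latMax = 50,
                                      lonMin = 16, lonMax = 38),
                           jitterDeg = 0.5) {
  lambda <- rep_len(lambda, K)
  ## sources on a grid over the extent widened by 4 degrees
  g <- ceiling(sqrt(K))
  srcLat <- seq(extent["latMin"] - 4, extent["latMax"] + 4, length.out = g)
  srcLon <- seq(extent["lonMin"] - 4, extent["lonMax"] + 4, length.out = g)
  grid <- expand.grid(lat = srcLat, lon = srcLon)[seq_len(K), ]
  sources <- cbind(lat = grid$lat, lon = grid$lon)
  rownames(sources) <- paste0("source", seq_len(K))
  m <- round(sqrt(nSites))
  set.seed(.streamSeed(seed, 1) %% 2147483647)
  if (m * m == nSites) {
    la <- seq(extent["latMin"] + jitterDeg, extent["latMax"] - jitterDeg,
              length.out = m)
    lo <- seq(extent["lonMin"] + jitterDeg, extent["lonMax"] - jitterDeg,
              length.out = m)
    pos <- expand.grid(lat = la, lon = lo)
    pos$lat <- pos$lat + runif(nSites, -jitterDeg, jitterDeg)
    pos$lon <- pos$lon + runif(nSites, -jitterDeg, jitterDeg)
  } else {
    pos <- data.frame(lat = runif(nSites, extent["latMin"], extent["latMax"]),
                      lon = runif(nSites, extent["lonMin"], extent["lonMax"]))
  }
  sites <- data.frame(name = sprintf("site%02d", seq_len(nSites)),
                      lat = pos$lat, lon = pos$lon, n = perSite,
                      stringsAsFactors = FALSE)
  new("SyntheticWorld", sources = sources, lambda = lambda,
      extent = extent, sites = sites, alpha = alpha, seed = seed)
}

#' Expected admixture vector at a map position
#'
#' Component j is proportional to `exp(-dist_km(point, source_j) / lambda_j)`
#' and the vector is normalized to the simplex. Deterministic and
#' continuous over the extent.
#'
#' @param world A [SyntheticWorld-class].
#' @param lat,lon Query point inside the world's extent.
#' @return Named numeric admixture vector of length K.
#' @export
expectedAdmixture <- function(world, lat, lon) {
  stopifnot(is(world, "SyntheticWorld"))
  e <- world@extent
  if (lat < e["latMin"] || lat > e["latMax"] ||
      lon < e["lonMin"] || lon > e["lonMax"])
    stop("point (", lat, ", ", lon, ") is outside the world extent")
  d <- geodesicKm(lat, lon, world@sources[, "lat"], world@sources[, "lon"])
  w <- exp(-d / world@lambda)
  setNames(w / sum(w), rownames(world@sources))
}

## square region of the given side (km), centred on (lat, lon)
.squareRegion <- function(lat, lon, sideKm) {
  dLat <- (sideKm / 2) / (EARTH_RADIUS_KM * pi / 180)
  dLon <- dLat / cos(lat * pi / 180)
  ring <- cbind(lon = c(lon - dLon, lon + dLon, lon + dLon, lon - dLon, lon - dLon),
                lat = c(lat - dLat, lat - dLat, lat + dLat, lat + dLat, lat - dLat))
  list(list(ring))
}

#' Sample a full synthetic dataset from a world
#'
#' Draws each site's members from `Dirichlet(alpha * expected)` at the site
#' coordinate, compiles the reference panel, and emits one square home
#' region per site (side `regionSideKm`, a country-sized stand-in for
#' political boundaries). Fully reproducible from the world's master seed.
#'
#' @param world A [SyntheticWorld-class].
#' @param regionSideKm Side of the square home regions, km (default 500).
#' @return List: `individuals` ([AdmixtureSet-class]), `panel`
#'   ([ReferencePanel-class]), `regions` ([RegionSet-class]), and `home`
#'   (named character vector sample ID -> region name).
#' @export
sampleWorld <- function(world, regionSideKm = 500) {
  stopifnot(is(world, "SyntheticWorld"))
  s <- world@sites
  K <- nrow(world@sources)
  Q <- matrix(NA_real_, sum(s$n), K)
  ids <- character(sum(s$n)); popLab <- character(sum(s$n))
  lat <- numeric(sum(s$n)); lon <- numeric(sum(s$n))
  regions <- list()
  row <- 0L
  for (i in seq_len(nrow(s))) {
    mu <- expectedAdmixture(world, s$lat[i], s$lon[i])
    set.seed(.streamSeed(world@seed, 100 + i) %% 2147483647)
    draws <- .rdirichlet(s$n[i], world@alpha * mu)
    idx <- row + seq_len(s$n[i])
    Q[idx, ] <- draws
    ids[idx] <- sprintf("%s_ind%03d", s$name[i], seq_len(s$n[i]))
    popLab[idx] <- s$name[i]
    lat[idx] <- s$lat[i]; lon[idx] <- s$lon[i]
    regions[[s$name[i]]] <- .squareRegion(s$lat[i], s$lon[i], regionSideKm)
    row <- row + s$n[i]
  }
  colnames(Q) <- rownames(world@sources)
  individuals <- AdmixtureSet(Q, sampleID = ids, population = popLab,
                              lat = lat, lon = lon)
  list(individuals = individuals,
       panel = ReferencePanel(individuals),
       regions = RegionSet(regions),
       home = setNames(popLab, ids))
}

#' Sample a single migrant with a known true origin
#'
#' One individual drawn from `Dirichlet(alpha * expected)` at an arbitrary
#' coordinate inside the extent; the true origin is recorded in the
#' returned object, independent of any later prediction.
#'
#' @param world A [SyntheticWorld-class].
#' @param lat,lon True origin (inside the extent).
#' @param seed Seed for this draw.
#' @param sampleID Sample ID (default "migrant").
#' @return A single-sample [AdmixtureSet-class].
#' @export
sampleMigrant <- function(world, lat, lon, seed = 1, sampleID = "migrant") {
  mu <- expectedAdmixture(world, lat, lon)    # also validates the extent
  set.seed(seed)
  q <- .rdirichlet(1, world@alpha * mu)
  colnames(q) <- rownames(world@sources)
  AdmixtureSet(q, sampleID = sampleID, population = "migrant",
               lat = lat, lon = lon)
}

#' Sample a cohort-labelled haplogroup table
#'
#' Multinomial draws of haplogroup labels per cohort from stated
#' frequencies, producing a table shaped like a study supplementary table.
#'
#' @param freqSpec Named list, one entry per cohort, each a list with
#'   element `mt` (named numeric frequencies summing to 1) and optional
#'   element `y` (ditto; omit for no Y calls in that cohort).
#' @param n Individuals per cohort (recycled over cohorts).
#' @param seed Seed; the table is fully reproducible.
#' @return A [HaplogroupTable-class].
#' @export
sampleHaplogroupTable <- function(freqSpec, n, seed = 1) {
  stopifnot(length(freqSpec) >= 1, !is.null(names(freqSpec)))
  n <- rep_len(n, length(freqSpec))
  rows <- list()
  counter <- 0L
  for (ci in seq_along(freqSpec)) {
    co <- names(freqSpec)[ci]
    spec <- freqSpec[[ci]]
    for (locus in intersect(c("mt", "y"), names(spec))) {
      f <- spec[[locus]]
      if (abs(sum(f) - 1) > 1e-9)
        stop("frequencies for cohort '", co, "' locus '", locus,
             "' sum to ", sum(f), ", not 1")
    }
    set.seed(.streamSeed(seed, ci) %% 2147483647)
    mt <- sample(names(spec$mt), n[ci], replace = TRUE, prob = spec$mt)
    y <- if (!is.null(spec$y))
      sample(names(spec$y), n[ci], replace = TRUE, prob = spec$y)
    else rep(NA_character_, n[ci])
    rows[[ci]] <- data.frame(
      sample_id = sprintf("%s_%04d", co, counter + seq_len(n[ci])),
      mt_haplogroup = mt, y_haplogroup = y, cohort = co,
      stringsAsFactors = FALSE)
    counter <- counter + n[ci]
  }
  HaplogroupTable(do.call(rbind, rows))
}

#' Write a sampled synthetic world to disk
#'
#' Writes the standard input files consumed by the analysis pipeline:
#' `admixture.csv` (samples with population, origin and proportions),
#' `coords.csv` (population centroids), `regions.geojson` (home region
#' polygons) and `homes.csv` (sample ID to home region).
#'
#' @param sampled List from [sampleWorld()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeWorld <- function(sampled, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ind <- sampled$individuals
  df <- data.frame(sample_id = sampleIDs(ind),
                   population = unname(populations(ind)),
                   lat = sampleCoords(ind)[, "lat"],
                   lon = sampleCoords(ind)[, "lon"],
                   as.data.frame(admixProportions(ind)),
                   check.names = FALSE)
  write.csv(df, file.path(dir, "admixture.csv"), row.names = FALSE,
            quote = FALSE)
  cc <- panelCoords(sampled$panel)
  write.csv(data.frame(population = rownames(cc), lat = cc[, "lat"],
                       lon = cc[, "lon"]),
            file.path(dir, "coords.csv"), row.names = FALSE, quote = FALSE)
  writeRegions(sampled$regions, file.path(dir, "regions.geojson"))
  write.csv(data.frame(sample_id = names(sampled$home),
                       region = unname(sampled$home)),
            file.path(dir, "homes.csv"), row.names = FALSE, quote = FALSE)
  invisible(dir)
}
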