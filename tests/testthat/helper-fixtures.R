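# Shared fixtures: toy admixture sets, a small reference panel on known
# coordinates, and the standard synthetic-world experiment used in the
# recovery and curation tests.

# random points on the K-simplex
randomSimplex <- function(n, K, seed = 1) {
  set.seed(seed)
  Q <- matrix(rexp(n * K), n, K)
  Q <- Q / rowSums(Q)
  rownames(Q) <- sprintf("r%03d", seq_len(n))
  colnames(Q) <- paste0("C", seq_len(K))
  Q
}

toySet <- function(Q, population = NA, lat = NA, lon = NA, cohort = NA) {
  AdmixtureSet(Q, population = population, lat = lat, lon = lon,
               cohort = cohort)
}

# 3 well-separated populations of 5 members each, on one meridian
toyPanel <- function(noise = 0.01, seed = 42) {
  set.seed(seed)
  centers <- rbind(A = c(0.70, 0.20, 0.10),
                   B = c(0.20, 0.70, 0.10),
                   C = c(0.10, 0.20, 0.70))
  Q <- do.call(rbind, lapply(rownames(centers), function(p) {
    m <- matrix(pmax(rep(centers[p, ], each = 5) +
                       rnorm(15, 0, noise), 1e-6), 5, 3)
    m / rowSums(m)
  }))
  rownames(Q) <- sprintf("%s%02d", rep(c("A", "B", "C"), each = 5), 1:5)
  ind <- AdmixtureSet(Q, population = rep(c("A", "B", "C"), each = 5))
  ReferencePanel(ind, coords = data.frame(population = c("A", "B", "C"),
                                          lat = c(40, 45, 50), lon = 20))
}

squareRegionSet <- function(name = "A", lonMin = 0, lonMax = 1,
                            latMin = 0, latMax = 1) {
  ring <- cbind(lon = c(lonMin, lonMax, lonMax, lonMin, lonMin),
                lat = c(latMin, latMin, latMax, latMax, latMin))
  rs <- list(ring)
  names(rs) <- name
  RegionSet(rs)
}

# the four geographically extreme sites of a synthetic world (grid corners)
cornerSites <- function(world) {
  s <- world@sites
  unique(sapply(list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1)), function(sgn)
    s$name[which.max(sgn[1] * s$lat + sgn[2] * s$lon)]))
}

# relabel a fraction of individuals to a far site (>= minKm away), emulating
# mislabelled panel members; exempt populations are never used as targets
plantOutliers <- function(sampled, world, frac = 0.10, minKm = 800,
                          exempt = character(), seed = 99) {
  ind <- sampled$individuals
  s <- world@sites
  set.seed(seed)
  idx <- sample(length(ind), round(frac * length(ind)))
  pop <- unname(populations(ind))
  newpop <- pop
  for (i in idx) {
    here <- match(pop[i], s$name)
    dk <- geodesicKm(s$lat[here], s$lon[here], s$lat, s$lon)
    far <- setdiff(which(dk >= minKm), match(exempt, s$name))
    newpop[i] <- s$name[far[sample.int(length(far), 1)]]
  }
  ind@info$population <- newpop
  list(individuals = ind, home = setNames(newpop, sampleIDs(ind)),
       planted = sampleIDs(ind)[idx])
}
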