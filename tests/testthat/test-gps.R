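test_that("geodesic distances match the spherical closed form", {
  expect_equal(geodesicKm(40, 20, 40, 20), 0)
  expect_equal(geodesicKm(0, 0, 0, 1), 6371 * pi / 180, tolerance = 1e-9)
  # second-implementation haversine oracle on two Anatolian villages
  hav <- function(la1, lo1, la2, lo2) {
    r <- pi / 180
    a <- sin((la2 - la1) * r / 2)^2 +
      cos(la1 * r) * cos(la2 * r) * sin((lo2 - lo1) * r / 2)^2
    2 * 6371 * asin(sqrt(a))
  }
  la1 <- parseDMS("40°9′N"); lo1 <- parseDMS("40°26′E")
  la2 <- parseDMS("40°4′N"); lo2 <- parseDMS("40°8′E")
  d <- geodesicKm(la1, lo1, la2, lo2)
  expect_equal(d, hav(la1, lo1, la2, lo2), tolerance = 1e-9)
  expect_lt(abs(d - 27), 2)    # the two villages are ~27 km apart
  expect_error(geodesicKm(95, 0, 0, 0), "latitude")
})

test_that("origin prediction is exact at panel vertices", {
  panel <- toyPanel()
  # a query equal to a population's mean signature lands on its centroid
  for (p in populationNames(panel)) {
    pr <- predictOrigin(panelMeans(panel)[p, ], panel)
    expect_identical(pr$best_population, p)
    expect_equal(c(pr$lat, pr$lon),
                 unname(panelCoords(panel)[p, c("lat", "lon")]))
    expect_equal(pr$gen_distances$d[1], 0)
  }
  # single-population panel returns its centroid regardless of distance
  members <- panelMembers(panel)
  one <- ReferencePanel(members[populations(members) == "A"],
                        data.frame(population = "A", lat = 40, lon = 20))
  pr <- predictOrigin(c(0.1, 0.1, 0.8), one)
  expect_equal(c(pr$lat, pr$lon), c(40, 20))
  expect_error(predictOrigin(c(0.5, 0.5), panel), "does not match panel K")
})

test_that("prediction matches an independent weight/centroid recomputation", {
  panel <- toyPanel()
  q <- c(0.5, 0.35, 0.15)
  pr <- predictOrigin(q, panel, M = 3)
  # independent recomputation: distances, inverse-square relative weights,
  # weighted 3-vector centroid
  means <- panelMeans(panel); coords <- panelCoords(panel)
  d <- apply(means, 1, function(m) sqrt(sum((q - m)^2)))
  ord <- order(d)
  w <- (d[ord][1] / d[ord])^2; w <- w / sum(w)
  phi <- coords[ord, "lat"] * pi / 180; lam <- coords[ord, "lon"] * pi / 180
  v <- c(sum(w * cos(phi) * cos(lam)), sum(w * cos(phi) * sin(lam)),
         sum(w * sin(phi)))
  v <- v / sqrt(sum(v^2))
  expect_equal(pr$lat, asin(v[3]) * 180 / pi, tolerance = 1e-9)
  expect_equal(pr$lon, atan2(v[2], v[1]) * 180 / pi, tolerance = 1e-9)
  expect_identical(pr$gen_distances$population, names(d)[ord])
})

test_that("prediction is invariant to panel population order", {
  panel <- toyPanel()
  members <- panelMembers(panel)
  perm <- c("C", "A", "B")
  ord <- unlist(lapply(perm, function(p) which(populations(members) == p)))
  coords <- panelCoords(panel)[perm, ]
  panel2 <- ReferencePanel(members[ord],
                           data.frame(population = perm,
                                      lat = coords[, "lat"],
                                      lon = coords[, "lon"]))
  q <- c(0.45, 0.40, 0.15)
  p1 <- predictOrigin(q, panel); p2 <- predictOrigin(q, panel2)
  expect_equal(c(p1$lat, p1$lon), c(p2$lat, p2$lon), tolerance = 1e-12)
})

test_that("prediction stays in the hull and moves monotonically", {
  panel <- toyPanel()
  members <- panelMembers(panel)
  two <- ReferencePanel(members[populations(members) %in% c("A", "C")],
                        data.frame(population = c("A", "C"),
                                   lat = c(40, 50), lon = 20))
  mA <- panelMeans(two)["A", ]; mC <- panelMeans(two)["C", ]
  lastKm <- Inf
  for (t in seq(0, 1, by = 0.1)) {
    q <- (1 - t) * mA + t * mC
    pr <- predictOrigin(q / sum(q), two)
    # within the hull of the two centroids (same meridian)
    expect_equal(pr$lon, 20, tolerance = 1e-9)
    expect_gte(pr$lat, 40 - 1e-9); expect_lte(pr$lat, 50 + 1e-9)
    km <- geodesicKm(pr$lat, pr$lon, 50, 20)
    expect_lte(km, lastKm + 1e-9)   # monotone approach to C
    lastKm <- km
  }
})

test_that("leave-one-out excludes the whole home population", {
  panel <- toyPanel()
  loo <- leaveOneOut(panel)
  expect_equal(nrow(loo), 15L)
  gd <- attr(loo, "genDistances")
  for (i in seq_len(nrow(loo)))
    expect_false(loo$population[i] %in% gd[[loo$sample_id[i]]]$population)
  # 2-population panel: everyone is predicted at the other centroid
  members <- panelMembers(panel)
  two <- ReferencePanel(members[populations(members) %in% c("A", "B")],
                        data.frame(population = c("A", "B"),
                                   lat = c(40, 45), lon = 20))
  loo2 <- leaveOneOut(two)
  expect_true(all(loo2$lat[loo2$population == "A"] == 45))
  expect_true(all(loo2$lat[loo2$population == "B"] == 40))
  expect_error(leaveOneOut(ReferencePanel(
    members[populations(members) == "A"],
    data.frame(population = "A", lat = 40, lon = 20))), ">= 2")
})

test_that("leave-one-out equals one-at-a-time manual panel removal", {
  w <- syntheticWorld(seed = 11, perSite = 4)
  sw <- sampleWorld(w)
  loo <- leaveOneOut(sw$panel)
  set.seed(1)
  for (i in sample(nrow(loo), 8)) {
    id <- loo$sample_id[i]
    reduced <- removePopulations(sw$panel, loo$population[i])
    manual <- predictOrigin(
      admixProportions(sw$individuals)[id, ], reduced)
    expect_equal(loo$lat[i], manual$lat, tolerance = 1e-12)
    expect_equal(loo$lon[i], manual$lon, tolerance = 1e-12)
    expect_identical(loo$best_population[i], manual$best_population)
  }
})

test_that("distance to a region is exact on the sphere", {
  rs <- squareRegionSet("sq", lonMin = 0, lonMax = 2, latMin = -1, latMax = 1)
  expect_equal(distanceToRegion(0, 1, rs, "sq"), 0)      # inside
  expect_equal(distanceToRegion(0.5, 0, rs, "sq"), 0)    # on the boundary
  # 1 degree due east of the meridian-aligned edge at the equator
  rsW <- squareRegionSet("w", lonMin = -3, lonMax = -1, latMin = -1, latMax = 1)
  expect_equal(distanceToRegion(0, 0, rsW, "w"), 6371 * pi / 180,
               tolerance = 1e-6)
  expect_error(distanceToRegion(0, 0, rs, "nope"), "unknown region")
})

test_that("region distance matches a dense boundary-sampling oracle", {
  rs <- squareRegionSet("sq", lonMin = 10, lonMax = 12, latMin = 40, latMax = 42)
  ring <- regionPolygons(rs, "sq")[[1]][[1]]
  densify <- function(ring, step = 0.01) {
    out <- NULL
    for (i in seq_len(nrow(ring) - 1)) {
      n <- max(2, ceiling(max(abs(ring[i + 1, ] - ring[i, ])) / step))
      out <- rbind(out, cbind(seq(ring[i, 1], ring[i + 1, 1], length.out = n),
                              seq(ring[i, 2], ring[i + 1, 2], length.out = n)))
    }
    out
  }
  dense <- densify(ring)
  set.seed(9)
  for (k in 1:5) {
    plat <- runif(1, 37, 45); plon <- runif(1, 7, 15)
    if (plat >= 40 && plat <= 42 && plon >= 10 && plon <= 12) next
    oracle <- min(geodesicKm(plat, plon, dense[, 2], dense[, 1]))
    expect_equal(distanceToRegion(plat, plon, rs, "sq"), oracle,
                 tolerance = 1)   # km
  }
})

test_that("assignment accuracy counts thresholds correctly", {
  rs <- squareRegionSet("home", lonMin = 20, lonMax = 22,
                        latMin = 44, latMax = 46)
  inside <- data.frame(sample_id = c("a", "b", "c"),
                       lat = c(44.5, 45, 45.9), lon = c(20.5, 21, 21.9))
  home <- setNames(rep("home", 4), c("a", "b", "c", "d"))
  acc <- assignmentAccuracy(inside, rs, home)
  expect_equal(acc$overall$fraction, c(1, 1))

  # one of four ~300 km outside: 75% at 250 km, 100% at 500 km
  far <- rbind(inside, data.frame(sample_id = "d", lat = 45, lon = 25.2))
  d4 <- distanceToRegion(45, 25.2, rs, "home")
  expect_gt(d4, 250); expect_lt(d4, 500)
  acc <- assignmentAccuracy(far, rs, home)
  expect_equal(acc$overall$fraction, c(0.75, 1))
  # per-threshold monotonicity
  expect_true(all(diff(acc$overall$fraction) >= 0))

  expect_error(assignmentAccuracy(far[0, ], rs, home), "no predictions")
  expect_error(assignmentAccuracy(
    data.frame(sample_id = "zz", lat = 45, lon = 21), rs, home), "zz")
})
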