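# three reference populations whose mean signatures are (nearly) the unit
# vectors e1, e2, e3, at known coordinates
triField <- function() {
  Q <- diag(3)
  rownames(Q) <- c("u", "v", "w"); colnames(Q) <- c("C1", "C2", "C3")
  ind <- AdmixtureSet(Q, population = c("U", "V", "W"))
  panel <- ReferencePanel(ind, data.frame(population = c("U", "V", "W"),
                                          lat = c(40, 40, 48),
                                          lon = c(10, 20, 15)))
  buildField(panel)
}

test_that("three populations triangulate into a single triangle", {
  f <- triField()
  expect_equal(nrow(f@triangles), 1L)
  expect_length(f@hull, 3L)
})

test_that("field evaluation is exact at vertices and linear on edges", {
  f <- triField()
  expect_equal(unname(admixtureAt(f, 40, 10)), c(1, 0, 0))
  expect_equal(unname(admixtureAt(f, 40, 20)), c(0, 1, 0))
  expect_equal(unname(admixtureAt(f, 48, 15)), c(0, 0, 1))
  # midpoint of the U--V edge: componentwise average
  expect_equal(unname(admixtureAt(f, 40, 15)), c(0.5, 0.5, 0))
  # centroid of the triangle with vertex vectors e1, e2, e3
  expect_equal(unname(admixtureAt(f, mean(c(40, 40, 48)), 15)),
               rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("interior interpolation matches a 3x3 barycentric solve", {
  w <- syntheticWorld(seed = 11, perSite = 3)
  sw <- sampleWorld(w)
  f <- buildField(sw$panel)
  set.seed(12)
  for (k in 1:8) {
    lat <- runif(1, 40, 46); lon <- runif(1, 24, 30)   # well inside
    got <- admixtureAt(f, lat, lon)
    # oracle: locate the triangle, solve the linear system for barycentric
    # weights, combine vertex vectors
    found <- FALSE
    for (t in seq_len(nrow(f@triangles))) {
      V <- f@points[f@triangles[t, ], ]
      A <- rbind(t(V), c(1, 1, 1))
      lam <- solve(A, c(lon, lat, 1))
      if (all(lam >= -1e-9)) {
        oracle <- drop(pmax(lam, 0) %*% f@values[f@triangles[t, ], ])
        expect_equal(unname(got), unname(oracle / sum(oracle)),
                     tolerance = 1e-9)
        found <- TRUE
        break
      }
    }
    expect_true(found)
    expect_equal(sum(got), 1, tolerance = 1e-12)   # simplex preserved
  }
})

test_that("out-of-hull evaluation and degenerate panels are errors", {
  f <- triField()
  expect_error(admixtureAt(f, 52, 15), "outside the reference hull")
  Q <- randomSimplex(3, 3, seed = 2)
  collinear <- ReferencePanel(
    AdmixtureSet(Q, population = c("A", "B", "C")),
    data.frame(population = c("A", "B", "C"), lat = c(40, 42, 44), lon = 10))
  expect_error(buildField(collinear), "collinear")
  two <- ReferencePanel(AdmixtureSet(Q[1:2, ], population = c("A", "B")),
                        data.frame(population = c("A", "B"),
                                   lat = c(40, 42), lon = c(10, 12)))
  expect_error(buildField(two), "at least 3")
})

test_that("native simulation honours its contract and seed", {
  f <- triField()
  rs <- squareRegionSet("mid", lonMin = 13, lonMax = 17,
                        latMin = 41, latMax = 45)
  nat <- simulateNatives(f, rs, "mid", n = 100, seed = 7)
  expect_equal(length(nat), 100L)
  Q <- admixProportions(nat)
  expect_equal(unname(rowSums(Q)), rep(1, 100))
  expect_true(all(Q >= 0))
  xy <- sampleCoords(nat)
  expect_true(all(xy[, "lat"] >= 41 & xy[, "lat"] <= 45 &
                    xy[, "lon"] >= 13 & xy[, "lon"] <= 17))
  # reproducibility
  nat2 <- simulateNatives(f, rs, "mid", n = 100, seed = 7)
  expect_identical(admixProportions(nat2), Q)
  expect_identical(sampleCoords(nat2), xy)
  nat3 <- simulateNatives(f, rs, "mid", n = 100, seed = 8)
  expect_false(identical(sampleCoords(nat3), xy))
  # disjoint region
  far <- squareRegionSet("far", lonMin = 60, lonMax = 61,
                         latMin = 10, latMax = 11)
  expect_error(simulateNatives(f, far, "far", n = 5, seed = 1), "disjoint")
})

test_that("native simulation is invariant to ring vertex rotation", {
  f <- triField()
  ring <- cbind(lon = c(13, 17, 17, 13, 13), lat = c(41, 41, 45, 45, 41))
  rot <- rbind(ring[3:5, ], ring[2:3, ])   # same ring, rotated start
  rs1 <- RegionSet(list(mid = ring)); rs2 <- RegionSet(list(mid = rot))
  n1 <- simulateNatives(f, rs1, "mid", n = 30, seed = 4)
  n2 <- simulateNatives(f, rs2, "mid", n = 30, seed = 4)
  expect_identical(sampleCoords(n1), sampleCoords(n2))
})

test_that("native sample means approach the polygon-average field value", {
  f <- triField()
  rs <- squareRegionSet("mid", lonMin = 13, lonMax = 16,
                        latMin = 41, latMax = 44)
  nat <- simulateNatives(f, rs, "mid", n = 400, seed = 21)
  # Monte-Carlo oracle for the polygon average, independent draw
  set.seed(1234)
  m <- 4000
  lon <- runif(m, 13, 16); lat <- runif(m, 41, 44)
  oracle <- colMeans(t(vapply(seq_len(m), function(i)
    admixtureAt(f, lat[i], lon[i]), numeric(3))))
  got <- colMeans(admixProportions(nat))
  se <- apply(admixProportions(nat), 2, sd) / sqrt(400)
  expect_true(all(abs(got - oracle) <= 3 * (se + 0.005)))
})

test_that("closest-group assignment matches an exhaustive scan", {
  set.seed(31)
  g1 <- toySet(randomSimplex(8, 5, seed = 41), population = "G1",
               lat = runif(8, 40, 42), lon = runif(8, 10, 12))
  g2 <- toySet(randomSimplex(7, 5, seed = 52), population = "G2",
               lat = runif(7, 46, 48), lon = runif(7, 20, 22))
  groups <- list(G1 = g1, G2 = g2)
  qQ <- randomSimplex(20, 5, seed = 63)
  rownames(qQ) <- sprintf("q%02d", 1:20)
  queries <- toySet(qQ, lat = runif(20, 40, 48), lon = runif(20, 10, 22))
  prop <- closestGroupAssignment(queries, groups, metric = "genetic")
  expect_equal(sum(prop), 1)
  # exhaustive nearest-member oracle
  ass <- attr(prop, "assignments")
  for (i in 1:20) {
    d1 <- min(apply(admixProportions(g1), 1, function(g)
      sqrt(sum((qQ[i, ] - g)^2))))
    d2 <- min(apply(admixProportions(g2), 1, function(g)
      sqrt(sum((qQ[i, ] - g)^2))))
    expect_identical(unname(ass[i]), if (d1 <= d2) "G1" else "G2")
  }
  # a query identical to a member is assigned to that member's group
  same <- toySet(admixProportions(g2)[3, , drop = FALSE])
  p <- closestGroupAssignment(same, groups, metric = "genetic")
  expect_equal(unname(p["G2"]), 1)

  # geographic metric uses great-circle distances to member origins
  pg <- closestGroupAssignment(queries, groups, metric = "geographic")
  assg <- attr(pg, "assignments")
  cq <- sampleCoords(queries)
  for (i in c(1, 7, 14)) {
    d1 <- min(geodesicKm(cq[i, "lat"], cq[i, "lon"],
                         sampleCoords(g1)[, "lat"], sampleCoords(g1)[, "lon"]))
    d2 <- min(geodesicKm(cq[i, "lat"], cq[i, "lon"],
                         sampleCoords(g2)[, "lat"], sampleCoords(g2)[, "lon"]))
    expect_identical(unname(assg[i]), if (d1 <= d2) "G1" else "G2")
  }
  noCoord <- toySet(qQ)
  expect_error(closestGroupAssignment(noCoord, groups, metric = "geographic"),
               "coordinates")
})
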