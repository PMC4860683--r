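## Spatial interpolation of admixture signatures: Delaunay triangulation of
## reference population centroids on the plate-carree (lon, lat) plane with
## componentwise barycentric interpolation; simulation of "native"
## individuals inside named regions; closest-group assignment.

## Bowyer-Watson Delaunay triangulation. Input: n x 2 matrix (x, y).
## Returns an integer matrix, one triangle (3 vertex indices) per row.
## Panel sizes here are tens of points, so the O(n^2) insertion is fine.
.delaunay <- function(pts) {
  n <- nrow(pts)
  stopifnot(n >= 3)
  rng <- apply(pts, 2, range)
  span <- max(rng[2, ] - rng[1, ], 1)
  mid <- colMeans(rng)
  ## super-triangle comfortably enclosing all points
  super <- rbind(mid + c(-20 * span, -10 * span),
                 mid + c(20 * span, -10 * span),
                 mid + c(0, 20 * span))
  P <- rbind(pts, super)
  circum <- function(tri) {
    a <- P[tri[1], ]; b <- P[tri[2], ]; c <- P[tri[3], ]
    d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
    if (abs(d) < 1e-14) return(c(Inf, Inf, Inf))
    ux <- ((sum(a^2)) * (b[2] - c[2]) + (sum(b^2)) * (c[2] - a[2]) +
             (sum(c^2)) * (a[2] - b[2])) / d
    uy <- ((sum(a^2)) * (c[1] - b[1]) + (sum(b^2)) * (a[1] - c[1]) +
             (sum(c^2)) * (b[1] - a[1])) / d
    c(ux, uy, sqrt((a[1] - ux)^2 + (a[2] - uy)^2))
  }
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  ccs <- list(circum(tris[[1]]))
  for (ip in seq_len(n)) {
    p <- P[ip, ]
    bad <- vapply(ccs, function(cc)
      sqrt((p[1] - cc[1])^2 + (p[2] - cc[2])^2) <= cc[3] * (1 + 1e-12),
      logical(1))
    badTris <- tris[bad]
    ## boundary of the cavity: edges of bad triangles not shared by two
    edges <- do.call(rbind, lapply(badTris, function(t)
      rbind(sort(t[c(1, 2)]), sort(t[c(2, 3)]), sort(t[c(1, 3)]))))
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[!bad]; ccs <- ccs[!bad]
    for (e in seq_len(nrow(boundary))) {
      newTri <- c(boundary[e, 1], boundary[e, 2], ip)
      tris <- c(tris, list(newTri))
      ccs <- c(ccs, list(circum(newTri)))
    }
  }
  keep <- vapply(tris, function(t) all(t <= n), logical(1))
  out <- do.call(rbind, tris[keep])
  storage.mode(out) <- "integer"
  out
}

## Barycentric coordinates of point p in triangle with vertices V (3 x 2).
.barycentric <- function(p, V) {
  A <- cbind(V[1, ] - V[3, ], V[2, ] - V[3, ])
  det <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  if (abs(det) < 1e-14) return(c(-1, -1, -1))
  rhs <- p - V[3, ]
  l1 <- (A[2, 2] * rhs[1] - A[1, 2] * rhs[2]) / det
  l2 <- (-A[2, 1] * rhs[1] + A[1, 1] * rhs[2]) / det
  c(l1, l2, 1 - l1 - l2)
}

#' Build a spatially interpolated admixture field from a panel
#'
#' Triangulates the reference population centroids on the (lon, lat) plane
#' (Delaunay) and attaches each population's mean admixture vector to its
#' vertex. Each of the K components is then a piecewise-linear function of
#' position; evaluation at a vertex returns the vertex vector exactly.
#'
#' @param panel A [ReferencePanel-class] with at least 3 non-collinear
#'   population centroids.
#' @return An [AdmixtureField-class].
#' @export
buildField <- function(panel) {
  stopifnot(is(panel, "ReferencePanel"))
  coords <- panelCoords(panel)
  pts <- cbind(lon = coords[, "lon"], lat = coords[, "lat"])
  if (nrow(pts) < 3) stop("need at least 3 reference populations")
  h <- grDevices::chull(pts)
  area2 <- 0
  for (i in seq_along(h)) {
    j <- if (i == length(h)) 1 else i + 1
    area2 <- area2 + pts[h[i], 1] * pts[h[j], 2] - pts[h[j], 1] * pts[h[i], 2]
  }
  if (length(h) < 3 || abs(area2) < 1e-10)
    stop("reference population centroids are collinear")
  rownames(pts) <- rownames(coords)
  new("AdmixtureField", points = pts, values = panelMeans(panel),
      triangles = .delaunay(pts), hull = as.integer(h))
}

#' Evaluate an admixture field at a point
#'
#' Barycentric linear interpolation inside the triangle containing the
#' point. Because the per-component interpolation is linear and every
#' vertex vector sums to 1, the interpolated vector sums to 1 up to float
#' error (asserted at 1e-10) and is then renormalized exactly.
#'
#' @param field An [AdmixtureField-class].
#' @param lat,lon Query point, decimal degrees. Must lie inside the convex
#'   hull of the reference populations; no extrapolation is performed.
#' @return Named numeric admixture vector.
#' @export
admixtureAt <- function(field, lat, lon) {
  stopifnot(is(field, "AdmixtureField"))
  p <- c(lon, lat)
  tri <- field@triangles
  for (t in seq_len(nrow(tri))) {
    V <- field@points[tri[t, ], , drop = FALSE]
    lam <- .barycentric(p, V)
    if (all(lam >= -1e-9)) {
      lam <- pmax(lam, 0)
      q <- drop(lam %*% field@values[tri[t, ], , drop = FALSE])
      stopifnot(abs(sum(q) - 1) <= 1e-10)
      return(q / sum(q))
    }
  }
  stop("point (", lat, ", ", lon, ") is outside the reference hull; ",
       "no extrapolation")
}

.inHull <- function(field, lat, lon) {
  hp <- field@points[field@hull, , drop = FALSE]
  pracma::inpolygon(lon, lat, hp[, 1], hp[, 2], boundary = TRUE)
}

#' Simulate "native" individuals inside a region
#'
#' Samples `n` coordinates uniformly inside the intersection of a named
#' region and the field's convex hull (rejection sampling from the bounding
#' box) and assigns each individual the interpolated admixture signature at
#' its coordinate. Signatures are deterministic given the coordinate; an
#' optional Dirichlet jitter (concentration `alpha` times the local
#' signature) can be enabled for noisy cohorts, and is off by default.
#'
#' @param field An [AdmixtureField-class].
#' @param regions A [RegionSet-class].
#' @param region Region name; must intersect the field's hull.
#' @param n Number of individuals (the standard cohort sizes are 100 or
#'   200).
#' @param seed Seed making the cohort fully reproducible.
#' @param alpha Optional Dirichlet concentration for jitter (NULL = none).
#' @return An [AdmixtureSet-class] with origins recorded and population set
#'   to the region name.
#' @export
simulateNatives <- function(field, regions, region, n = 100, seed = 1,
                            alpha = NULL) {
  stopifnot(is(field, "AdmixtureField"))
  polys <- regionPolygons(regions, region)
  allv <- do.call(rbind, lapply(polys, function(p) do.call(rbind, p)))
  bbox <- rbind(range(allv[, 1]), range(allv[, 2]))     # lon, lat
  hp <- field@points[field@hull, , drop = FALSE]
  if (bbox[1, 1] > max(hp[, 1]) || bbox[1, 2] < min(hp[, 1]) ||
      bbox[2, 1] > max(hp[, 2]) || bbox[2, 2] < min(hp[, 2]))
    stop("region '", region, "' is disjoint from the reference hull")
  set.seed(seed)
  lat <- numeric(n); lon <- numeric(n)
  got <- 0L; draws <- 0L
  while (got < n) {
    if (draws >= 1e6)
      stop("rejection sampling failed after 1e6 draws; region '", region,
           "' may be disjoint from the reference hull")
    m <- min(4096L, 1000000L - draws)
    cx <- runif(m, bbox[1, 1], bbox[1, 2])
    cy <- runif(m, bbox[2, 1], bbox[2, 2])
    draws <- draws + m
    for (i in seq_len(m)) {
      if (got >= n) break
      if (.pointInAnyPolygon(cy[i], cx[i], polys) &&
          .inHull(field, cy[i], cx[i])) {
        got <- got + 1L
        lat[got] <- cy[i]; lon[got] <- cx[i]
      }
    }
  }
  Q <- t(vapply(seq_len(n), function(i) admixtureAt(field, lat[i], lon[i]),
                numeric(ncol(field@values))))
  if (!is.null(alpha)) {
    Q <- t(vapply(seq_len(n), function(i)
      drop(.rdirichlet(1, alpha * Q[i, ])), numeric(ncol(Q))))
  }
  colnames(Q) <- colnames(field@values)
  AdmixtureSet(Q, sampleID = sprintf("%s_native_%04d", region, seq_len(n)),
               population = region, lat = lat, lon = lon)
}

#' Assign queries to the group holding their nearest member
#'
#' Each query individual is assigned to the group containing its single
#' nearest member, either in admixture space (`metric = "genetic"`,
#' minimal Euclidean distance between vectors) or on the map
#' (`metric = "geographic"`, great-circle distance between origins).
#'
#' @param queries [AdmixtureSet-class] of query individuals.
#' @param groups Named list of [AdmixtureSet-class] objects.
#' @param metric `"genetic"` or `"geographic"`.
#' @return Named numeric vector of per-group assignment proportions
#'   (summing to 1 over all groups); per-query group labels are attached as
#'   the `assignments` attribute.
#' @export
closestGroupAssignment <- function(queries, groups,
                                   metric = c("genetic", "geographic")) {
  metric <- match.arg(metric)
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  if (any(vapply(groups, length, integer(1)) == 0))
    stop("all groups must be non-empty")
  groupOf <- rep(names(groups), vapply(groups, length, integer(1)))
  if (metric == "genetic") {
    Qq <- .asQ(queries)
    Qg <- do.call(rbind, lapply(groups, .asQ))
    D <- .crossDist(Qq, Qg)
  } else {
    cq <- sampleCoords(queries)
    cg <- do.call(rbind, lapply(groups, sampleCoords))
    if (anyNA(cq) || anyNA(cg))
      stop("geographic metric requires coordinates on both sides")
    D <- outer(seq_len(nrow(cq)), seq_len(nrow(cg)), Vectorize(function(i, j)
      geodesicKm(cq[i, "lat"], cq[i, "lon"], cg[j, "lat"], cg[j, "lon"])))
  }
  assign <- groupOf[apply(D, 1, which.min)]
  prop <- vapply(names(groups), function(g) mean(assign == g), numeric(1))
  attr(prop, "assignments") <- setNames(assign, sampleIDs(queries))
  prop
}
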