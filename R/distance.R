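## Genetic admixture distances and distance-based statistics.
##
## The genetic admixture distance d between an individual and a population is
## the minimal Euclidean distance between the individual's admixture vector
## and the vectors of all members of that population. Distances are held as
## fractions internally; reported summaries are multiplied by 100 (percent).

.asQ <- function(x) {
  if (is(x, "AdmixtureSet")) return(x@proportions)
  if (is.null(dim(x))) return(matrix(x, 1, dimnames = list("query", NULL)))
  as.matrix(x)
}

#' Euclidean distance between two admixture vectors
#'
#' @param a,b Numeric vectors of K admixture proportions (or single-sample
#'   [AdmixtureSet-class] objects). K must agree.
#' @return The Euclidean distance, a fraction (multiply by 100 for percent).
#' @export
admixtureDistance <- function(a, b) {
  a <- drop(.asQ(a)); b <- drop(.asQ(b))
  if (length(a) != length(b))
    stop("admixture vectors have different K: ", length(a), " vs ", length(b))
  sqrt(sum((a - b)^2))
}

## rows of A vs rows of B -> |A| x |B| Euclidean distance matrix
.crossDist <- function(A, B) {
  aa <- rowSums(A^2); bb <- rowSums(B^2)
  d2 <- outer(aa, bb, "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

#' Minimal genetic distance from an individual to a group
#'
#' Computes d: the minimum over group members of the Euclidean distance in
#' admixture space. When the query individual itself is a member of the
#' group (matched by sample ID), it is excluded, so that within-population
#' diversity never scores a self-match of zero.
#'
#' @param query Numeric admixture vector or single-sample
#'   [AdmixtureSet-class].
#' @param group [AdmixtureSet-class] (or matrix with sample IDs as rownames)
#'   holding the target population's members.
#' @param queryID Sample ID of the query, used for self-exclusion; taken
#'   from `query` automatically when it is an AdmixtureSet.
#' @param targetName Optional label for the target group.
#' @return A one-row data frame: `query_id`, `target_group`, `d` (fraction),
#'   `nearest_member`.
#' @export
minDistanceToGroup <- function(query, group, queryID = NULL, targetName = NA) {
  if (is(query, "AdmixtureSet")) {
    stopifnot(length(query) == 1)
    if (is.null(queryID)) queryID <- sampleIDs(query)
  }
  q <- drop(.asQ(query))
  G <- .asQ(group)
  if (!is.null(queryID) && !is.null(rownames(G)))
    G <- G[setdiff(rownames(G), queryID), , drop = FALSE]
  if (nrow(G) == 0) stop("group is empty (after self-exclusion)")
  if (length(q) != ncol(G)) stop("K mismatch between query and group")
  d <- sqrt(colSums((t(G) - q)^2))
  i <- which.min(d)
  data.frame(query_id = if (is.null(queryID)) NA_character_ else queryID,
             target_group = targetName,
             d = unname(d[i]),
             nearest_member = rownames(G)[i],
             stringsAsFactors = FALSE)
}

#' Summary of genetic distances from one group to another
#'
#' For each individual of group A, computes its minimal distance to group B
#' (with self-exclusion when A and B share samples) and summarizes those
#' minima. Median and standard deviation are the primary summary (the
#' "median +/- SD" convention); the mean is also returned since either
#' convention appears in practice.
#'
#' @param groupA,groupB [AdmixtureSet-class] objects (or matrices with
#'   sample-ID rownames).
#' @return List with `median`, `sd`, `mean` (all in percent), `n`, and the
#'   per-individual minima `d` (percent).
#' @export
groupDistanceSummary <- function(groupA, groupB) {
  A <- .asQ(groupA); B <- .asQ(groupB)
  if (nrow(A) == 0 || nrow(B) == 0) stop("both groups must be non-empty")
  ## exact per-pair arithmetic (the expanded-square formula loses the exact
  ## zeros needed for self-comparisons)
  tB <- t(B)
  D <- t(vapply(seq_len(nrow(A)), function(i)
    sqrt(colSums((tB - A[i, ])^2)), numeric(nrow(B))))
  dimnames(D) <- list(rownames(A), rownames(B))
  if (!is.null(rownames(A)) && !is.null(rownames(B))) {
    shared <- intersect(rownames(A), rownames(B))
    for (s in shared) D[s, s] <- Inf   # self-exclusion
  }
  d <- apply(D, 1, min)
  if (any(!is.finite(d))) stop("a group member has no non-self counterpart")
  d <- 100 * d
  list(median = median(d), sd = if (length(d) > 1) sd(d) else 0,
       mean = mean(d), n = length(d), d = d)
}

#' Two-sample Kolmogorov-Smirnov comparison of distance distributions
#'
#' D is the supremum over thresholds of the absolute difference between the
#' two empirical CDFs; the p-value uses the asymptotic Kolmogorov
#' distribution with effective sample size nx*ny/(nx+ny).
#'
#' @param x,y Numeric samples (e.g., genetic distances), each non-empty.
#' @return List with `statistic` (D) and `p.value`.
#' @export
ksTwoSample <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(statistic = unname(kt$statistic), p.value = unname(kt$p.value))
}

#' Genetic similarity graph
#'
#' Undirected edges between every pair of individuals whose pairwise
#' admixture distance, in percent, is strictly below the threshold. No
#' self-edges; each unordered pair appears once.
#'
#' @param x [AdmixtureSet-class] with at least two samples.
#' @param threshold Edge threshold in percent (default 0.75). Strict `<`.
#' @return Data frame with columns `id_a`, `id_b`, `d_percent`.
#' @export
similarityGraph <- function(x, threshold = 0.75) {
  if (threshold < 0) stop("threshold must be non-negative")
  Q <- .asQ(x)
  if (nrow(Q) < 2) stop("need at least 2 individuals")
  ids <- rownames(Q)
  D <- 100 * as.matrix(stats::dist(Q))
  idx <- which(upper.tri(D) & D < threshold, arr.ind = TRUE)
  data.frame(id_a = ids[idx[, 1]], id_b = ids[idx[, 2]],
             d_percent = D[idx], stringsAsFactors = FALSE)
}

#' Write a similarity edge list to CSV
#'
#' @param edges Data frame from [similarityGraph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(edges, path) {
  write.csv(edges, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
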