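## Haplogroup frequency statistics on cohort-labelled mtDNA / Y tables:
## resolution collapsing by prefix, frequency tables, coverage of common
## groups, unique-label counts, founding-lineage shares, and labels
## exclusive to one cohort.

## Does haplogroup h belong to the clade named by prefix p?
## Prefix match, except that a prefix ending in a digit must not be
## continued by another digit: "H1" covers "H1a1" but not "H10" (which is a
## sibling clade, not a subclade), while "K1a" covers "K1a9" because the
## digit after a letter opens a deeper level.
.prefixMatch <- function(h, p) {
  if (!startsWith(h, p)) return(FALSE)
  if (nchar(h) == nchar(p)) return(TRUE)
  lastP <- substr(p, nchar(p), nchar(p))
  nextH <- substr(h, nchar(p) + 1, nchar(p) + 1)
  !(grepl("[0-9]", lastP) && grepl("[0-9]", nextH))
}

#' Collapse a haplogroup name to a lower-resolution prefix
#'
#' Returns the longest of the given prefixes that names a clade containing
#' the haplogroup (prefix match with the digit-boundary rule of the
#' nomenclature: `"H1"` covers `"H1a1"` but not `"H10"`). Haplogroups
#' matching no prefix are returned unchanged.
#'
#' @param haplogroup Character vector of haplogroup names (non-empty).
#' @param prefixes Character vector of low-resolution prefixes.
#' @return Character vector of collapsed labels.
#' @examples
#' collapseResolution(c("K1a1b1a", "H10", "HV1b2"), c("K1a", "H1", "HV"))
#' @export
collapseResolution <- function(haplogroup, prefixes) {
  if (!length(prefixes)) stop("prefixes must be non-empty")
  if (any(is.na(haplogroup) | !nzchar(haplogroup)))
    stop("empty haplogroup string")
  prefixes <- prefixes[order(nchar(prefixes), decreasing = TRUE)]
  vapply(haplogroup, function(h) {
    for (p in prefixes) if (.prefixMatch(h, p)) return(p)
    h
  }, character(1), USE.NAMES = FALSE)
}

.locusCalls <- function(table, locus = c("mt", "y"), cohort = NULL) {
  locus <- match.arg(locus)
  d <- as.data.frame(table)
  if (!is.null(cohort)) {
    if (!all(cohort %in% d$cohort))
      stop("unknown cohort: ",
           paste(setdiff(cohort, d$cohort), collapse = ", "))
    d <- d[d$cohort %in% cohort, , drop = FALSE]
  }
  calls <- if (locus == "mt") d$mt_haplogroup else d$y_haplogroup
  calls[!is.na(calls)]
}

#' Haplogroup frequency table
#'
#' Counts (optionally collapsed) haplogroup labels among the individuals
#' with a call at the locus, after cohort filtering. The denominator is the
#' number of called individuals (females lack Y calls, so per-locus
#' percentages use per-locus totals). Rows are ordered by descending count,
#' then label.
#'
#' @param table A [HaplogroupTable-class].
#' @param locus `"mt"` or `"y"`.
#' @param cohort Optional cohort label(s) to filter on.
#' @param prefixes Optional low-resolution prefixes passed to
#'   [collapseResolution()]; collapsing moves counts, never drops them.
#' @return Data frame `label`, `count`, `fraction`, with attribute `total`
#'   (called individuals).
#' @export
frequencyTable <- function(table, locus = c("mt", "y"), cohort = NULL,
                           prefixes = NULL) {
  calls <- .locusCalls(table, locus, cohort)
  if (!length(calls)) stop("no individuals with a call at this locus")
  if (!is.null(prefixes)) calls <- collapseResolution(calls, prefixes)
  tab <- table(calls)
  out <- data.frame(label = names(tab), count = as.integer(tab),
                    fraction = as.numeric(tab) / length(calls),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$label), ]
  rownames(out) <- NULL
  attr(out, "total") <- length(calls)
  out
}

#' Fraction of individuals covered by a set of common haplogroups
#'
#' Sums the frequency-table fractions of either an explicit label set or
#' the top `k` most frequent labels.
#'
#' @param freqs Data frame from [frequencyTable()].
#' @param labels Explicit labels to sum; unknown labels warn and count 0.
#' @param k Alternatively, use the `k` most frequent labels.
#' @return Summed fraction in `[0, 1]`.
#' @export
topKCoverage <- function(freqs, labels = NULL, k = NULL) {
  if (is.null(labels) && is.null(k)) stop("give either labels or k")
  if (is.null(labels)) {
    if (k > nrow(freqs)) stop("k exceeds the number of labels")
    labels <- freqs$label[seq_len(k)]
  } else {
    unknown <- setdiff(labels, freqs$label)
    if (length(unknown))
      warning("label(s) not present, counted as 0: ",
              paste(unknown, collapse = ", "))
  }
  sum(freqs$fraction[freqs$label %in% labels])
}

#' Unique haplogroup counts per cohort
#'
#' Number of distinct full-resolution Y and mtDNA haplogroups in each
#' cohort (a haplogroup-diversity comparison).
#'
#' @param table A [HaplogroupTable-class].
#' @param cohortNames Cohorts to tabulate (default: all).
#' @return Data frame `cohort`, `unique_y`, `unique_mt`.
#' @export
uniqueCounts <- function(table, cohortNames = cohorts(table)) {
  d <- as.data.frame(table)
  unknown <- setdiff(cohortNames, d$cohort)
  if (length(unknown))
    stop("unknown cohort: ", paste(unknown, collapse = ", "))
  do.call(rbind, lapply(cohortNames, function(co) {
    sel <- d$cohort == co
    data.frame(cohort = co,
               unique_y = length(unique(d$y_haplogroup[sel & !is.na(d$y_haplogroup)])),
               unique_mt = length(unique(d$mt_haplogroup[sel])),
               stringsAsFactors = FALSE)
  }))
}

#' Share of a cohort belonging to a set of founding lineages
#'
#' Fraction of the cohort's mtDNA-called individuals whose haplogroup falls
#' under any of the lineage prefixes (digit-boundary rule; nested prefixes
#' count each individual once). Aliases for a lineage (alternate printed
#' notations) can be supplied as extra prefixes.
#'
#' @param table A [HaplogroupTable-class].
#' @param lineages Character vector of lineage prefixes (non-empty).
#' @param cohort Optional cohort filter.
#' @return Fraction in `[0, 1]`.
#' @export
lineageShare <- function(table, lineages, cohort = NULL) {
  if (!length(lineages)) stop("lineages must be non-empty")
  calls <- .locusCalls(table, "mt", cohort)
  if (!length(calls)) stop("no mtDNA calls in cohort")
  hit <- vapply(calls, function(h)
    any(vapply(lineages, function(p) .prefixMatch(h, p), logical(1))),
    logical(1))
  mean(hit)
}

#' Haplogroups present in one cohort and absent from another
#'
#' Distinct labels observed in cohort A at the locus but never in cohort B,
#' with their counts in A (lineage loss / exclusivity comparison).
#'
#' @param table A [HaplogroupTable-class].
#' @param cohortA,cohortB Cohort labels.
#' @param locus `"mt"` or `"y"`.
#' @return Data frame `label`, `count_a` (possibly zero rows).
#' @export
exclusiveHaplogroups <- function(table, cohortA, cohortB,
                                 locus = c("mt", "y")) {
  callsA <- .locusCalls(table, locus, cohortA)
  callsB <- .locusCalls(table, locus, cohortB)
  only <- setdiff(unique(callsA), unique(callsB))
  tab <- table(callsA)[only]
  out <- data.frame(label = only,
                    count_a = if (length(only)) as.integer(tab) else integer(0),
                    stringsAsFactors = FALSE)
  out[order(-out$count_a, out$label), , drop = FALSE]
}
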