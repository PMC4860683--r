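#' @include AllClasses.R
NULL

#' Accessors for admixgeo containers
#'
#' `admixProportions()` returns the samples-x-K proportion matrix;
#' `sampleIDs()`, `populations()`, `cohorts()` and `sampleCoords()` return the
#' per-sample metadata; `nComponents()` and `componentNames()` describe the
#' admixture components; `panelMeans()`, `panelCoords()`, `populationNames()`
#' and `nPopulations()` describe a reference panel; `panelMembers()` returns
#' the member individuals; `regionNames()` lists the regions of a
#' [RegionSet-class].
#'
#' @param x An [AdmixtureSet-class], [ReferencePanel-class],
#'   [RegionSet-class] or [HaplogroupTable-class] object, as appropriate.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("admixProportions", function(x) standardGeneric("admixProportions"))
#' @rdname accessors
#' @export
setMethod("admixProportions", "AdmixtureSet", function(x) x@proportions)

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setMethod("sampleIDs", "AdmixtureSet", function(x) rownames(x@proportions))
#' @rdname accessors
#' @export
setMethod("sampleIDs", "HaplogroupTable", function(x) x@data$sample_id)

#' @rdname accessors
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))
#' @rdname accessors
#' @export
setMethod("populations", "AdmixtureSet",
          function(x) setNames(x@info$population, rownames(x@proportions)))

#' @rdname accessors
#' @export
setGeneric("cohorts", function(x) standardGeneric("cohorts"))
#' @rdname accessors
#' @export
setMethod("cohorts", "AdmixtureSet",
          function(x) setNames(x@info$cohort, rownames(x@proportions)))
#' @rdname accessors
#' @export
setMethod("cohorts", "HaplogroupTable", function(x) unique(x@data$cohort))

#' @rdname accessors
#' @export
setGeneric("sampleCoords", function(x) standardGeneric("sampleCoords"))
#' @rdname accessors
#' @export
setMethod("sampleCoords", "AdmixtureSet", function(x) {
  m <- cbind(lat = x@info$lat, lon = x@info$lon)
  rownames(m) <- rownames(x@proportions)
  m
})

#' @rdname accessors
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))
#' @rdname accessors
#' @export
setMethod("nComponents", "AdmixtureSet", function(x) ncol(x@proportions))
#' @rdname accessors
#' @export
setMethod("nComponents", "ReferencePanel", function(x) ncol(x@means))

#' @rdname accessors
#' @export
setGeneric("componentNames", function(x) standardGeneric("componentNames"))
#' @rdname accessors
#' @export
setMethod("componentNames", "AdmixtureSet", function(x) colnames(x@proportions))
#' @rdname accessors
#' @export
setMethod("componentNames", "ReferencePanel", function(x) colnames(x@means))

#' @rdname accessors
#' @export
setGeneric("panelMeans", function(x) standardGeneric("panelMeans"))
#' @rdname accessors
#' @export
setMethod("panelMeans", "ReferencePanel", function(x) x@means)

#' @rdname accessors
#' @export
setGeneric("panelCoords", function(x) standardGeneric("panelCoords"))
#' @rdname accessors
#' @export
setMethod("panelCoords", "ReferencePanel", function(x) x@coords)

#' @rdname accessors
#' @export
setGeneric("panelMembers", function(x) standardGeneric("panelMembers"))
#' @rdname accessors
#' @export
setMethod("panelMembers", "ReferencePanel", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("populationNames", function(x) standardGeneric("populationNames"))
#' @rdname accessors
#' @export
setMethod("populationNames", "ReferencePanel", function(x) rownames(x@means))

#' @rdname accessors
#' @export
setGeneric("nPopulations", function(x) standardGeneric("nPopulations"))
#' @rdname accessors
#' @export
setMethod("nPopulations", "ReferencePanel", function(x) nrow(x@means))

#' @rdname accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @rdname accessors
#' @export
setMethod("regionNames", "RegionSet", function(x) names(x@regions))

#' Polygons of one named region
#'
#' @param x A [RegionSet-class].
#' @param name Region name.
#' @return List of polygons (each a list of closed lon/lat ring matrices).
#' @export
regionPolygons <- function(x, name) {
  stopifnot(is(x, "RegionSet"))
  if (!name %in% names(x@regions))
    stop("unknown region: ", name)
  x@regions[[name]]
}

#' @export
#' @describeIn AdmixtureSet-class Number of samples.
setMethod("length", "AdmixtureSet", function(x) nrow(x@proportions))

#' @export
#' @describeIn AdmixtureSet-class Subset by sample index, ID or logical mask.
setMethod("[", "AdmixtureSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, rownames(x@proportions))
  initialize(x, proportions = x@proportions[i, , drop = FALSE],
             info = x@info[i, , drop = FALSE])
})

#' @export
#' @describeIn HaplogroupTable-class Convert to a plain data frame.
setMethod("as.data.frame", "HaplogroupTable",
          function(x, ...) as.data.frame(x@data))

setMethod("show", "AdmixtureSet", function(object) {
  cat("AdmixtureSet with", nrow(object@proportions), "samples,",
      ncol(object@proportions), "components\n")
  pops <- unique(object@info$population)
  cat("  populations:", if (all(is.na(pops))) "<unset>" else
    paste(head(pops, 6), collapse = ", "),
    if (length(pops) > 6) "..." else "", "\n")
  if (!all(is.na(object@info$cohort)))
    cat("  cohorts:", paste(unique(object@info$cohort), collapse = ", "), "\n")
})

setMethod("show", "ReferencePanel", function(object) {
  cat("ReferencePanel:", nrow(object@means), "populations,",
      length(sampleIDs(object@members)), "members, K =",
      ncol(object@means), "\n")
  cat("  ", paste(head(rownames(object@means), 8), collapse = ", "),
      if (nrow(object@means) > 8) "..." else "", "\n")
})

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet with", length(object@regions), "region(s):",
      paste(head(names(object@regions), 8), collapse = ", "),
      if (length(object@regions) > 8) "..." else "", "\n")
})

setMethod("show", "HaplogroupTable", function(object) {
  d <- object@data
  cat("HaplogroupTable:", nrow(d), "individuals;",
      sum(!is.na(d$y_haplogroup)), "with Y calls; cohorts:",
      paste(unique(d$cohort), collapse = ", "), "\n")
})

setMethod("show", "AdmixtureField", function(object) {
  cat("AdmixtureField:", nrow(object@points), "vertices,",
      nrow(object@triangles), "triangles, K =", ncol(object@values), "\n")
})

setMethod("show", "SyntheticWorld", function(object) {
  cat("SyntheticWorld: K =", nrow(object@sources), "sources,",
      nrow(object@sites), "sites, alpha =", object@alpha,
      ", seed =", object@seed, "\n")
})
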