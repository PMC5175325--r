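#' Accessors for pharmRegIRT objects
#'
#' \code{itemIds} and \code{countryIds} return identifier vectors;
#' \code{responseMatrix} returns the countries-by-items observed matrix X;
#' \code{lambdaDraws}, \code{alphaDraws} and \code{phiDraws} return the
#' retained draw matrices (one row per joint draw); \code{nDraws} the number
#' of retained draws.
#'
#' @param x a \linkS4class{ResponseSet}, \linkS4class{PosteriorDraws} or
#'   \linkS4class{TrueParameters} object.
#' @return See the description of each accessor.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("itemIds", function(x) standardGeneric("itemIds"))

#' @rdname accessors
#' @export
setGeneric("countryIds", function(x) standardGeneric("countryIds"))

#' @rdname accessors
#' @export
setGeneric("responseMatrix", function(x) standardGeneric("responseMatrix"))

#' @rdname accessors
#' @export
setGeneric("lambdaDraws", function(x) standardGeneric("lambdaDraws"))

#' @rdname accessors
#' @export
setGeneric("alphaDraws", function(x) standardGeneric("alphaDraws"))

#' @rdname accessors
#' @export
setGeneric("phiDraws", function(x) standardGeneric("phiDraws"))

#' @rdname accessors
#' @export
setGeneric("nDraws", function(x) standardGeneric("nDraws"))

#' @rdname accessors
#' @export
setMethod("itemIds", "ResponseSet", function(x)
  rownames(SummarizedExperiment::assay(x, "responses")))

#' @rdname accessors
#' @export
setMethod("countryIds", "ResponseSet", function(x)
  colnames(SummarizedExperiment::assay(x, "responses")))

#' @rdname accessors
#' @export
setMethod("responseMatrix", "ResponseSet", function(x)
  t(SummarizedExperiment::assay(x, "responses")))

#' @rdname accessors
#' @export
setMethod("itemIds", "PosteriorDraws", function(x) colnames(x@lambda))

#' @rdname accessors
#' @export
setMethod("countryIds", "PosteriorDraws", function(x) colnames(x@phi))

#' @rdname accessors
#' @export
setMethod("lambdaDraws", "PosteriorDraws", function(x) x@lambda)

#' @rdname accessors
#' @export
setMethod("alphaDraws", "PosteriorDraws", function(x) x@alpha)

#' @rdname accessors
#' @export
setMethod("phiDraws", "PosteriorDraws", function(x) x@phi)

#' @rdname accessors
#' @export
setMethod("nDraws", "PosteriorDraws", function(x) nrow(x@lambda))

#' @rdname accessors
#' @export
setMethod("itemIds", "TrueParameters", function(x) names(x@lambda))

#' @rdname accessors
#' @export
setMethod("countryIds", "TrueParameters", function(x) names(x@phi))

setMethod("show", "ItemRegistry", function(object) {
  it <- object@items
  cat("ItemRegistry with", nrow(it), "item definitions\n")
  for (ix in unique(it$index)) {
    sub <- it[it$index == ix, ]
    cat(sprintf("  %-15s %2d items (%d derived)\n", ix, nrow(sub),
                sum(sub$derived)))
  }
})

setMethod("show", "ResponseSet", function(object) {
  m <- SummarizedExperiment::assay(object, "responses")
  cat("ResponseSet:", ncol(m), "countries x", nrow(m), "items\n")
  cat(sprintf("  observed: %d/%d entries (%.1f%% missing)\n",
              sum(!is.na(m)), length(m), 100 * mean(is.na(m))))
})

setMethod("show", "TrueParameters", function(object) {
  cat("TrueParameters:", length(object@phi), "countries,",
      length(object@lambda), "items\n")
  cat(sprintf("  lambda in [%.2f, %.2f], alpha in [%.2f, %.2f], missing rate %.2f\n",
              min(object@lambda), max(object@lambda),
              min(object@alpha), max(object@alpha), object@missingRate))
})

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig: prior N(", paste(object@priorMean, collapse = ", "),
      "; sd ", paste(object@priorSD, collapse = ", "), ")\n", sep = "")
  cat(sprintf("  chain: %d iterations, %d burn-in, thin %d, seed %d; anchor '%s'\n",
              object@nIterations, object@nBurnin, object@thin, object@seed,
              object@anchorItem))
})

setMethod("show", "PosteriorDraws", function(object) {
  cat("PosteriorDraws:", nDraws(object), "retained draws;",
      ncol(object@lambda), "items,", ncol(object@phi), "countries\n")
  cat("  anchor item:", object@config@anchorItem,
      " data fingerprint:", object@dataFingerprint, "\n")
})

setMethod("show", "PosteriorSummary", function(object) {
  cat("PosteriorSummary:", nrow(object@items), "items,",
      nrow(object@countries), "countries\n")
  fl <- object@items$item_id[object@items$flagged]
  cat(sprintf("  flagged items (P(lambda<0) >= %.2f): %s\n",
              object@flagThreshold,
              if (length(fl)) paste(fl, collapse = ", ") else "none"))
})

setMethod("show", "ComparisonReport", function(object) {
  cat("ComparisonReport:", object@indexNames[1], "vs", object@indexNames[2],
      "-", nrow(object@scores), "countries\n")
  cat(sprintf("  R^2 = %.3f; corner occupancy (x<q%.2f, y>q%.2f): %d\n",
              object@rSquared, object@xQuantile, object@yQuantile,
              object@cornerCount))
  if (length(object@excluded))
    cat("  excluded:", paste(object@excluded, collapse = ", "), "\n")
})

#' Extract per-item or per-country tables from a summary
#'
#' @param x a \linkS4class{PosteriorSummary}.
#' @return \code{itemSummary}: the ordered item table; \code{countryScores}:
#'   the ordered country-score table.
#' @export
setGeneric("itemSummary", function(x) standardGeneric("itemSummary"))

#' @rdname itemSummary
#' @export
setGeneric("countryScores", function(x) standardGeneric("countryScores"))

#' @rdname itemSummary
#' @export
setMethod("itemSummary", "PosteriorSummary", function(x) x@items)

#' @rdname itemSummary
#' @export
setMethod("countryScores", "PosteriorSummary", function(x) x@countries)
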