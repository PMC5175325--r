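#' Coefficient of determination between paired index scores
#'
#' The squared Pearson correlation of paired posterior-mean latent scores --
#' symmetric in its arguments and invariant to affine rescaling of either
#' score vector.
#'
#' @param x,y paired numeric score vectors of equal length (>= 3).
#' @return R^2 in [0, 1].
#' @export
rSquared <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("at least 3 paired scores are required",
                           call. = FALSE)
  if (.sdPop(x) == 0 || .sdPop(y) == 0)
    stop("scores must not be constant", call. = FALSE)
  cor(x, y)^2
}

#' Corner occupancy: the "empty triangle" diagnostic
#'
#' Counts the countries lying in the upper-left corner of a score-vs-score
#' scatter: x strictly below its lower quantile and y strictly above its
#' upper quantile. An empty corner (count 0) operationalizes the visual
#' observation that a high x-score is a necessary condition for a high
#' y-score. Quantiles use the default continuous convention (type 7); the
#' count is invariant under strictly monotone transforms of either axis.
#'
#' @inheritParams rSquared
#' @param xQuantile lower quantile level for x (default 0.25).
#' @param yQuantile upper quantile level for y (default 0.75).
#' @return integer count.
#' @export
cornerOccupancy <- function(x, y, xQuantile = 0.25, yQuantile = 0.75) {
  stopifnot(length(x) == length(y))
  if (xQuantile <= 0 || xQuantile >= 1 || yQuantile <= 0 || yQuantile >= 1)
    stop("quantile levels must lie in (0, 1)", call. = FALSE)
  xt <- quantile(x, xQuantile, names = FALSE)
  yt <- quantile(y, yQuantile, names = FALSE)
  sum(x < xt & y > yt)
}

#' Compare two indices' country scores
#'
#' Pairs the posterior-mean scores of the countries present in both indices
#' (after user-supplied exclusions), and reports the coefficient of
#' determination together with the corner-occupancy diagnostic and the
#' thresholds it used. Exclusions are never automatic; any excluded country
#' is recorded in the report.
#'
#' @param scoresX,scoresY country scores for the two indices: either a
#'   \linkS4class{PosteriorSummary}, the data.frame returned by
#'   [countryScores()], or a named numeric vector of posterior means.
#' @param exclusions character vector of country ids to drop before pairing.
#' @param indexNames length-2 character, names for the two indices.
#' @inheritParams cornerOccupancy
#' @return a \linkS4class{ComparisonReport}.
#' @export
compareIndices <- function(scoresX, scoresY, exclusions = character(),
                           indexNames = c("x", "y"),
                           xQuantile = 0.25, yQuantile = 0.75) {
  sx <- .asScoreVector(scoresX)
  sy <- .asScoreVector(scoresY)
  common <- setdiff(intersect(names(sx), names(sy)), exclusions)
  if (length(common) < 3L)
    stop("fewer than 3 countries shared by both indices after exclusions",
         call. = FALSE)
  sx <- sx[common]
  sy <- sy[common]
  xt <- quantile(sx, xQuantile, names = FALSE)
  yt <- quantile(sy, yQuantile, names = FALSE)
  new("ComparisonReport",
      scores = data.frame(country_id = common, score_x = unname(sx),
                          score_y = unname(sy), row.names = NULL),
      indexNames = as.character(indexNames),
      rSquared = rSquared(sx, sy),
      cornerCount = as.integer(cornerOccupancy(sx, sy, xQuantile, yQuantile)),
      xQuantile = xQuantile, yQuantile = yQuantile,
      xThreshold = xt, yThreshold = yt,
      excluded = as.character(exclusions))
}

.asScoreVector <- function(s) {
  if (is(s, "PosteriorSummary")) s <- countryScores(s)
  if (is.data.frame(s)) {
    stopifnot(all(c("country_id", "phi_mean") %in% names(s)))
    return(structure(s$phi_mean, names = s$country_id))
  }
  if (is.numeric(s) && !is.null(names(s))) return(s)
  stop("scores must be a PosteriorSummary, a country-score data.frame, ",
       "or a named numeric vector", call. = FALSE)
}

#' Write a comparison report to CSV
#'
#' @param report a \linkS4class{ComparisonReport}.
#' @param path output CSV path; paired scores are written with the summary
#'   statistics attached as leading comment lines.
#' @return the path, invisibly.
#' @export
writeComparisonCSV <- function(report, path) {
  stopifnot(is(report, "ComparisonReport"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# indices: %s vs %s", report@indexNames[1], report@indexNames[2]),
    sprintf("# r_squared: %.6f", report@rSquared),
    sprintf("# corner_count: %d (x<q%.2f=%.4f, y>q%.2f=%.4f)",
            report@cornerCount, report@xQuantile, report@xThreshold,
            report@yQuantile, report@yThreshold),
    sprintf("# excluded: %s",
            if (length(report@excluded)) paste(report@excluded, collapse = ";")
            else "none")), con)
  write.csv(report@scores, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
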