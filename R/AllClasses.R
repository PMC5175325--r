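#' @import methods
#' @importFrom stats pnorm qnorm rnorm runif quantile cor sd
#' @importFrom utils read.csv write.csv packageVersion
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors DataFrame
NULL

#' Item registry for the pharmaceutical-regulation indices
#'
#' Holds the item definitions of the three indices: state regulatory
#' infrastructure (14 items), monitoring of the private market (26 items, one
#' of which -- regularity of inspections -- is derived from per-segment
#' inspection frequencies), and public quality control (18 items).
#'
#' @slot items data.frame with one row per (index, item): columns
#'   \code{item_id}, \code{label}, \code{index}, \code{aspect} (private-market
#'   items only: legal_framework / supply_chain / pharmacovigilance, otherwise
#'   NA), \code{derived} (logical), and list-column \code{sources} (character
#'   vector of raw survey columns a derived item is computed from).
#'
#' @seealso [loadRegistry()], [indexItems()], [assembleResponses()]
#' @export
setClass("ItemRegistry", representation(items = "data.frame"))

.INDEX_NAMES <- c("infrastructure", "private_market", "public_quality")
.INDEX_SIZES <- c(infrastructure = 14L, private_market = 26L,
                  public_quality = 18L)
.ASPECTS <- c("legal_framework", "supply_chain", "pharmacovigilance")

# Canonical item ids per index; used to name missing/extra ids when a
# user-authored registry fails the cardinality check (the packaged YAML
# carries the same sets plus labels).
.CANONICAL_IDS <- list(
  infrastructure = c("3.01.04", "3.01.12", "3.01.14", "3.01.16", "5.01.01",
                     "5.01.02", "5.01.04.02", "5.01.10", "5.01.11", "5.01.15",
                     "5.02.15S", "5.05.03", "5.05.07", "5.05.11"),
  private_market = c("5.02.08", "5.02.12S", "5.05.01", "5.05.02", "5.05.05",
                     "5.05.06", "5.05.08", "5.05.09", "5.07.01", "5.03.05.01",
                     "5.03.05.02", "5.03.05.03", "5.03.05.05", "inspections",
                     "5.04.02", "5.04.03", "5.04.04", "5.05.04", "5.10.01",
                     "5.10.02", "5.10.03", "5.10.05", "5.10.06", "5.10.10",
                     "5.10.16S", "5.10.22S"),
  public_quality = c("5.03.05.04", "5.03.05.05", "5.05.08", "5.05.10",
                     "5.06.04.01", "5.06.04.06", "7.01.03", "7.01.04",
                     "7.01.05", "7.01.07S", "7.01.10S", "7.01.11S",
                     "7.01.12.01S", "7.01.12.02S", "7.02.03", "7.10.10.01S",
                     "7.10.10.02S", "7.10.10.03S"))

setValidity("ItemRegistry", function(object) {
  it <- object@items
  need <- c("item_id", "label", "index", "aspect", "derived", "sources")
  if (!all(need %in% names(it)))
    return(paste("items must have columns:", paste(need, collapse = ", ")))
  if (!all(it$index %in% .INDEX_NAMES))
    return("unknown index name in registry")
  msgs <- character()
  for (ix in .INDEX_NAMES) {
    sub <- it[it$index == ix, ]
    if (anyDuplicated(sub$item_id))
      msgs <- c(msgs, sprintf("duplicate item ids within index '%s'", ix))
    if (nrow(sub) != .INDEX_SIZES[[ix]]) {
      miss <- setdiff(.CANONICAL_IDS[[ix]], sub$item_id)
      extra <- setdiff(sub$item_id, .CANONICAL_IDS[[ix]])
      msgs <- c(msgs, sprintf(
        "index '%s' must have %d items, found %d%s%s",
        ix, .INDEX_SIZES[[ix]], nrow(sub),
        if (length(miss)) paste0("; missing: ", paste(miss, collapse = ", "))
        else "",
        if (length(extra)) paste0("; extra: ", paste(extra, collapse = ", "))
        else ""))
    }
  }
  pm <- it[it$index == "private_market", ]
  if (nrow(pm) && sum(pm$derived) != 1L)
    msgs <- c(msgs, "private_market must contain exactly one derived item")
  if (nrow(pm) && !all(pm$aspect %in% .ASPECTS))
    msgs <- c(msgs, "private_market aspects must be legal_framework, supply_chain or pharmacovigilance")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Country-by-item binary response container
#'
#' A \linkS4class{SummarizedExperiment} holding the observed response matrix
#' X: the assay \code{"responses"} stores items as rows (features) and
#' countries as columns (samples), with entries 0, 1 or NA (missing).
#' \code{\link{responseMatrix}} returns the countries-by-items orientation the
#' measurement model is written in.
#'
#' Validity requires unique country and item identifiers, all observed
#' entries binary, and at least one observed entry per country and per item.
#'
#' @seealso [ResponseSet()], [responseMatrix()], [assembleResponses()]
#' @export
setClass("ResponseSet", contains = "SummarizedExperiment")

setValidity("ResponseSet", function(object) {
  if (!"responses" %in% SummarizedExperiment::assayNames(object))
    return("assay 'responses' is required")
  m <- SummarizedExperiment::assay(object, "responses")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    return("item and country identifiers are required as dimnames")
  if (anyDuplicated(rownames(m))) return("duplicate item ids")
  if (anyDuplicated(colnames(m))) return("duplicate country ids")
  obs <- m[!is.na(m)]
  if (!all(obs %in% c(0, 1)))
    return("observed entries must be binary (0/1)")
  if (any(rowSums(!is.na(m)) == 0))
    return(paste("item(s) with no observed responses:",
                 paste(rownames(m)[rowSums(!is.na(m)) == 0], collapse = ", ")))
  if (any(colSums(!is.na(m)) == 0))
    return(paste("country(ies) with no observed responses:",
                 paste(colnames(m)[colSums(!is.na(m)) == 0], collapse = ", ")))
  TRUE
})

#' Ground-truth parameters of the synthetic survey generator
#'
#' The one-factor probit measurement model X*_ij = lambda_j phi_i - alpha_j +
#' e_ij (e standard normal; x_ij = 1 iff X*_ij > 0) with per-item
#' discrimination lambda and difficulty alpha, per-country latent score phi,
#' and a completely-at-random missingness rate.
#'
#' @slot lambda named numeric, per-item discrimination.
#' @slot alpha named numeric, per-item difficulty.
#' @slot phi named numeric, per-country latent score.
#' @slot missingRate numeric in [0, 1).
#' @slot seed integer seed used by [simulateResponses()].
#' @export
setClass("TrueParameters",
         representation(lambda = "numeric", alpha = "numeric",
                        phi = "numeric", missingRate = "numeric",
                        seed = "integer"))

setValidity("TrueParameters", function(object) {
  if (length(object@lambda) != length(object@alpha))
    return("lambda and alpha must have the same length (one per item)")
  if (length(object@lambda) < 2L) return("at least 2 items are required")
  if (length(object@phi) < 2L) return("at least 2 countries are required")
  if (length(object@missingRate) != 1L ||
      object@missingRate < 0 || object@missingRate >= 1)
    return("missingRate must be a single value in [0, 1)")
  if (!all(is.finite(c(object@lambda, object@alpha, object@phi))))
    return("parameters must be finite")
  TRUE
})

#' Sampler configuration
#'
#' Priors, chain settings and identification constraint for the probit IRT
#' Gibbs sampler. The binary cut point is fixed at zero; difficulty enters as
#' the item intercept. Missing entries are excluded from the likelihood.
#'
#' @slot priorMean numeric(2): prior means of (lambda_j, alpha_j).
#' @slot priorSD numeric(2): prior standard deviations of (lambda_j, alpha_j).
#' @slot anchorItem item whose discrimination is constrained positive, to
#'   resolve the reflection invariance of the one-factor model; NA selects
#'   the per-index default (see [defaultAnchor()]).
#' @slot nBurnin,nIterations,thin chain settings; draws retained are the
#'   post-burn-in iterations at the given thinning.
#' @slot seed integer RNG seed.
#' @export
setClass("ModelConfig",
         representation(priorMean = "numeric", priorSD = "numeric",
                        anchorItem = "character", nBurnin = "integer",
                        nIterations = "integer", thin = "integer",
                        seed = "integer"))

setValidity("ModelConfig", function(object) {
  if (length(object@priorMean) != 2L || length(object@priorSD) != 2L)
    return("priorMean and priorSD must each have length 2: (lambda, alpha)")
  if (any(object@priorSD <= 0)) return("priorSD must be positive")
  if (object@nBurnin < 0L) return("nBurnin must be >= 0")
  if (object@nIterations <= object@nBurnin)
    return("nIterations must exceed nBurnin")
  if (object@thin < 1L) return("thin must be >= 1")
  TRUE
})

#' Retained posterior draws of the probit IRT model
#'
#' @slot lambda M-by-J matrix of discrimination draws (columns named by item).
#' @slot alpha M-by-J matrix of difficulty draws.
#' @slot phi M-by-N matrix of latent country-score draws (columns named by
#'   country). Rows are joint draws, so rank probabilities computed across a
#'   row honour the posterior correlation between countries.
#' @slot config the \linkS4class{ModelConfig} used.
#' @slot dataFingerprint hash of the response data the model was fitted to.
#' @export
setClass("PosteriorDraws",
         representation(lambda = "matrix", alpha = "matrix", phi = "matrix",
                        config = "ModelConfig", dataFingerprint = "character"))

setValidity("PosteriorDraws", function(object) {
  M <- nrow(object@lambda)
  if (nrow(object@alpha) != M || nrow(object@phi) != M)
    return("lambda, alpha and phi must have the same number of draws")
  if (ncol(object@lambda) != ncol(object@alpha))
    return("lambda and alpha must have one column per item")
  cfg <- object@config
  M_expected <- (cfg@nIterations - cfg@nBurnin) %/% cfg@thin
  if (M != M_expected)
    return(sprintf("draw count %d does not match (nIterations - nBurnin)/thin = %d",
                   M, M_expected))
  if (!all(is.finite(object@lambda)) || !all(is.finite(object@alpha)) ||
      !all(is.finite(object@phi)))
    return("draws must be finite")
  anchor <- object@config@anchorItem
  if (!is.na(anchor) && anchor %in% colnames(object@lambda) &&
      any(object@lambda[, anchor] <= 0))
    return("anchor item discrimination must be positive in every retained draw")
  TRUE
})

#' Posterior summary of item parameters and country scores
#'
#' @slot items data.frame, one row per item (mean/SD/5%/95% quantiles of
#'   discrimination and difficulty, probability of discrimination mass below
#'   zero, flag), ordered by posterior mean discrimination with flagged items
#'   last -- the layout of the published index tables.
#' @slot countries data.frame, one row per country: posterior mean and SD of
#'   phi and the equal-tailed 90% credible interval, ordered by posterior mean.
#' @slot flagThreshold probability threshold used for the weak-item flag.
#' @export
setClass("PosteriorSummary",
         representation(items = "data.frame", countries = "data.frame",
                        flagThreshold = "numeric"))

#' Cross-index comparison report
#'
#' @slot scores data.frame of countries present in both indices: country_id,
#'   score_x, score_y (posterior-mean latent scores).
#' @slot indexNames character(2): names of the x and y indices.
#' @slot rSquared squared Pearson correlation of the paired scores.
#' @slot cornerCount number of countries in the "forbidden" corner (x below
#'   its lower quantile, y above its upper quantile).
#' @slot xQuantile,yQuantile quantile levels defining the corner.
#' @slot xThreshold,yThreshold the score thresholds those quantiles map to.
#' @slot excluded countries excluded before comparison (user-supplied).
#' @export
setClass("ComparisonReport",
         representation(scores = "data.frame", indexNames = "character",
                        rSquared = "numeric", cornerCount = "integer",
                        xQuantile = "numeric", yQuantile = "numeric",
                        xThreshold = "numeric", yThreshold = "numeric",
                        excluded = "character"))

setValidity("ComparisonReport", function(object) {
  if (length(object@rSquared) != 1L ||
      object@rSquared < 0 || object@rSquared > 1 + 1e-12)
    return("rSquared must be a single value in [0, 1]")
  if (object@cornerCount < 0L) return("cornerCount must be >= 0")
  TRUE
})
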