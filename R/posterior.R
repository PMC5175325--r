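#' Summarize posterior draws into index tables
#'
#' Produces the per-item table (posterior mean, population SD, 5%/95%
#' quantiles of discrimination and difficulty, probability of discrimination
#' mass below zero, weak-item flag) and the per-country score table
#' (posterior mean, SD and equal-tailed 90% credible interval of phi). Items
#' are ordered by posterior mean discrimination, flagged items last --
#' the layout of the published index tables; countries are ordered by
#' posterior mean score. All quantities are exact empirical moments of the
#' retained draws (SDs use the divide-by-n convention), so the summary is
#' deterministic given the draws.
#'
#' @param draws a \linkS4class{PosteriorDraws} with at least 100 retained
#'   draws.
#' @param flagThreshold probability in (0, 0.5]: an item is flagged when the
#'   fraction of its discrimination draws below zero reaches this value.
#' @return a \linkS4class{PosteriorSummary}.
#' @export
summarizePosterior <- function(draws, flagThreshold = 0.10) {
  stopifnot(is(draws, "PosteriorDraws"))
  if (nDraws(draws) < 100L)
    stop("at least 100 retained draws are required", call. = FALSE)
  lam <- lambdaDraws(draws)
  alp <- alphaDraws(draws)
  phi <- phiDraws(draws)
  flagged <- flagNegativeMass(lam, flagThreshold)

  items <- data.frame(
    item_id = colnames(lam),
    lambda_mean = colMeans(lam),
    lambda_sd = apply(lam, 2, .sdPop),
    lambda_q05 = apply(lam, 2, quantile, probs = 0.05, names = FALSE),
    lambda_q95 = apply(lam, 2, quantile, probs = 0.95, names = FALSE),
    lambda_pr_neg = colMeans(lam < 0),
    alpha_mean = colMeans(alp),
    alpha_sd = apply(alp, 2, .sdPop),
    alpha_q05 = apply(alp, 2, quantile, probs = 0.05, names = FALSE),
    alpha_q95 = apply(alp, 2, quantile, probs = 0.95, names = FALSE),
    row.names = NULL)
  items$flagged <- items$item_id %in% flagged
  items <- items[order(items$flagged, -items$lambda_mean), , drop = FALSE]
  rownames(items) <- NULL

  ci <- apply(phi, 2, quantile, probs = c(0.05, 0.95), names = FALSE)
  countries <- data.frame(
    country_id = colnames(phi),
    phi_mean = colMeans(phi),
    phi_sd = apply(phi, 2, .sdPop),
    ci_lower = ci[1, ],
    ci_upper = ci[2, ],
    row.names = NULL)
  countries <- countries[order(-countries$phi_mean), , drop = FALSE]
  rownames(countries) <- NULL

  new("PosteriorSummary", items = items, countries = countries,
      flagThreshold = flagThreshold)
}

#' Flag items with posterior discrimination mass below zero
#'
#' An item is flagged when the fraction of its discrimination draws that are
#' negative reaches the threshold -- the "significant posterior mass to the
#' left of zero" rule used to set weakly-discriminating items apart (and
#' last) in the index tables.
#'
#' @param lambdaDraws M-by-J matrix of discrimination draws, columns named by
#'   item.
#' @param threshold probability in (0, 0.5].
#' @return character vector of flagged item ids.
#' @export
flagNegativeMass <- function(lambdaDraws, threshold = 0.10) {
  if (length(threshold) != 1L || threshold <= 0 || threshold > 0.5)
    stop("threshold must be in (0, 0.5]", call. = FALSE)
  frac <- colMeans(lambdaDraws < 0)
  colnames(lambdaDraws)[frac >= threshold]
}

#' Posterior probability that one country outscores another
#'
#' The fraction of joint retained draws in which phi_a > phi_b. Computing
#' this on joint draws honours the positive posterior correlation between
#' country scores that makes marginal credible intervals misleading for
#' comparisons. Exact ties (possible only with degenerate draws) count as
#' not-greater.
#'
#' @param draws a \linkS4class{PosteriorDraws}.
#' @param a,b distinct country ids.
#' @return probability in [0, 1].
#' @export
rankPairProbability <- function(draws, a, b) {
  stopifnot(is(draws, "PosteriorDraws"))
  phi <- phiDraws(draws)
  missing <- setdiff(c(a, b), colnames(phi))
  if (length(missing))
    stop("unknown country id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (identical(a, b)) stop("countries must be distinct", call. = FALSE)
  mean(phi[, a] > phi[, b])
}

#' Posterior probability that a group holds the extreme score
#'
#' The fraction of joint draws in which the highest (or lowest) latent score
#' over the comparison universe belongs to a country in \code{group}. With
#' \code{group} equal to the whole universe this is exactly 1, and singleton
#' probabilities over all countries sum to exactly 1 (each draw has one
#' argmax).
#'
#' @param draws a \linkS4class{PosteriorDraws}.
#' @param group non-empty character vector of country ids.
#' @param direction \code{"highest"} or \code{"lowest"}.
#' @param universe optional subset of countries to compare within (default:
#'   all countries in the draws). \code{group} must lie inside it.
#' @return probability in [0, 1].
#' @export
extremeProbability <- function(draws, group,
                               direction = c("highest", "lowest"),
                               universe = NULL) {
  stopifnot(is(draws, "PosteriorDraws"))
  direction <- match.arg(direction)
  phi <- phiDraws(draws)
  if (length(group) == 0L) stop("group must be non-empty", call. = FALSE)
  if (is.null(universe)) universe <- colnames(phi)
  missing <- setdiff(universe, colnames(phi))
  if (length(missing))
    stop("unknown country id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (length(bad <- setdiff(group, universe)))
    stop("group countries outside the comparison universe: ",
         paste(bad, collapse = ", "), call. = FALSE)
  sub <- phi[, universe, drop = FALSE]
  pick <- if (direction == "highest") max.col(sub, ties.method = "first")
          else max.col(-sub, ties.method = "first")
  mean(universe[pick] %in% group)
}

#' Chain diagnostics
#'
#' Geweke convergence z-scores and effective sample sizes for every retained
#' parameter chain (via the coda package). Chains with |z| > 3 or effective
#' size below 100 are counted and reported with a warning.
#'
#' @param draws a \linkS4class{PosteriorDraws} with at least 200 retained
#'   draws.
#' @param quiet suppress the warning (diagnostics are still returned).
#' @return data.frame with columns parameter, type, geweke_z, ess.
#' @export
chainDiagnostics <- function(draws, quiet = FALSE) {
  stopifnot(is(draws, "PosteriorDraws"))
  if (nDraws(draws) < 200L)
    stop("at least 200 retained draws are required", call. = FALSE)
  chains <- cbind(lambdaDraws(draws), alphaDraws(draws), phiDraws(draws))
  types <- rep(c("lambda", "alpha", "phi"),
               c(ncol(lambdaDraws(draws)), ncol(alphaDraws(draws)),
                 ncol(phiDraws(draws))))
  mc <- coda::mcmc(chains)
  z <- tryCatch(unname(coda::geweke.diag(mc)$z), error = function(e)
    rep(NA_real_, ncol(chains)))
  ess <- unname(coda::effectiveSize(mc))
  out <- data.frame(parameter = colnames(chains), type = types,
                    geweke_z = z, ess = ess, row.names = NULL)
  nbad <- sum(abs(out$geweke_z) > 3, na.rm = TRUE) + sum(out$ess < 100)
  if (nbad > 0 && !quiet)
    warning(nbad, " chain(s) show |Geweke z| > 3 or ESS < 100",
            call. = FALSE)
  out
}
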