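#' Ground-truth parameters for the synthetic generator
#'
#' @param lambda per-item discriminations (optionally named).
#' @param alpha per-item difficulties, same length as \code{lambda}.
#' @param phi per-country latent scores (optionally named).
#' @param missingRate completely-at-random missingness probability in [0, 1).
#' @param seed integer seed used by [simulateResponses()].
#' @return a \linkS4class{TrueParameters}.
#' @export
TrueParameters <- function(lambda, alpha, phi, missingRate = 0, seed = 1L) {
  J <- length(lambda)
  N <- length(phi)
  if (is.null(names(lambda))) names(lambda) <- sprintf("item%02d", seq_len(J))
  names(alpha) <- names(lambda)
  if (is.null(names(phi))) names(phi) <- sprintf("SY%03d", seq_len(N))
  obj <- new("TrueParameters", lambda = lambda, alpha = alpha, phi = phi,
             missingRate = as.numeric(missingRate), seed = as.integer(seed))
  validObject(obj)
  obj
}

#' Simulate a binary survey from the probit measurement model
#'
#' Generates x_ij = 1 iff lambda_j phi_i - alpha_j + e_ij > 0 with e_ij
#' standard normal, then masks entries missing independently at the truth's
#' missing rate. The marginal prevalence of item j over standard-normal
#' latent scores is pnorm(-alpha_j / sqrt(1 + lambda_j^2)). Output is
#' reproducible given the truth's seed, and the truth is returned unchanged
#' for recovery tests.
#'
#' @param truth a \linkS4class{TrueParameters} (its \code{phi} length sets
#'   the number of countries N, its \code{lambda}/\code{alpha} length the
#'   number of items J; N >= 2 and J >= 2 are required).
#' @return list with elements \code{responses} (a
#'   \linkS4class{ResponseSet}) and \code{truth} (the input).
#' @examples
#' tp <- TrueParameters(lambda = c(1, 1.5), alpha = c(0, 0.5),
#'                      phi = rnorm(10), seed = 7)
#' sim <- simulateResponses(tp)
#' responseMatrix(sim$responses)
#' @export
simulateResponses <- function(truth) {
  stopifnot(is(truth, "TrueParameters"))
  validObject(truth)   # enforces N >= 2, J >= 2, missingRate < 1
  N <- length(truth@phi)
  J <- length(truth@lambda)
  set.seed(truth@seed)
  eta <- tcrossprod(truth@phi, truth@lambda)              # N x J
  eta <- sweep(eta, 2, truth@alpha, "-")
  x <- (eta + matrix(rnorm(N * J), N, J) > 0) * 1L
  if (truth@missingRate > 0) {
    mask <- matrix(runif(N * J) < truth@missingRate, N, J)
    x[mask] <- NA_integer_
  }
  dimnames(x) <- list(names(truth@phi), names(truth@lambda))
  list(responses = ResponseSet(x), truth = truth)
}

#' Survey-scale synthetic scenario for one index
#'
#' Emulates the WHO country pharmaceutical situation survey at its published
#' scale: 78 countries and the item set of the requested index (14
#' infrastructure, 26 private-market, 18 public-quality items). True
#' discriminations are drawn uniform on [0.2, 2.2] and difficulties uniform
#' on [-1, 1.5], bracketing the posterior means reported for the three
#' published indices; latent scores are standard normal (the identification
#' convention of the sampler) and 5% of entries are missing completely at
#' random.
#'
#' @inheritParams indexItems
#' @param seed integer seed.
#' @param N number of countries (default 78).
#' @param missingRate missingness probability (default 0.05).
#' @return list with \code{responses} and \code{truth}, as
#'   [simulateResponses()].
#' @export
paperlikeScenario <- function(index = c("infrastructure", "private_market",
                                        "public_quality"),
                              seed = 1L, N = 78L, missingRate = 0.05) {
  index <- match.arg(index)
  N <- .assertCount(N, "N", min = 2L)
  items <- indexItems(loadRegistry(), index)
  J <- nrow(items)
  set.seed(seed)
  lambda <- runif(J, 0.2, 2.2)
  alpha <- runif(J, -1, 1.5)
  phi <- rnorm(N)
  names(lambda) <- names(alpha) <- items$item_id
  names(phi) <- sprintf("SY%03d", seq_len(N))
  truth <- TrueParameters(lambda = lambda, alpha = alpha, phi = phi,
                          missingRate = missingRate,
                          seed = as.integer(seed) + 1L)
  simulateResponses(truth)
}

#' Write generator ground truth to sidecar CSVs
#'
#' Two CSVs: \code{<stem>_items.csv} (item_id, lambda, alpha) and
#' \code{<stem>_countries.csv} (country_id, phi).
#'
#' @param truth a \linkS4class{TrueParameters}.
#' @param stem output path stem.
#' @return the two paths, invisibly.
#' @export
writeTruthCSV <- function(truth, stem) {
  stopifnot(is(truth, "TrueParameters"))
  pItems <- paste0(stem, "_items.csv")
  pCountries <- paste0(stem, "_countries.csv")
  write.csv(data.frame(item_id = names(truth@lambda),
                       lambda = unname(truth@lambda),
                       alpha = unname(truth@alpha)),
            pItems, row.names = FALSE, quote = FALSE)
  write.csv(data.frame(country_id = names(truth@phi),
                       phi = unname(truth@phi)),
            pCountries, row.names = FALSE, quote = FALSE)
  invisible(c(pItems, pCountries))
}
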