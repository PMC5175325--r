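#' Sampler configuration constructor
#'
#' Defaults: independent N(0, 2^2) priors on each discrimination and
#' difficulty (weakly informative; brackets the posterior means reported for
#' all three published indices), 20,000 burn-in sweeps of 120,000 iterations
#' thinned by 10, and the per-index default anchor when \code{anchorItem} is
#' left NA.
#'
#' @param priorMean,priorSD length-2 numeric: prior mean / SD of
#'   (lambda_j, alpha_j).
#' @param anchorItem item id whose discrimination is constrained positive;
#'   NA selects [defaultAnchor()] for a known index, otherwise the first item.
#' @param nBurnin,nIterations,thin chain settings.
#' @param seed integer RNG seed.
#' @return a \linkS4class{ModelConfig}.
#' @export
ModelConfig <- function(priorMean = c(0, 0), priorSD = c(2, 2),
                        anchorItem = NA_character_, nBurnin = 20000L,
                        nIterations = 120000L, thin = 10L, seed = 1L) {
  obj <- new("ModelConfig", priorMean = as.numeric(priorMean),
             priorSD = as.numeric(priorSD),
             anchorItem = as.character(anchorItem),
             nBurnin = as.integer(nBurnin),
             nIterations = as.integer(nIterations),
             thin = as.integer(thin), seed = as.integer(seed))
  validObject(obj)
  obj
}

#' Draw latent continuous responses given their means
#'
#' The data-augmentation step: for each observed binary response the latent
#' x*_ij is drawn from a unit-variance normal centred at the current linear
#' predictor, truncated to (0, Inf) when x = 1 and to (-Inf, 0] when x = 0.
#' Missing responses yield NA (no draw is consumed for them).
#'
#' @param x vector of responses in \{0, 1, NA\}.
#' @param mean vector of linear predictors, same length.
#' @return numeric vector of latent draws (NA where x is missing).
#' @export
augmentLatent <- function(x, mean) {
  if (length(x) != length(mean))
    stop("x and mean must have the same length", call. = FALSE)
  obs <- !is.na(x)
  if (!all(x[obs] %in% c(0, 1)))
    stop("x must contain only 0, 1 or NA", call. = FALSE)
  if (!all(is.finite(mean[obs])))
    stop("mean must be finite for observed entries", call. = FALSE)
  out <- rep(NA_real_, length(x))
  out[obs] <- .rtnormAtZero(x[obs] == 1, mean[obs])
  out
}

#' Full conditional of a latent country score
#'
#' With a standard-normal prior on phi_i and latent responses
#' x*_ij = lambda_j phi_i - alpha_j + e_ij, the full conditional of phi_i is
#' normal with variance 1 / (1 + sum_obs lambda_j^2) and mean
#' variance * sum_obs lambda_j (x*_ij + alpha_j), the sums running over the
#' country's observed items only.
#'
#' @param lambda,alpha per-item parameter vectors (length J).
#' @param xstar the country's latent responses (length J, NA where the
#'   response is missing). At least one entry must be observed.
#' @return list with \code{mean} and \code{variance}.
#' @export
conditionalPhi <- function(lambda, alpha, xstar) {
  stopifnot(length(lambda) == length(alpha), length(lambda) == length(xstar))
  obs <- !is.na(xstar)
  if (!any(obs))
    stop("at least one observed response is required", call. = FALSE)
  v <- 1 / (1 + sum(lambda[obs]^2))
  m <- v * sum(lambda[obs] * (xstar[obs] + alpha[obs]))
  list(mean = m, variance = v)
}

#' Full conditional of one item's (discrimination, difficulty) pair
#'
#' A conjugate Bayesian linear regression of the item's latent responses on
#' the design (phi_i, -1) with independent normal priors: returns the exact
#' bivariate-normal posterior mean and covariance of (lambda_j, alpha_j)
#' given the current latent scores.
#'
#' @param phi latent country scores (length N).
#' @param xstar the item's latent responses (length N, NA where missing);
#'   at least 2 observed entries are required.
#' @param priorMean,priorSD length-2 prior mean / SD of (lambda_j, alpha_j).
#' @return list with \code{mean} (length 2) and \code{cov} (2 x 2).
#' @export
conditionalItem <- function(phi, xstar, priorMean = c(0, 0),
                            priorSD = c(2, 2)) {
  stopifnot(length(phi) == length(xstar), length(priorMean) == 2L,
            length(priorSD) == 2L, all(priorSD > 0))
  obs <- !is.na(xstar)
  if (sum(obs) < 2L)
    stop("at least 2 observed responses are required", call. = FALSE)
  w <- phi[obs]
  y <- xstar[obs]
  priorPrec <- 1 / priorSD^2
  # W = cbind(w, -1):  W'W = [sum w^2, -sum w; -sum w, n]
  P <- matrix(c(sum(w^2) + priorPrec[1], -sum(w),
                -sum(w), length(y) + priorPrec[2]), 2L, 2L)
  b <- c(sum(w * y) + priorPrec[1] * priorMean[1],
         -sum(y) + priorPrec[2] * priorMean[2])
  V <- solve(P)
  list(mean = as.numeric(V %*% b), cov = V)
}

# One draw of (lambda_j, alpha_j) from its bivariate-normal conditional;
# when anchored, lambda is drawn from its truncated-positive marginal and
# alpha from the exact conditional given lambda.
.drawItem <- function(cond, anchored) {
  m <- cond$mean
  V <- cond$cov
  if (anchored) {
    lam <- .rtnormPositive(m[1], sqrt(V[1, 1]))
    amean <- m[2] + V[1, 2] / V[1, 1] * (lam - m[1])
    asd <- sqrt(max(V[2, 2] - V[1, 2]^2 / V[1, 1], 0))
    c(lam, rnorm(1L, amean, asd))
  } else {
    m + drop(rnorm(2L) %*% chol(V))
  }
}

#' Fit the one-factor binary probit IRT model by Gibbs sampling
#'
#' Data-augmented Gibbs sampling for the measurement model
#' X*_i = Lambda phi_i + e_i with a single cut point fixed at zero (all items
#' binary), standard-normal latent scores, and independent normal priors on
#' each item's (discrimination, difficulty). Each sweep (i) draws all latent
#' responses by [augmentLatent()], (ii) draws every country score from
#' [conditionalPhi()], and (iii) draws every item's parameter pair from
#' [conditionalItem()], with the anchor item's discrimination drawn from its
#' conditional truncated to (0, Inf). Missing responses are excluded from
#' every conditional sum. Runs are fully reproducible given the config seed.
#'
#' @param responses a \linkS4class{ResponseSet}.
#' @param config a \linkS4class{ModelConfig}.
#' @param verbose log progress every 10,000 sweeps.
#' @return a \linkS4class{PosteriorDraws}.
#' @examples
#' sim <- paperlikeScenario("infrastructure", seed = 11)
#' cfg <- ModelConfig(nBurnin = 100, nIterations = 600, thin = 1, seed = 5)
#' draws <- fitIRT(sim$responses, cfg)
#' draws
#' @export
fitIRT <- function(responses, config = ModelConfig(), verbose = FALSE) {
  stopifnot(is(responses, "ResponseSet"), is(config, "ModelConfig"))
  validObject(responses)
  validObject(config)
  x <- responseMatrix(responses)        # N x J
  N <- nrow(x)
  J <- ncol(x)
  ids <- colnames(x)
  anchor <- config@anchorItem
  if (is.na(anchor)) {
    anchor <- .matchedIndexAnchor(ids)
    config@anchorItem <- anchor
  }
  if (!anchor %in% ids)
    stop("anchor item '", anchor, "' is not in the item set", call. = FALSE)
  j0 <- match(anchor, ids)
  if (any(colSums(!is.na(x)) < 2L))
    stop("every item needs at least 2 observed responses", call. = FALSE)

  O <- !is.na(x)
  Onum <- O * 1
  xv <- as.vector(x)
  fingerprint <- .fingerprintMatrix(x)

  set.seed(config@seed)
  # initial state: anchor-positive loadings, difficulty from item prevalence,
  # scores from standardized row means
  pbar <- pmin(pmax(colMeans(x, na.rm = TRUE), 0.02), 0.98)
  alpha <- -qnorm(pbar)
  lambda <- rep(1, J)
  rmeans <- rowMeans(x, na.rm = TRUE)
  phi <- if (.sdPop(rmeans) > 0) (rmeans - mean(rmeans)) / .sdPop(rmeans)
         else rep(0, N)

  M <- (config@nIterations - config@nBurnin) %/% config@thin
  lamDraws <- matrix(NA_real_, M, J, dimnames = list(NULL, ids))
  alphaDraws <- matrix(NA_real_, M, J, dimnames = list(NULL, ids))
  phiDraws <- matrix(NA_real_, M, N, dimnames = list(NULL, rownames(x)))
  pm <- config@priorMean
  ps <- config@priorSD
  kept <- 0L

  for (iter in seq_len(config@nIterations)) {
    eta <- tcrossprod(phi, lambda)
    eta <- sweep(eta, 2, alpha, "-")
    xstar <- matrix(augmentLatent(xv, as.vector(eta)), N, J)

    A <- xstar + matrix(alpha, N, J, byrow = TRUE)
    A[!O] <- 0
    v <- 1 / (1 + drop(Onum %*% lambda^2))
    phi <- rnorm(N, v * drop(A %*% lambda), sqrt(v))

    for (j in seq_len(J)) {
      cond <- conditionalItem(phi, xstar[, j], pm, ps)
      th <- .drawItem(cond, anchored = (j == j0))
      lambda[j] <- th[1]
      alpha[j] <- th[2]
    }

    if (!all(is.finite(lambda)) || !all(is.finite(alpha)) ||
        !all(is.finite(phi)))
      stop("non-finite sampler state at iteration ", iter, call. = FALSE)

    if (iter > config@nBurnin &&
        (iter - config@nBurnin) %% config@thin == 0L) {
      kept <- kept + 1L
      lamDraws[kept, ] <- lambda
      alphaDraws[kept, ] <- alpha
      phiDraws[kept, ] <- phi
    }
    if (verbose && iter %% 10000L == 0L)
      message("  sweep ", iter, "/", config@nIterations)
  }

  out <- new("PosteriorDraws", lambda = lamDraws, alpha = alphaDraws,
             phi = phiDraws, config = config, dataFingerprint = fingerprint)
  validObject(out)
  out
}

# Anchor default when the item set matches one of the registered indices;
# otherwise the first item.
.matchedIndexAnchor <- function(ids) {
  reg <- tryCatch(loadRegistry(), error = function(e) NULL)
  if (!is.null(reg)) {
    for (ix in .INDEX_NAMES) {
      if (identical(sort(indexItems(reg, ix)$item_id), sort(ids)))
        return(defaultAnchor(ix))
    }
  }
  ids[1]
}

#' Gibbs draws of one latent score with item parameters held fixed
#'
#' Alternates the data-augmentation and score-update steps for a single
#' response pattern, keeping (lambda, alpha) fixed. Used to check the sampler
#' against one-dimensional quadrature of the probit likelihood.
#'
#' @inheritParams conditionalPhi
#' @param x binary response pattern (0/1/NA), length J.
#' @param nDraws retained draws after \code{nBurnin}.
#' @param nBurnin burn-in sweeps.
#' @param seed integer RNG seed.
#' @return numeric vector of phi draws.
#' @export
samplePhiFixedItems <- function(x, lambda, alpha, nDraws = 50000L,
                                nBurnin = 500L, seed = 1L) {
  stopifnot(length(x) == length(lambda), length(lambda) == length(alpha))
  obs <- !is.na(x)
  if (!any(obs)) stop("at least one observed response is required",
                      call. = FALSE)
  x <- x[obs]
  lambda <- lambda[obs]
  alpha <- alpha[obs]
  set.seed(seed)
  phi <- 0
  v <- 1 / (1 + sum(lambda^2))
  sv <- sqrt(v)
  out <- numeric(nDraws)
  for (it in seq_len(nBurnin + nDraws)) {
    xstar <- .rtnormAtZero(x == 1, lambda * phi - alpha)
    phi <- rnorm(1L, v * sum(lambda * (xstar + alpha)), sv)
    if (it > nBurnin) out[it - nBurnin] <- phi
  }
  out
}

#' Posterior mean of a latent score by Gauss-Hermite quadrature
#'
#' Independent oracle for the sampler: integrates phi against the probit
#' likelihood of a response pattern times the standard-normal prior using
#' Gauss-Hermite quadrature.
#'
#' @inheritParams samplePhiFixedItems
#' @param nNodes number of quadrature nodes.
#' @return the posterior mean of phi.
#' @export
phiPosteriorQuadrature <- function(x, lambda, alpha, nNodes = 101L) {
  obs <- !is.na(x)
  if (!any(obs)) stop("at least one observed response is required",
                      call. = FALSE)
  x <- x[obs]
  lambda <- lambda[obs]
  alpha <- alpha[obs]
  gh <- pracma::gaussHermite(nNodes)
  phi <- sqrt(2) * gh$x                 # standard-normal change of variables
  logL <- vapply(phi, function(p) {
    q <- lambda * p - alpha
    sum(pnorm(ifelse(x == 1, q, -q), log.p = TRUE))
  }, numeric(1))
  w <- gh$w * exp(logL - max(logL))
  sum(w * phi) / sum(w)
}
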