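# Build a PosteriorDraws object directly from given draw matrices, so
# identities can be checked on constructed chains.
makeDraws <- function(phi, lambda = NULL, alpha = NULL, anchor = "i1") {
  M <- nrow(phi)
  if (is.null(lambda))
    lambda <- matrix(1, M, 2, dimnames = list(NULL, c("i1", "i2")))
  if (is.null(alpha))
    alpha <- matrix(0, M, 2, dimnames = list(NULL, c("i1", "i2")))
  cfg <- ModelConfig(anchorItem = anchor, nBurnin = 0L, nIterations = M,
                     thin = 1L, seed = 1L)
  new("PosteriorDraws", lambda = lambda, alpha = alpha, phi = phi,
      config = cfg, dataFingerprint = "test")
}

test_that("summarizePosterior reports exact empirical moments", {
  M <- 200
  phi <- cbind(A = rep(2, M), B = rep(-1, M), C = rep(0.5, M))
  lam <- cbind(i1 = rep(c(-1, 1), M / 2), i2 = rep(1.5, M))
  alp <- cbind(i1 = rep(0.2, M), i2 = rep(-0.3, M))
  s <- summarizePosterior(makeDraws(phi, lam, alp, anchor = "i2"),
                          flagThreshold = 0.10)
  it <- itemSummary(s)
  # two-point chain {-1, +1}: mean 0, population SD 1
  r1 <- it[it$item_id == "i1", ]
  expect_equal(r1$lambda_mean, 0)
  expect_equal(r1$lambda_sd, 1)
  expect_equal(r1$lambda_pr_neg, 0.5)
  expect_true(r1$flagged)
  # constant chain: mean c, SD 0
  r2 <- it[it$item_id == "i2", ]
  expect_equal(r2$lambda_mean, 1.5)
  expect_equal(r2$lambda_sd, 0)
  expect_false(r2$flagged)
  # flagged items are ordered last
  expect_equal(it$item_id, c("i2", "i1"))
  # country scores ordered by posterior mean, CI contains the mean
  co <- countryScores(s)
  expect_equal(co$country_id, c("A", "C", "B"))
  expect_true(all(co$ci_lower <= co$phi_mean & co$phi_mean <= co$ci_upper))
  # too few draws is a domain error
  expect_error(summarizePosterior(makeDraws(phi[1:99, , drop = FALSE],
                                            lam[1:99, ], alp[1:99, ],
                                            anchor = "i2")),
               "100")
})

test_that("flagNegativeMass thresholds the negative-mass fraction", {
  lam <- cbind(pos = abs(rnorm(100)) + 0.1,
               half = rep(c(-1, 1), 50),
               mild = c(rep(-1, 12), rep(1, 88)))
  expect_equal(flagNegativeMass(lam, 0.10), c("half", "mild"))
  expect_equal(flagNegativeMass(lam, 0.5), "half")
  expect_equal(flagNegativeMass(lam, 0.13), "half")
  expect_error(flagNegativeMass(lam, 0.6), "0.5")
  expect_error(flagNegativeMass(lam, 0), "0.5")
})

test_that("pairwise rank probabilities honour joint draws and sum to one", {
  set.seed(31)
  M <- 4000
  phi <- cbind(A = rnorm(M, 1), B = rnorm(M, 0.8), C = rnorm(M, -1))
  d <- makeDraws(phi)
  # dominance
  dDom <- makeDraws(cbind(A = rexp(200) + 1, B = -rexp(200)))
  expect_equal(rankPairProbability(dDom, "A", "B"), 1.0)
  # exchangeable labels: probability one half within Monte-Carlo error
  phiEx <- cbind(A = phi[, "A"], B = sample(phi[, "A"]))
  expect_lt(abs(rankPairProbability(makeDraws(phiEx), "A", "B") - 0.5),
            3 * 0.5 / sqrt(M))
  # complementarity holds exactly for continuous draws
  expect_equal(rankPairProbability(d, "A", "B") +
                 rankPairProbability(d, "B", "A"), 1.0)
  expect_error(rankPairProbability(d, "A", "Z"), "Z")
  expect_error(rankPairProbability(d, "A", "A"), "distinct")
})

test_that("extreme probabilities are exact set functions of the draws", {
  set.seed(17)
  M <- 3000
  phi <- cbind(A = rnorm(M), B = rnorm(M), C = rnorm(M), D = rnorm(M, -2))
  d <- makeDraws(phi)
  # whole universe: certainty
  expect_equal(extremeProbability(d, colnames(phi), "highest"), 1.0)
  # singleton probabilities partition the draws exactly
  singles <- vapply(colnames(phi), function(cc)
    extremeProbability(d, cc, "highest"), numeric(1))
  expect_equal(sum(singles), 1.0)
  # three exchangeable countries: each has the top score about 1/3 of draws
  expect_lt(abs(extremeProbability(d, "A", "highest",
                                   universe = c("A", "B", "C")) - 1 / 3),
            3 * sqrt(2 / 9) / sqrt(M))
  # group membership adds up with the sub-universe argument
  pAB <- extremeProbability(d, c("A", "B"), "lowest",
                            universe = c("A", "B", "C"))
  expect_equal(pAB + extremeProbability(d, "C", "lowest",
                                        universe = c("A", "B", "C")), 1.0)
  expect_error(extremeProbability(d, character(0), "highest"), "non-empty")
  expect_error(extremeProbability(d, "A", "highest", universe = c("B", "C")),
               "universe")
})

test_that("diagnostics separate white-noise from trending chains", {
  set.seed(5)
  M <- 1000
  phi <- cbind(A = rnorm(M), B = seq(0, 5, length.out = M))
  d <- makeDraws(phi,
                 lambda = matrix(rnorm(2 * M), M, 2,
                                 dimnames = list(NULL, c("i1", "i2"))) + 5,
                 alpha = matrix(rnorm(2 * M), M, 2,
                                dimnames = list(NULL, c("i1", "i2"))))
  expect_warning(dg <- chainDiagnostics(d), "Geweke|ESS")
  white <- dg[dg$parameter == "A", ]
  ramp <- dg[dg$parameter == "B", ]
  # independent draws: effective size near the draw count
  expect_gt(white$ess, 0.8 * M)
  expect_lt(abs(white$geweke_z), 3)
  # linear ramp: unambiguous mean drift
  expect_gt(abs(ramp$geweke_z), 3)
  short <- makeDraws(phi[1:100, , drop = FALSE],
                     lambda = matrix(1, 100, 2,
                                     dimnames = list(NULL, c("i1", "i2"))),
                     alpha = matrix(0, 100, 2,
                                    dimnames = list(NULL, c("i1", "i2"))))
  expect_error(chainDiagnostics(short), "200")
})

test_that("summaries of a real fit recover the generating truth", {
  fit <- sharedFit()
  s <- summarizePosterior(fit$draws)
  it <- itemSummary(s)
  truth <- fit$sim$truth
  # posterior means within 3 posterior SDs of truth for >= 90% of items
  zLam <- abs(it$lambda_mean - truth@lambda[it$item_id]) /
    pmax(it$lambda_sd, 1e-9)
  zAlp <- abs(it$alpha_mean - truth@alpha[it$item_id]) /
    pmax(it$alpha_sd, 1e-9)
  expect_gte(mean(c(zLam, zAlp) <= 3), 0.9)
  # items are ordered by posterior mean discrimination (flagged last)
  unflagged <- it[!it$flagged, ]
  expect_true(all(diff(unflagged$lambda_mean) <= 0))
})
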