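# Shared fixtures, built in code.

# Small deterministic response matrix (no missing entries) for plumbing tests.
tinyResponses <- function(N = 6, J = 4, seed = 99) {
  set.seed(seed)
  m <- matrix(rbinom(N * J, 1, 0.5), N, J,
              dimnames = list(sprintf("C%02d", seq_len(N)),
                              sprintf("it%02d", seq_len(J))))
  # guarantee variation in every row/column
  m[1, ] <- 1L
  m[2, ] <- 0L
  m[, 1] <- c(rep(1L, N - 1), 0L)
  ResponseSet(m)
}

# One moderate infrastructure-scale fit, computed once per test run and
# shared across test files.
sharedFitEnv <- new.env()
sharedFit <- function() {
  if (is.null(sharedFitEnv$draws)) {
    sharedFitEnv$sim <- paperlikeScenario("infrastructure", seed = 11)
    sharedFitEnv$draws <- fitIRT(
      sharedFitEnv$sim$responses,
      ModelConfig(nBurnin = 500, nIterations = 3500, thin = 3, seed = 5))
  }
  list(sim = sharedFitEnv$sim, draws = sharedFitEnv$draws)
}

# Independent brute-force coding of the inspection composite, transcribed
# directly from the stated rule (not via buildInspectionsComposite).
bruteForceComposite <- function(m, r, d, variant) {
  if (any(is.na(c(m, r, d)))) return(NA_integer_)
  if (variant == "regular") {
    as.integer((m <= 3 && r <= 3 && d <= 3) || m <= 1 || r <= 1 || d <= 1)
  } else {
    as.integer(m <= 1 && r <= 1 && d <= 1)
  }
}

# A raw survey data.frame for one index with given response matrix.
rawSurveyFrame <- function(m) {
  data.frame(country = rownames(m), m, check.names = FALSE,
             stringsAsFactors = FALSE)
}
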