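# Internal helpers: truncated-normal inversion sampling and a small
# self-contained FNV-1a hash for run-manifest fingerprints.

# Draw from N(mean, 1) truncated to (0, Inf) (sign = 1) or (-Inf, 0]
# (sign = 0), by inverse-CDF. Probabilities are clamped away from 0/1 so the
# draw stays finite even when the untruncated mean is far from the boundary
# (|qnorm(1 - 1e-16)| ~ 8.2).
.rtnormAtZero <- function(sign1, mean) {
  p0 <- pnorm(0, mean = mean)          # mass below the cut point
  u <- runif(length(mean))
  q <- ifelse(sign1, p0 + u * (1 - p0), u * p0)
  q <- pmin(pmax(q, 1e-16), 1 - 1e-16)
  qnorm(q, mean = mean)
}

# Draw from N(mean, sd^2) truncated to (0, Inf); scalar use in the anchor
# update.
.rtnormPositive <- function(mean, sd) {
  p0 <- pnorm(0, mean = mean, sd = sd)
  q <- pmin(pmax(p0 + runif(1L) * (1 - p0), 1e-16), 1 - 1e-16)
  qnorm(q, mean = mean, sd = sd)
}

# FNV-1a 32-bit over the UTF-8 bytes of a string; returns 8 hex chars.
# 32-bit modular multiply done in doubles via 16-bit splits (exact).
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\x1f")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    lo <- h %% 2^16
    h <- (h - lo) + bitwXor(as.integer(lo), b)        # xor touches low byte only
    lo <- h %% 2^16
    hi <- (h %/% 2^16) %% 2^16
    h <- ((lo * p) %% 2^32 + ((hi * p) %% 2^16) * 2^16) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 2^16), as.integer(h %% 2^16))
}

# Fingerprint of a response matrix (values + dimnames), deterministic across
# sessions.
.fingerprintMatrix <- function(m) {
  .fnv1a(c(rownames(m), colnames(m),
           ifelse(is.na(m), "NA", format(m, trim = TRUE))))
}

# Population (divide-by-n) standard deviation: the convention used in all
# posterior summaries.
.sdPop <- function(x) sqrt(mean((x - mean(x))^2))

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x != as.integer(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min),
         call. = FALSE)
  as.integer(x)
}
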