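# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Deterministic child seed for recursive/bootstrap procedures; kept < 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + 1000003 * as.numeric(index)) %% 2147483629) + 1L
}

# Weighted variance with reliability weights; equals var() when w is constant.
weighted_var <- function(x, w) {
  sw <- sum(w)
  if (sw <= 0) {
    return(NA_real_)
  }
  m <- sum(w * x) / sw
  denom <- sw - sum(w^2) / sw
  if (denom <= 0) {
    return(0)
  }
  sum(w * (x - m)^2) / denom
}

# Vectorized Welch two-sample t-test on rows of two matrices (genes x samples).
# Returns two-sided p-values; degenerate rows (zero variance in both groups)
# give p = 1 when means agree and p = 0 otherwise.
welch_test_rows <- function(a, b) {
  na <- ncol(a)
  nb <- ncol(b)
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * stats::pt(-abs(tt), df)
  zero <- se2 == 0
  if (any(zero)) {
    p[zero] <- ifelse(ma[zero] == mb[zero], 1, 0)
  }
  p[!is.finite(p)] <- 1
  p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
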