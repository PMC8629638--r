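# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
# Kinds are pinned so seeded output is identical across platforms and R
# versions that support the Rejection sampler.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single non-missing integer.")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

# Linear-interpolation (type 7) quantile, the convention pinned for all cost
# fences and IQRs in this package.
quantile7 <- function(x, probs) {
  unname(quantile(x, probs = probs, type = 7, names = FALSE))
}

iqr7 <- function(x) {
  q <- quantile7(x, c(0.25, 0.75))
  q[2] - q[1]
}

# Stirling number of the second kind S(n, k), as a double. Used for the
# Bonferroni multiplier of free (nominal) predictors; n stays small (number
# of categories of one predictor) so doubles are exact.
stirling2 <- function(n, k) {
  if (k < 0 || k > n) return(0)
  if (k == 0) return(as.numeric(n == 0))
  s <- matrix(0, nrow = n + 1, ncol = k + 1)
  s[1, 1] <- 1
  for (i in seq_len(n)) {
    for (j in seq_len(min(i, k))) {
      s[i + 1, j + 1] <- j * s[i, j + 1] + s[i, j]
    }
  }
  s[n + 1, k + 1]
}
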