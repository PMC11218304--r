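# Internal numeric and bookkeeping helpers.

# Elementwise log(exp(x) + exp(y)) without overflow; -Inf + -Inf stays -Inf.
lse2 <- function(x, y) {
  m <- pmax(x, y)
  out <- m + log(exp(x - m) + exp(y - m))
  out[m == -Inf] <- -Inf
  out
}

logsumexp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

# Convolve two log-probability vectors over contiguous integer supports.
conv_log <- function(la, lb) {
  na <- length(la)
  nb <- length(lb)
  if (na == 1L) return(la + lb)
  if (nb == 1L) return(lb + la)
  out <- rep(-Inf, na + nb - 1L)
  for (i in seq_len(na)) {
    idx <- i:(i + nb - 1L)
    out[idx] <- lse2(out[idx], la[i] + lb)
  }
  out
}

# Integer apportionment by largest remainder: counts sum to `total` exactly.
apportion <- function(total, fractions) {
  raw <- total * fractions
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

# Deterministic per-stage seed derivation from a single global seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

`%||%` <- rlang::`%||%`

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
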