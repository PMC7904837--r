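# Internal numerical and plumbing helpers.

#' @keywords internal
"_PACKAGE"

## log-sum-exp in base 2 over the columns of a matrix of log2 values:
## returns, per row, log2(sum_k 2^x[, k]). -Inf entries are handled exactly.
row_lse2 <- function(x) {
  m <- apply(x, 1L, max)
  out <- m
  ok <- is.finite(m)
  if (any(ok)) {
    xs <- x[ok, , drop = FALSE] - m[ok]
    out[ok] <- m[ok] + log2(rowSums(2^xs))
  }
  out
}

lse2 <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log2(sum(2^(x - m)))
}

## Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
## caller's RNG state afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", globalenv(), mode = "integer"))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

## Classed errors so callers can discriminate failure modes.
dynmi_stop <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "dynmi_error", "error", "condition")))
}

## Column-normalize a non-negative matrix; all-zero columns become uniform.
normalize_columns <- function(m) {
  s <- colSums(m)
  zero <- s <= 0
  if (any(zero)) {
    m[, zero] <- 1
    s[zero] <- nrow(m)
  }
  sweep(m, 2L, s, "/")
}

## Random column-stochastic matrix (columns i.i.d. flat Dirichlet).
random_stochastic <- function(nrow, ncol) {
  normalize_columns(matrix(stats::rexp(nrow * ncol), nrow, ncol))
}

## Shannon entropy (bits) of a probability vector; 0 * log 0 = 0.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

## KL(p || q) in bits. Assumes q > 0 wherever p > 0.
kl_bits <- function(p, q) {
  i <- p > 0
  sum(p[i] * (log2(p[i]) - log2(q[i])))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
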