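# internal helpers shared across modules

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber the
# session RNG.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Row/column Gaussian smoother matrices; smoothing a matrix M is
# S_r %*% M %*% t(S_c).  Rows are normalized so edges keep unit mass.
smoother_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  w <- stats::dnorm(abs(outer(seq_len(n), seq_len(n), "-")), sd = sigma)
  w / rowSums(w)
}

# Seeded smooth Gaussian random field, standardized to mean 0 / sd 1.
smooth_noise <- function(n_rows, n_cols, sigma, seed) {
  z <- with_seed(seed, matrix(stats::rnorm(n_rows * n_cols), n_rows, n_cols))
  s <- smoother_matrix(n_rows, sigma) %*% z %*% t(smoother_matrix(n_cols, sigma))
  (s - mean(s)) / stats::sd(s)
}
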