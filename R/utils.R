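#' Derive a reproducible child seed from a master seed and labels
#'
#' Deterministically hashes a master integer seed together with an arbitrary
#' sequence of string/integer labels into a new seed. Used throughout the
#' pipeline so that a single global seed yields independent, reproducible
#' random streams per stage, group, and restart without manual bookkeeping.
#'
#' @param seed integer master seed.
#' @param ... labels (coerced to character) identifying the consumer.
#' @return an integer seed in `[1, 2^31 - 39]`.
#' @export
derive_seed <- function(seed, ...) {
  labs <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  m <- 2147483587 # large prime < 2^31
  h <- 0
  if (nzchar(labs)) {
    for (ch in utf8ToInt(labs)) h <- (h * 31 + ch) %% m
  }
  as.integer((abs(as.numeric(seed)) %% m * 48271 + h) %% m) + 1L
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Stationary distribution of a row-stochastic matrix (left eigenvector for
# eigenvalue 1, renormalized to a probability vector).
stationary_distribution <- function(P) {
  K <- nrow(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

bs_log <- function(stage, msg, verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
  }
  invisible(NULL)
}
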