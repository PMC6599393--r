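# Independent oracles and fixture builders. Nothing here calls the package's
# inference code paths: the brute-force HMM oracle enumerates every state
# path directly from the model definition.

lse <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }

# Exhaustive-path HMM oracle for tiny instances: log-likelihood, posteriors,
# and the maximal path log-probability, by summing over all K^T paths.
bf_hmm <- function(params, obs) {
  K <- params$K
  T_ <- nrow(obs)
  C <- ncol(obs)
  ld <- vapply(seq_len(K), function(k)
    rowSums(matrix(dnorm(obs,
                         matrix(params$means[k, ], T_, C, byrow = TRUE),
                         matrix(sqrt(params$vars[k, ]), T_, C, byrow = TRUE),
                         log = TRUE), T_, C)),
    numeric(T_))
  ld <- matrix(ld, T_, K)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  lp <- apply(paths, 1L, function(p) {
    l <- log(params$init[p[1L]]) + ld[1L, p[1L]]
    if (T_ > 1L) for (t in 2:T_) l <- l + log(params$trans[p[t - 1L], p[t]]) + ld[t, p[t]]
    l
  })
  ll <- lse(lp)
  w <- exp(lp - ll)
  post <- vapply(seq_len(K), function(k) colSums(w * (paths == k)), numeric(T_))
  list(loglik = ll, posteriors = matrix(post, T_, K), max_path_logprob = max(lp))
}

# Log-probability of a given path under the model (for checking Viterbi
# optimality without relying on the oracle's tie ordering).
path_logprob <- function(params, obs, path) {
  T_ <- nrow(obs)
  l <- log(params$init[path[1L]]) +
    sum(dnorm(obs[1L, ], params$means[path[1L], ], sqrt(params$vars[path[1L], ]), log = TRUE))
  if (T_ > 1L) for (t in 2:T_)
    l <- l + log(params$trans[path[t - 1L], path[t]]) +
      sum(dnorm(obs[t, ], params$means[path[t], ], sqrt(params$vars[path[t], ]), log = TRUE))
  l
}

rand_hmm <- function(K, C) {
  init <- runif(K) + 0.1; init <- init / sum(init)
  trans <- matrix(runif(K * K) + 0.1, K); trans <- trans / rowSums(trans)
  hmm_params(init, trans, matrix(rnorm(K * C), K, C),
             matrix(runif(K * C, 0.5, 2), K, C))
}

# Small fitted four-group world shared by alignment/dynamics tests.
make_tiny_fitted <- function(K = 3L, C = 10L, runs = 8L, Tlen = c(60L, 90L),
                             seed = 11L, jitter = 0, n_restarts = 2L) {
  cfg <- gt_config(K = K, C = C, runs_per_group = rep(runs, 4L),
                   run_length_range = Tlen,
                   on_diag_by_group = rep(0.53, 4L),
                   subject_tpm_jitter_sd = rep(jitter, 4L), seed = seed)
  co <- simulate_cohort(cfg)
  z <- lapply(co$runs, zscore_run)
  groups <- assemble_groups(z, co$phenotypes)
  fits <- lapply(groups, function(gd)
    em_fit(group_data(gd), gd$boundaries$length, K = K, n_restarts = n_restarts,
           max_iter = 100L, seed = seed))
  list(cfg = cfg, cohort = co, groups = groups, fits = fits)
}

run_python <- function(code, input = NULL) {
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  on.exit(unlink(script))
  out <- suppressWarnings(system2("python", script, stdout = TRUE, stderr = TRUE,
                                  input = input))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("python oracle failed: ", paste(out, collapse = "\n"))
  out
}
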