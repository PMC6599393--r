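VAR_FLOOR <- 1e-6

#' Construct Gaussian-emission HMM parameters
#'
#' @param init length-K initial state distribution (simplex).
#' @param trans K x K row-stochastic transition matrix.
#' @param means K x C matrix of per-state emission means (one "mean activation
#'   map" per state, in z-scored signal units).
#' @param vars for diagonal covariance, a K x C matrix of per-state,
#'   per-channel variances; for full covariance, a C x C x K array of SPD
#'   covariance matrices.
#' @param covariance `"diagonal"` or `"full"`.
#' @return an object of class `hmm_params`.
#' @export
hmm_params <- function(init, trans, means, vars,
                       covariance = c("diagonal", "full")) {
  covariance <- match.arg(covariance)
  init <- as.numeric(init)
  trans <- as.matrix(trans)
  means <- as.matrix(means)
  K <- length(init)
  C <- ncol(means)
  stopifnot(K >= 1L, nrow(means) == K, nrow(trans) == K, ncol(trans) == K)
  if (abs(sum(init) - 1) > 1e-12) stop("initial probabilities must sum to 1")
  if (any(init < 0)) stop("initial probabilities must be nonnegative")
  rs <- rowSums(trans)
  if (any(abs(rs - 1) > 1e-12)) stop("every transition-matrix row must sum to 1")
  if (any(trans < 0)) stop("transition probabilities must be nonnegative")
  if (covariance == "diagonal") {
    vars <- as.matrix(vars)
    stopifnot(nrow(vars) == K, ncol(vars) == C)
    if (any(vars <= 0)) stop("variances must be positive")
  } else {
    stopifnot(length(dim(vars)) == 3L, dim(vars)[1L] == C, dim(vars)[3L] == K)
  }
  structure(list(K = K, C = C, init = init, trans = trans, means = means,
                 vars = vars, covariance = covariance),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("<hmm_params> K=%d states, C=%d channels, %s covariance\n",
              x$K, x$C, x$covariance))
  invisible(x)
}

# Per-state log emission densities, T x K. Diagonal case is fully vectorized
# (one T x C by C x K product); full covariance loops over states.
emission_logdens <- function(params, obs) {
  K <- params$K; C <- params$C
  if (ncol(obs) != C)
    stop(sprintf("channel-count mismatch: observations have %d channels, model has %d",
                 ncol(obs), C))
  if (params$covariance == "diagonal") {
    V <- params$vars
    if (any(!is.finite(V)) || any(V <= 0)) {
      bad <- which(!is.finite(V) | V <= 0, arr.ind = TRUE)[1L, ]
      stop(sprintf("non-positive/non-finite variance for state %d, channel %d",
                   bad[1L], bad[2L]))
    }
    IV <- t(1 / V)                                   # C x K
    MIV <- t(params$means) * IV                      # C x K
    const <- colSums(t(params$means)^2 * IV) + rowSums(log(V)) + C * log(2 * pi)
    Q <- obs^2 %*% IV - 2 * (obs %*% MIV)
    ld <- -0.5 * sweep(Q, 2L, const, "+")
  } else {
    T_ <- nrow(obs)
    ld <- matrix(NA_real_, T_, K)
    for (k in seq_len(K)) {
      S <- params$vars[, , k]
      ch <- tryCatch(chol(S), error = function(e)
        stop("covariance for state ", k, " is not positive definite"))
      xc <- sweep(obs, 2L, params$means[k, ], "-")
      z <- backsolve(ch, t(xc), transpose = TRUE)
      ld[, k] <- -0.5 * (colSums(z^2) + 2 * sum(log(diag(ch))) + C * log(2 * pi))
    }
  }
  if (any(!is.finite(ld))) {
    bad <- which(!is.finite(ld), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite log emission density at time %d, state %d", bad[1L], bad[2L]))
  }
  ld
}

check_boundaries <- function(run_lengths, T_) {
  run_lengths <- as.integer(run_lengths)
  if (any(run_lengths < 1L)) stop("run lengths must be positive")
  if (sum(run_lengths) != T_)
    stop(sprintf("run boundaries do not partition the observations: lengths sum to %d, T=%d",
                 sum(run_lengths), T_))
  list(starts = as.integer(cumsum(c(1L, run_lengths[-length(run_lengths)]))),
       lengths = run_lengths)
}

#' Forward-backward inference
#'
#' Exact posterior state probabilities and log-likelihood for a Gaussian HMM,
#' computed with per-step scaling. Recursions restart at every run boundary:
#' no transition probability is spent across concatenated scans, and the
#' log-likelihood is the sum over runs.
#'
#' @param params an [hmm_params].
#' @param obs T x C observation matrix.
#' @param run_lengths integer vector of per-run lengths partitioning T
#'   (default: one run).
#' @return list with `posteriors` (T x K, rows sum to 1), `loglik`, and
#'   `xi_sum` (K x K summed two-slice posterior counts, used by EM).
#' @export
forward_backward <- function(params, obs, run_lengths = nrow(obs)) {
  obs <- as.matrix(obs)
  if (any(!is.finite(obs))) stop("observations must be finite")
  b <- check_boundaries(run_lengths, nrow(obs))
  ld <- emission_logdens(params, obs)
  r <- fb_cpp(ld, params$init, params$trans, b$starts, b$lengths)
  list(posteriors = r$gamma, loglik = r$loglik, xi_sum = r$xi_sum,
       start_post = r$start_post)
}

#' Viterbi decoding
#'
#' Jointly most probable state path per run, in consensus with the
#' forward-backward boundary convention. Ties are broken toward the lower
#' state index, deterministically.
#'
#' @inheritParams forward_backward
#' @return integer vector of length T with 1-based state labels.
#' @export
viterbi <- function(params, obs, run_lengths = nrow(obs)) {
  obs <- as.matrix(obs)
  if (any(!is.finite(obs))) stop("observations must be finite")
  b <- check_boundaries(run_lengths, nrow(obs))
  ld <- emission_logdens(params, obs)
  viterbi_cpp(ld, log(params$init), log(params$trans), b$starts, b$lengths)
}

# Posterior-argmax decoding (per-time-point MAP); ties toward lower index.
posterior_argmax <- function(params, obs, run_lengths = nrow(obs)) {
  post <- forward_backward(params, obs, run_lengths)$posteriors
  max.col(post, ties.method = "first")
}

# k-means-based initialization: cluster pooled observations for means, global
# channel variances, uniform initial probabilities, sticky uniform transitions.
init_params <- function(obs, K, covariance, seed) {
  C <- ncol(obs)
  gvar <- pmax(apply(obs, 2L, var) * (nrow(obs) - 1) / nrow(obs), VAR_FLOOR)
  if (K == 1L) {
    means <- matrix(colMeans(obs), 1L, C)
  } else {
    means <- with_seed(seed, {
      km <- tryCatch(
        kmeans(obs, centers = K, nstart = 1L, iter.max = 30L),
        error = function(e) NULL)
      if (is.null(km)) obs[sample.int(nrow(obs), K), , drop = FALSE] else km$centers
    })
  }
  trans <- matrix(if (K > 1L) 0.5 / (K - 1) else 0, K, K)
  diag(trans) <- if (K > 1L) 0.5 else 1
  vars <- if (covariance == "diagonal") {
    matrix(gvar, K, C, byrow = TRUE)
  } else {
    array(diag(gvar, C), dim = c(C, C, K))
  }
  hmm_params(rep(1 / K, K), trans, means, vars, covariance)
}

m_step <- function(obs, obs2, fb, n_runs, covariance, prev) {
  gamma <- fb$posteriors
  K <- ncol(gamma); C <- ncol(obs)
  Nk <- colSums(gamma)
  events <- character(0)
  empty <- which(Nk < 1e-8)
  if (length(empty)) {
    # re-seed each empty state at the least-explained observation
    tot_dens <- apply(emission_logdens(prev, obs), 1L, logsumexp)
    worst <- order(tot_dens)[seq_along(empty)]
    for (i in seq_along(empty)) {
      k <- empty[i]
      gamma[, k] <- 1e-6
      gamma[worst[i], k] <- 1
      events <- c(events, sprintf("re-seeded empty state %d at observation %d", k, worst[i]))
    }
    gamma <- gamma / rowSums(gamma)
    Nk <- colSums(gamma)
  }
  init <- fb$start_post / n_runs
  init <- pmax(init, 1e-12); init <- init / sum(init)
  xr <- rowSums(fb$xi_sum)
  trans <- fb$xi_sum / ifelse(xr > 0, xr, 1)
  trans[xr == 0, ] <- 1 / K
  means <- t(gamma) %*% obs / Nk
  if (covariance == "diagonal") {
    vars <- pmax(t(gamma) %*% obs2 / Nk - means^2, VAR_FLOOR)
  } else {
    vars <- array(NA_real_, dim = c(C, C, K))
    for (k in seq_len(K)) {
      xc <- sweep(obs, 2L, means[k, ], "-")
      S <- crossprod(xc * gamma[, k], xc) / Nk[k]
      vars[, , k] <- S + diag(VAR_FLOOR, C)
    }
  }
  list(params = hmm_params(init, trans, means, vars, covariance), events = events)
}

#' Fit a Gaussian HMM by expectation-maximization
#'
#' Maximum-likelihood EM (Baum-Welch) with k-means initialization, multiple
#' restarts, a per-channel variance floor, and empty-state re-seeding. The
#' best restart by final log-likelihood is returned. Runs are treated as
#' independent chains: the recursion restarts at every boundary.
#'
#' @inheritParams forward_backward
#' @param K number of latent states.
#' @param covariance `"diagonal"` (default; appropriate for ~190-channel
#'   parcellations) or `"full"`.
#' @param n_restarts number of EM restarts with different k-means seeds.
#' @param max_iter maximum EM iterations per restart.
#' @param tol relative log-likelihood change declaring convergence.
#' @param seed integer; restart seeds are derived deterministically from it.
#' @return object of class `hmm_fit`: list with `params`, `loglik`,
#'   `loglik_trace`, `n_iter`, `converged`, `K`, `events`.
#' @export
em_fit <- function(obs, run_lengths = nrow(obs), K,
                   covariance = c("diagonal", "full"),
                   n_restarts = 5L, max_iter = 200L, tol = 1e-4, seed = 1L) {
  covariance <- match.arg(covariance)
  obs <- as.matrix(obs)
  if (any(!is.finite(obs))) stop("observations must be finite")
  stopifnot(K >= 1L, nrow(obs) > K)
  b <- check_boundaries(run_lengths, nrow(obs))
  obs2 <- obs^2
  n_runs <- length(b$lengths)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    params <- init_params(obs, K, covariance, derive_seed(seed, "em-init", K, r))
    trace <- numeric(0)
    events <- character(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      fb <- forward_backward(params, obs, run_lengths)
      trace <- c(trace, fb$loglik)
      if (it > 1L) {
        rel <- abs(trace[it] - trace[it - 1L]) / (abs(trace[it - 1L]) + 1e-12)
        if (rel < tol) { converged <- TRUE; break }
      }
      ms <- m_step(obs, obs2, fb, n_runs, covariance, params)
      params <- ms$params
      events <- c(events, ms$events)
    }
    cand <- list(params = params, loglik = trace[length(trace)],
                 loglik_trace = trace, n_iter = length(trace),
                 converged = converged, K = K, covariance = covariance,
                 restart = r, seed = seed, events = events)
    if (is.null(best) || cand$loglik > best$loglik) best <- cand
  }
  class(best) <- "hmm_fit"
  best
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("<hmm_fit> K=%d, loglik=%.4f, %d iterations (%s), restart %d\n",
              x$K, x$loglik, x$n_iter,
              if (x$converged) "converged" else "max_iter reached", x$restart))
  invisible(x)
}

#' Fit HMMs over a range of state counts
#'
#' One [em_fit()] per K with shared settings and per-K derived seeds. Failures
#' for individual K are recorded, not propagated, so a long scan never aborts.
#'
#' @inheritParams em_fit
#' @param k_min,k_max inclusive scan range (default 1 to 10).
#' @return object of class `fit_scan`: list of entries, each with `K`,
#'   `loglik`, `params`, `n_iter`, `converged`, `error` (NULL on success), and
#'   a `summary()`/`as.data.frame()` view.
#' @export
scan_states <- function(obs, run_lengths = nrow(obs), k_min = 1L, k_max = 10L,
                        covariance = c("diagonal", "full"), n_restarts = 5L,
                        max_iter = 200L, tol = 1e-4, seed = 1L, verbose = FALSE) {
  covariance <- match.arg(covariance)
  stopifnot(k_min >= 1L, k_max >= k_min)
  entries <- lapply(seq.int(k_min, k_max), function(K) {
    bs_log("scan", sprintf("fitting K=%d", K), verbose)
    fit <- tryCatch(
      em_fit(obs, run_lengths, K, covariance, n_restarts, max_iter, tol,
             seed = derive_seed(seed, "scan", K)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      list(K = K, loglik = NA_real_, params = NULL, n_iter = NA_integer_,
           converged = FALSE, error = conditionMessage(fit))
    } else {
      list(K = K, loglik = fit$loglik, params = fit$params, n_iter = fit$n_iter,
           converged = fit$converged, error = NULL)
    }
  })
  structure(list(entries = entries), class = "fit_scan")
}

#' @export
as.data.frame.fit_scan <- function(x, ...) {
  data.frame(
    K = vapply(x$entries, `[[`, integer(1), "K"),
    loglik = vapply(x$entries, `[[`, numeric(1), "loglik"),
    n_iter = vapply(x$entries, `[[`, integer(1), "n_iter"),
    converged = vapply(x$entries, `[[`, logical(1), "converged"),
    failed = !vapply(x$entries, function(e) is.null(e$error), logical(1)))
}

#' @export
print.fit_scan <- function(x, ...) {
  print(as.data.frame(x))
  invisible(x)
}

#' Elbow selection of the number of states
#'
#' Chooses the state count where fit improvement per added state drops most
#' sharply: the interior K maximizing the second difference
#' `[L(K) - L(K-1)] - [L(K+1) - L(K)]` of the scan's log-likelihoods. Ties go
#' to the smaller K. The full first/second-difference table is returned so a
#' visual/manual override stays possible.
#'
#' @param scan a `fit_scan` with at least 3 successful entries.
#' @return list with `k` (selected), `table` (K, loglik, delta, delta2), and
#'   `clear` (FALSE when all second differences are equal, i.e. no elbow; a
#'   warning is also raised in that case).
#' @export
select_elbow <- function(scan) {
  df <- if (inherits(scan, "fit_scan")) as.data.frame(scan) else
    data.frame(K = seq_along(scan), loglik = as.numeric(scan))
  df <- df[is.finite(df$loglik), c("K", "loglik")]
  if (nrow(df) < 3L) stop("insufficient scan: elbow selection needs >= 3 successful fits")
  L <- df$loglik
  delta <- c(NA, diff(L))
  delta2 <- c(NA, diff(L, differences = 2L), NA) * -1 # drop in improvement
  df$delta <- delta
  df$delta2 <- delta2
  interior <- which(!is.na(delta2))
  spread <- diff(range(delta2[interior]))
  clear <- spread > 1e-10
  if (!clear) {
    warning("no clear elbow: all second differences are equal; returning smallest interior K")
    k <- df$K[interior[1L]]
  } else {
    k <- df$K[interior[which.max(delta2[interior])]]
  }
  list(k = k, table = df, clear = clear)
}
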