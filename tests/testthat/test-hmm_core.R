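test_that("single-state model reduces to closed forms", {
  set.seed(1)
  obs <- matrix(rnorm(40), 20, 2)
  p <- hmm_params(1, matrix(1, 1, 1), matrix(c(0.2, -0.3), 1, 2),
                  matrix(c(1.5, 0.7), 1, 2))
  fb <- forward_backward(p, obs)
  expect_equal(as.numeric(fb$posteriors), rep(1, 20))
  expect_equal(fb$loglik,
               sum(dnorm(obs[, 1], 0.2, sqrt(1.5), log = TRUE)) +
                 sum(dnorm(obs[, 2], -0.3, sqrt(0.7), log = TRUE)))
  # K=1 EM: mean = column means, variance = MLE column variances, one iteration
  fit <- em_fit(obs, K = 1, n_restarts = 1, seed = 1)
  expect_equal(as.numeric(fit$params$means), colMeans(obs))
  expect_equal(as.numeric(fit$params$vars),
               apply(obs, 2, function(x) mean((x - mean(x))^2)))
})

test_that("symmetric two-state model yields uniform posteriors and tie-broken paths", {
  obs <- matrix(rnorm(30), 15, 2)
  p <- hmm_params(c(0.5, 0.5), matrix(0.5, 2, 2),
                  rbind(c(0, 0), c(0, 0)), rbind(c(1, 1), c(1, 1)))
  fb <- forward_backward(p, obs)
  expect_equal(fb$posteriors, matrix(0.5, 15, 2))
  # fully symmetric: the tie-break rule picks the lowest state index throughout
  expect_equal(viterbi(p, obs), rep(1L, 15))
})

test_that("inference matches exhaustive path enumeration on random tiny instances", {
  set.seed(100)
  for (i in 1:40) {
    K <- sample(2:3, 1); T_ <- sample(2:6, 1)
    p <- rand_hmm(K, 2)
    obs <- matrix(rnorm(T_ * 2), T_, 2)
    o <- bf_hmm(p, obs)
    fb <- forward_backward(p, obs)
    expect_lt(abs(fb$loglik - o$loglik), 1e-10)
    expect_lt(max(abs(fb$posteriors - o$posteriors)), 1e-10)
    expect_lt(abs(path_logprob(p, obs, viterbi(p, obs)) - o$max_path_logprob), 1e-10)
    # posterior rows are simplexes
    expect_true(all(abs(rowSums(fb$posteriors) - 1) < 1e-10))
  }
})

test_that("run boundaries break the chain", {
  set.seed(7)
  p <- rand_hmm(2, 2)
  o1 <- matrix(rnorm(16), 8, 2); o2 <- matrix(rnorm(12), 6, 2)
  joint <- forward_backward(p, rbind(o1, o2), c(8, 6))
  expect_equal(joint$loglik,
               forward_backward(p, o1)$loglik + forward_backward(p, o2)$loglik)
  expect_equal(joint$posteriors[1:8, ], forward_backward(p, o1)$posteriors)
  expect_equal(viterbi(p, rbind(o1, o2), c(8, 6)),
               c(viterbi(p, o1), viterbi(p, o2)))
  expect_error(forward_backward(p, o1, c(3, 3)), "partition")
})

test_that("EM is monotone, deterministic, and recovers a planted 2-state model", {
  cfg <- gt_config(K = 2, C = 2, runs_per_group = c(1, 1, 1, 1),
                   run_length_range = c(50, 60),
                   state_map_templates = rbind(c(3, 3), c(-3, -3)),
                   map_group_jitter_sd = 0, on_diag_by_group = rep(0.7, 4),
                   subject_tpm_jitter_sd = 0, seed = 5)
  gt <- make_ground_truth(cfg)
  sim <- simulate_run(gt, "girl_ADHD", T = 5000L, seed = 9)
  fit <- em_fit(sim$run$data, K = 2, n_restarts = 2, seed = 42)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_true(fit$converged)
  # label matching: order states by first channel mean
  ord <- order(-fit$params$means[, 1])
  expect_lt(max(abs(fit$params$means[ord, ] - gt$group_params$girl_ADHD$means)), 0.1)
  expect_lt(max(abs(fit$params$trans[ord, ord] - gt$group_params$girl_ADHD$trans)), 0.05)
  # same data, same seed: identical parameters
  fit2 <- em_fit(sim$run$data, K = 2, n_restarts = 2, seed = 42)
  expect_identical(fit$params, fit2$params)
  expect_error(em_fit(sim$run$data, K = 2, covariance = "banana"), "arg")
})

test_that("full-covariance EM runs and beats nothing silently", {
  set.seed(31)
  obs <- rbind(matrix(rnorm(200, 2), 100, 2), matrix(rnorm(200, -2), 100, 2))
  fit <- em_fit(obs, K = 2, covariance = "full", n_restarts = 1, max_iter = 50, seed = 2)
  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_equal(dim(fit$params$vars), c(2L, 2L, 2L))
})

test_that("scan_states keeps ordered entries and survives per-K failure", {
  set.seed(8)
  obs <- rbind(matrix(rnorm(120, 2), 60, 2), matrix(rnorm(120, -2), 60, 2))
  sc <- scan_states(obs, k_min = 1, k_max = 4, n_restarts = 1, max_iter = 40, seed = 3)
  df <- as.data.frame(sc)
  expect_equal(df$K, 1:4)
  expect_true(all(is.finite(df$loglik)))
  sc1 <- scan_states(obs, k_min = 1, k_max = 1, n_restarts = 1, seed = 3)
  expect_equal(as.data.frame(sc1)$K, 1L)
})

test_that("select_elbow maximizes the second difference with documented ties", {
  pick <- select_elbow(c(-100, -50, -45, -44))
  expect_equal(pick$k, 2L)
  expect_true(pick$clear)
  expect_warning(lin <- select_elbow(c(-30, -20, -10, 0)), "no clear elbow")
  expect_equal(lin$k, 2L) # smallest interior K
  expect_error(select_elbow(c(-2, -1)), "insufficient")
})

test_that("log-likelihood agrees with an independent reference implementation", {
  set.seed(19)
  K <- 3; C <- 2; T_ <- 80
  p <- rand_hmm(K, C)
  obs <- matrix(rnorm(T_ * C), T_, C)
  ll <- forward_backward(p, obs)$loglik
  f_obs <- tempfile(fileext = ".csv"); f_par <- tempfile(fileext = ".json")
  utils::write.csv(obs, f_obs, row.names = FALSE)
  jsonlite::write_json(list(init = p$init, trans = p$trans, means = p$means,
                            vars = p$vars), f_par, digits = NA, matrix = "rowmajor")
  out <- run_python(sprintf('
import json, numpy as np, pandas as pd
from hmmlearn.hmm import GaussianHMM
X = pd.read_csv("%s").to_numpy()
par = json.load(open("%s"))
m = GaussianHMM(n_components=%d, covariance_type="diag", init_params="")
m.startprob_ = np.array(par["init"])
m.transmat_ = np.array(par["trans"])
m.means_ = np.array(par["means"])
m.covars_ = np.array(par["vars"])
print(repr(m.score(X)))
', f_obs, f_par, K))
  ref <- as.numeric(out[length(out)])
  expect_lt(abs(ll - ref) / abs(ref), 1e-10)

  # On well-separated data both EMs reach the same optimum: compare em_fit's
  # final log-likelihood with a reference EM fit of the same data
  set.seed(23)
  obs2 <- rbind(matrix(rnorm(300, 2), 150, 2), matrix(rnorm(300, -2), 150, 2))
  fit <- em_fit(obs2, K = 2, n_restarts = 2, max_iter = 200, tol = 1e-8, seed = 4)
  utils::write.csv(obs2, f_obs, row.names = FALSE)
  out2 <- run_python(sprintf('
import numpy as np, pandas as pd
from hmmlearn.hmm import GaussianHMM
X = pd.read_csv("%s").to_numpy()
m = GaussianHMM(n_components=2, covariance_type="diag", n_iter=500, tol=1e-8,
                random_state=0)
m.fit(X)
print(repr(m.score(X)))
', f_obs))
  ref2 <- as.numeric(out2[length(out2)])
  expect_lt(abs(fit$loglik - ref2) / abs(ref2), 1e-4)
})
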