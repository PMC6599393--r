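test_that("fractional occupancy hand examples and pooling identity", {
  expect_equal(unname(fractional_occupancy(c(1, 1, 2, 3), K = 3, "run")[1, ]),
               c(0.5, 0.25, 0.25))
  expect_equal(unname(fractional_occupancy(rep(2, 7), K = 5, "run")[1, ]),
               c(0, 1, 0, 0, 0))
  # group-level FO equals the run-length-weighted mean of run-level FO
  seqs <- list(c(1, 1, 2), c(2, 2, 2, 3, 3, 3))
  g <- fractional_occupancy(seqs, K = 3, "group")
  r <- fractional_occupancy(seqs, K = 3, "run")
  lens <- c(3, 6)
  expect_equal(g, colSums(r * lens) / sum(lens), ignore_attr = TRUE)
  expect_equal(sum(g), 1)
  expect_error(fractional_occupancy(list(), K = 3), "empty")
})

test_that("empirical transitions count pairs and flag undefined rows", {
  et <- empirical_transitions(c(1, 1, 2, 2), K = 2)
  expect_equal(et$counts, rbind(c(1L, 1L), c(0L, 1L)))
  expect_equal(et$tpm, rbind(c(0.5, 0.5), c(0, 1)))
  const <- empirical_transitions(rep(2, 10), K = 3)
  expect_equal(const$counts[2, 2], 9L)
  expect_equal(sum(const$counts), 9L)
  expect_equal(const$undefined_rows, c(1L, 3L))
  expect_true(all(is.na(const$tpm[1, ])))
  expect_error(empirical_transitions(1L, K = 2), "degenerate")
})

test_that("dwell episodes are maximal, ordered, and sum to T", {
  ep <- dwell_episodes(c(1, 1, 2, 3, 3, 3))
  expect_equal(ep$state, c(1, 2, 3))
  expect_equal(ep$length, c(2, 1, 3))
  expect_equal(ep$start_index, c(0, 2, 3))
  expect_equal(dwell_episodes(1L)$length, 1L)
  expect_equal(nrow(dwell_episodes(c(1, 2, 1, 2))), 4L)
  expect_true(all(dwell_episodes(c(1, 2, 1, 2))$length == 1L))
})

test_that("ITI conventions and per-state means behave as documented", {
  ep <- data.frame(state = c(1, 2, 1), length = c(2, 1, 3),
                   start_index = c(0, 2, 3))
  d1 <- iti_stats(ep, K = 3, convention = "dwell_minus_one")
  expect_equal(d1$iti_mean, 1.0) # values (1, 0, 2)
  d2 <- iti_stats(ep, K = 3, convention = "dwell")
  expect_equal(d2$iti_mean, 2.0)
  expect_equal(unname(d1$per_state), c(1.5, 0, NA))
  single <- iti_stats(data.frame(state = 1, length = 5, start_index = 0), K = 2)
  expect_true(is.na(single$iti_sd))
})

test_that("number of transitions is switches per time point", {
  expect_equal(number_of_transitions(c(1, 2, 1, 2)), 0.75)
  expect_equal(number_of_transitions(rep(3, 9)), 0)
  expect_error(number_of_transitions(2L), "degenerate")
  # simulated chain at on_diag 0.53: mean NT near 0.47
  cfg <- gt_config(K = 5, C = 2, runs_per_group = c(1, 1, 1, 1),
                   run_length_range = c(50, 60), on_diag_by_group = rep(0.53, 4),
                   subject_tpm_jitter_sd = 0, seed = 2)
  gt <- make_ground_truth(cfg)
  sim <- simulate_run(gt, "girl_control", T = 20000L, seed = 3)
  expect_lt(abs(number_of_transitions(sim$states) - 0.47), 0.02)
})

test_that("outlier screening is pooled, single-pass, and strict at the boundary", {
  set.seed(4)
  v <- c(rnorm(100), 50)
  scr <- screen_outliers(v, ids = c(sprintf("r%03d", 1:100), "wild"))
  expect_equal(scr$report$id, "wild")
  expect_equal(sum(!scr$keep), 1L)
  expect_warning(flat <- screen_outliers(rep(2, 10)), "zero variance")
  expect_true(all(flat$keep))
  # |z| exactly at the threshold is retained (strict inequality)
  z_max <- max(abs((v - mean(v)) / sd(v)))
  at <- screen_outliers(v, threshold_sd = z_max)
  expect_true(all(at$keep))
  expect_error(screen_outliers(c(1, 2)), "at least 3")
})

test_that("decoding splits at boundaries and is relabeling-invariant", {
  w <- make_tiny_fitted(K = 3, C = 8, runs = 4, seed = 13)
  gd <- w$groups$girl_ADHD
  params <- w$fits$girl_ADHD$params
  obs <- group_data(gd)
  joint <- viterbi(params, obs, gd$boundaries$length)
  sep <- unlist(lapply(gd$runs, function(r) viterbi(params, r$data)))
  expect_equal(joint, sep)

  run <- gd$runs[[1]]
  relab <- c(3L, 1L, 2L)
  sq <- decode_run(params, run, relabeling = relab)
  plain <- decode_run(params, run)
  expect_equal(sq$labels, relab[plain$labels])
  expect_equal(apply_relabeling(sq$labels, relab, invert = TRUE), plain$labels)
  # dynamics metrics invariant under relabeling (up to state permutation)
  d1 <- compute_dynamics(list(plain), K = 3)
  d2 <- compute_dynamics(list(sq), K = 3)
  expect_equal(d2$nt, d1$nt)
  expect_equal(d2$iti_mean, d1$iti_mean)
  expect_equal(unname(unlist(d2[paste0("fo_", relab)])),
               unname(unlist(d1[paste0("fo_", 1:3)])))
  # posterior-argmax decoder is also available
  pa <- decode_run(params, run, decoder = "posterior_argmax")
  expect_equal(length(pa$labels), nrow(run$data))
})

test_that("noise-free runs decode to the generating path", {
  cfg <- gt_config(K = 2, C = 4, runs_per_group = c(1, 1, 1, 1),
                   run_length_range = c(60, 80),
                   state_map_templates = rbind(rep(2, 4), rep(-2, 4)),
                   map_group_jitter_sd = 0, emission_noise_sd = 1e-4,
                   subject_tpm_jitter_sd = 0, seed = 21)
  gt <- make_ground_truth(cfg)
  sim <- simulate_run(gt, "boy_ADHD", T = 300L, seed = 5)
  sq <- decode_run(gt$group_params$boy_ADHD, sim$run)
  expect_equal(sq$labels, sim$states$labels)
})

test_that("mean dwell, episode count and NT satisfy exact structural identities", {
  set.seed(9)
  for (i in 1:20) {
    lab <- sample(1:4, 200, replace = TRUE, prob = c(.4, .3, .2, .1))
    ep <- dwell_episodes(lab)
    ntr <- sum(diff(lab) != 0)
    expect_equal(nrow(ep), ntr + 1L)
    expect_equal(sum(ep$length), 200L)
    mean_dwell <- mean(ep$length)
    nt <- number_of_transitions(lab)
    expect_equal(abs(mean_dwell - 1 / nt), 200 / (ntr * (ntr + 1L)))
  }
})
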