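test_that("balanced two-way ANOVA matches the hand SS decomposition", {
  # balanced 2x2, n=3 per cell: classical textbook decomposition applies
  set.seed(1)
  a <- rep(c(-1, 1), each = 6) # sex effect +/-1
  b <- rep(rep(c(-0.5, 0.5), each = 3), 2) # dx effect
  eps <- rnorm(12, 0, 0.01)
  y <- 10 + a + b + eps
  sx <- rep(c("girl", "boy"), each = 6)
  dx <- rep(rep(c("ADHD", "control"), each = 3), 2)
  tab <- two_way_anova(y, sx, dx)
  hand_ss <- function(f) {
    m <- tapply(y, f, mean)
    sum(table(f) * (m - mean(y))^2)
  }
  expect_lt(abs(tab$SS[tab$effect == "sex"] - hand_ss(sx)), 1e-8)
  expect_lt(abs(tab$SS[tab$effect == "diagnosis"] - hand_ss(dx)), 1e-8)
  cellm <- tapply(y, interaction(sx, dx), mean)
  ss_cells <- sum(3 * (cellm - mean(y))^2)
  expect_lt(abs(tab$SS[tab$effect == "sex:diagnosis"] -
                  (ss_cells - hand_ss(sx) - hand_ss(dx))), 1e-8)
  expect_equal(tab$df, c(1L, 1L, 1L, 8L))
  # partial eta squared is SS/(SS+SSE) and invariant to affine rescaling
  tab2 <- two_way_anova(3 * y - 7, sx, dx)
  expect_equal(tab2$partial_eta_sq, tab$partial_eta_sq)
  err <- tab$SS[tab$effect == "error"]
  expect_equal(tab$partial_eta_sq[1], tab$SS[1] / (tab$SS[1] + err))
})

test_that("degenerate and malformed designs are handled explicitly", {
  sx <- rep(c("girl", "boy"), each = 4)
  dx <- rep(c("ADHD", "control"), 4)
  tab <- two_way_anova(rep(2.5, 8), sx, dx)
  expect_true(all(tab$SS[1:3] == 0))
  expect_true(all(tab$F[1:3] == 0))
  expect_true(all(tab$partial_eta_sq[1:3] == 0))
  expect_error(two_way_anova(1:4, c("girl", "girl", "boy", "boy"),
                             c("ADHD", "ADHD", "ADHD", "control")),
               "design error: cell")
})

test_that("Type III F values agree with an independent implementation", {
  f_csv <- tempfile(fileext = ".csv")
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30 + seed * 7
    sx <- sample(c("girl", "boy"), n, TRUE, prob = c(.35, .65))
    dx <- sample(c("ADHD", "control"), n, TRUE)
    # guard against <2 cells in tiny draws
    sx[1:4] <- rep(c("girl", "boy"), 2); dx[1:4] <- rep(c("ADHD", "control"), each = 2)
    y <- rnorm(n) + 0.4 * (sx == "boy") - 0.2 * (dx == "control")
    utils::write.csv(data.frame(y = y, sx = sx, dx = dx), f_csv, row.names = FALSE)
    tab <- two_way_anova(y, sx, dx, ss_type = "III")
    out <- run_python(sprintf('
import pandas as pd, statsmodels.api as sm
from statsmodels.formula.api import ols
d = pd.read_csv("%s")
m = ols("y ~ C(sx, Sum)*C(dx, Sum)", data=d).fit()
a = sm.stats.anova_lm(m, typ=3)
print(",".join("%%.12g" %% x for x in a["F"][1:4]))
', f_csv))
    ref <- as.numeric(strsplit(out[length(out)], ",")[[1]])
    expect_equal(tab$F[1:3], ref, tolerance = 1e-6)
  }
})

test_that("mixed FO ANOVA matches base aov on a balanced split-plot design", {
  set.seed(9)
  N <- 24; K <- 4
  sx <- rep(c("girl", "boy"), each = N / 2)
  dx <- rep(rep(c("ADHD", "control"), each = N / 4), 2)
  fo <- matrix(rnorm(N * K), N, K)
  tab <- mixed_anova_fo(fo, sx, dx)
  d <- data.frame(y = as.numeric(t(fo)), st = factor(rep(1:K, N)),
                  run = factor(rep(1:N, each = K)),
                  sx = factor(rep(sx, each = K)), dx = factor(rep(dx, each = K)))
  ref <- summary(stats::aov(y ~ st * sx * dx + Error(run), data = d))
  btw <- as.data.frame(ref[["Error: run"]][[1]])
  rownames(btw) <- trimws(rownames(btw))
  wth <- as.data.frame(ref[["Error: Within"]][[1]])
  rownames(wth) <- trimws(rownames(wth))
  expect_equal(tab$SS[tab$effect == "sex"], btw["sx", "Sum Sq"], tolerance = 1e-8)
  expect_equal(tab$SS[tab$effect == "error_between"], btw["Residuals", "Sum Sq"],
               tolerance = 1e-8)
  expect_equal(tab$SS[tab$effect == "state:sex:diagnosis"],
               wth["st:sx:dx", "Sum Sq"], tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(tab$SS[tab$effect == "error_within"], wth["Residuals", "Sum Sq"],
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(tab$df[tab$effect == "error_within"], (K - 1) * (N - 4))
})

test_that("mixed FO ANOVA handles the simplex constraint and null state effect", {
  N <- 16; K <- 5
  sx <- rep(c("girl", "boy"), each = N / 2)
  dx <- rep(rep(c("ADHD", "control"), each = N / 4), 2)
  # FO identical across states for every run: state SS exactly 0
  flat <- matrix(1 / K, N, K)
  tab <- mixed_anova_fo(flat, sx, dx)
  expect_true(all(tab$SS[tab$effect %in%
    c("state", "state:sex", "state:diagnosis", "state:sex:diagnosis")] < 1e-20))
  # genuine simplex rows (built-in collinearity) must not error
  set.seed(2)
  raw <- matrix(rexp(N * K), N, K)
  fo <- raw / rowSums(raw)
  expect_silent(tab2 <- mixed_anova_fo(fo, sx, dx))
  # between stratum is degenerate for simplex data: run means all equal 1/K
  expect_lt(tab2$SS[tab2$effect == "error_between"], 1e-20)
  expect_error(mixed_anova_fo(fo[, 1, drop = FALSE], sx, dx), "at least 2 states")
})

test_that("cohens_d follows the pooled-SD convention and edge contracts", {
  expect_equal(cohens_d(1, 1, 10, 1, 1, 10), 0)
  expect_equal(cohens_d(0, 1, 50, 1, 1, 50), 1)
  expect_equal(cohens_d(0, 2, 20, 1, 2, 40), 0.5)
  expect_equal(cohens_d(3, 0, 5, 3, 0, 5), 0)
  expect_error(cohens_d(0, 0, 5, 1, 0, 5), "infinite effect")
  # sign convention: second group minus first
  expect_lt(cohens_d(1.2, 0.5, 30, 0.8, 0.5, 30), 0)
})

test_that("state-wise tests are calibrated and mark untestable states", {
  # identical group data: d = 0, p = 1
  v <- matrix(rep(c(1, 2, 1, 2), 5), 4, 5)
  g <- c("girl", "girl", "boy", "boy")
  tw <- state_wise_tests(v, g)
  expect_true(all(tw$p == 1))
  expect_true(all(tw$cohens_d == 0))
  # a state visited by <2 runs in a group is untestable
  v2 <- v; v2[c(1, 2), 2] <- NA
  tw2 <- state_wise_tests(v2, g)
  expect_false(tw2$testable[2])
  expect_true(all(tw2$testable[-2]))
  # estimator consistency: mean estimated d near the planted 0.3
  set.seed(11)
  d_hat <- replicate(120, {
    x <- c(rnorm(350, 0), rnorm(604, 0.3))
    gr <- rep(c("a", "b"), c(350, 604))
    state_wise_tests(matrix(x, ncol = 1), gr)$cohens_d
  })
  expect_lt(abs(mean(d_hat) - 0.3), 0.05)
})

test_that("ITI-NT correlation handles exact, null, and degenerate inputs", {
  x <- seq(1, 3, length.out = 20)
  expect_equal(iti_nt_correlation(data.frame(iti_mean = x, nt = 5 - 2 * x))$r, -1)
  set.seed(3)
  r_null <- iti_nt_correlation(data.frame(iti_mean = rnorm(500), nt = rnorm(500)))$r
  expect_lt(abs(r_null), 0.2)
  expect_error(iti_nt_correlation(data.frame(iti_mean = rep(1, 5), nt = rnorm(5))),
               "zero variance")
  expect_error(iti_nt_correlation(data.frame(iti_mean = 1:2, nt = 2:1)), "at least 3")
})

test_that("sub-sample analysis matches the smallest cell and is reproducible", {
  set.seed(5)
  counts <- c(girl_ADHD = 99, boy_ADHD = 347, girl_control = 251, boy_control = 257)
  metrics <- do.call(rbind, lapply(names(counts), function(g) {
    parts <- strsplit(g, "_")[[1]]
    data.frame(run_id = sprintf("%s_%d", g, seq_len(counts[[g]])),
               sex = parts[1], dx = parts[2],
               iti_mean = rnorm(counts[[g]], 1.1, 0.3),
               iti_sd = rnorm(counts[[g]], 1.6, 0.5),
               nt = rnorm(counts[[g]], 0.47, 0.07))
  }))
  sub <- subsample_analysis(metrics, seed = 7)
  expect_equal(sub$n_min, 99L)
  expect_equal(length(sub$selected), 4L * 99L)
  expect_equal(sum(grepl("^boy_control", sub$selected)), 99L)
  sub2 <- subsample_analysis(metrics, seed = 7)
  expect_identical(sub$selected, sub2$selected)
  expect_identical(sub$tables$nt, sub2$tables$nt)
  # groups already equal: sub-sample is the full sample
  eq <- metrics[unlist(lapply(split(seq_len(nrow(metrics)),
                                    paste(metrics$sex, metrics$dx)),
                              head, 99)), ]
  sub_eq <- subsample_analysis(eq, seed = 1)
  expect_equal(sort(sub_eq$selected), sort(eq$run_id))
  expect_equal(sub_eq$tables$iti_mean,
               two_way_anova(eq$iti_mean, eq$sex, eq$dx))
})
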