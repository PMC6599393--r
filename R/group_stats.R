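anova_table <- function(df) {
  class(df) <- c("anova_table", "data.frame")
  df
}

f_p_from_ss <- function(ss, df, ss_err, df_err) {
  ms_err <- ss_err / df_err
  if (ms_err == 0) {
    f <- ifelse(ss <= 1e-12, 0, Inf)
    p <- ifelse(ss <= 1e-12, 1, 0)
  } else {
    f <- (ss / df) / ms_err
    p <- pf(f, df, df_err, lower.tail = FALSE)
  }
  list(f = f, p = p,
       eta = ifelse(ss + ss_err > 0, ss / (ss + ss_err), 0))
}

rss_fit <- function(X, y) {
  q <- qr(X)
  sum(qr.resid(q, y)^2)
}

check_factors <- function(sex, dx, n) {
  f1 <- factor(sex, levels = if (all(sex %in% SEX_LEVELS)) SEX_LEVELS else unique(sex))
  f2 <- factor(dx, levels = if (all(dx %in% DX_LEVELS)) DX_LEVELS else unique(dx))
  stopifnot(length(f1) == n, length(f2) == n, nlevels(f1) == 2L, nlevels(f2) == 2L)
  tab <- table(f1, f2)
  if (any(tab < 2L)) {
    bad <- which(tab < 2L, arr.ind = TRUE)[1L, ]
    stop(sprintf("design error: cell (%s, %s) has %d run(s), need at least 2",
                 levels(f1)[bad[1L]], levels(f2)[bad[2L]], tab[bad[1L], bad[2L]]))
  }
  list(f1 = f1, f2 = f2)
}

#' Two-way between-subjects ANOVA with partial eta squared
#'
#' Sex-by-diagnosis factorial ANOVA on a per-run metric, with Type III sums
#' of squares under sum-to-zero contrasts (default, the convention for
#' unbalanced factorial designs in the psychological literature) or Type II.
#'
#' @param values numeric per-run metric (already outlier-screened).
#' @param sex,dx factors (or character vectors) of length `length(values)`
#'   with two levels each; canonical levels are `girl`/`boy` and
#'   `ADHD`/`control`.
#' @param ss_type `"III"` (default) or `"II"`.
#' @return an `anova_table` data frame with rows `sex`, `diagnosis`,
#'   `sex:diagnosis` and `error`; columns `effect`, `SS`, `df`, `F`, `p`,
#'   `partial_eta_sq`.
#' @export
two_way_anova <- function(values, sex, dx, ss_type = c("III", "II")) {
  ss_type <- match.arg(ss_type)
  ok <- is.finite(values)
  values <- values[ok]
  fs <- check_factors(sex[ok], dx[ok], length(values))
  f1 <- fs$f1; f2 <- fs$f2
  n <- length(values)
  ctr <- list(f1 = "contr.sum", f2 = "contr.sum")
  X <- model.matrix(~ f1 * f2, contrasts.arg = ctr)
  asgn <- attr(X, "assign") # 0=intercept, 1=f1, 2=f2, 3=f1:f2
  ss_err <- rss_fit(X, values)
  df_err <- n - ncol(X)
  drop_ss <- function(term) rss_fit(X[, asgn != term, drop = FALSE], values) - ss_err
  if (ss_type == "III") {
    ss <- c(sex = drop_ss(1L), diagnosis = drop_ss(2L), `sex:diagnosis` = drop_ss(3L))
  } else {
    X12 <- model.matrix(~ f1 + f2, contrasts.arg = ctr)
    a12 <- attr(X12, "assign")
    r12 <- rss_fit(X12, values)
    ss <- c(sex = rss_fit(X12[, a12 != 1L, drop = FALSE], values) - r12,
            diagnosis = rss_fit(X12[, a12 != 2L, drop = FALSE], values) - r12,
            `sex:diagnosis` = drop_ss(3L))
  }
  # clamp numerical dust relative to the metric's total variation
  eps <- 1e-12 * (sum((values - mean(values))^2) + 1)
  ss <- ifelse(ss < eps, 0, ss)
  if (ss_err < eps) ss_err <- 0
  stat <- lapply(ss, f_p_from_ss, df = 1L, ss_err = ss_err, df_err = df_err)
  anova_table(data.frame(
    effect = c(names(ss), "error"),
    SS = c(unname(ss), ss_err),
    df = c(1L, 1L, 1L, df_err),
    F = c(vapply(stat, `[[`, numeric(1), "f"), NA_real_),
    p = c(vapply(stat, `[[`, numeric(1), "p"), NA_real_),
    partial_eta_sq = c(vapply(stat, `[[`, numeric(1), "eta"), NA_real_),
    stringsAsFactors = FALSE))
}

#' Mixed (split-plot) ANOVA on fractional occupancy
#'
#' Sex and diagnosis as between-run factors, state as the within-run factor,
#' with the run as the repeated-measures unit. Because each run's occupancy
#' vector sums to one, the between-run stratum is degenerate for FO (all run
#' means equal 1/K); the scientifically meaningful rows are the within-run
#' ones, in particular the sex x diagnosis x state interaction. Type III sums
#' of squares with sum-to-zero contrasts in each stratum; the within-run
#' error has (K-1)(N-4) degrees of freedom.
#'
#' @param fo N x K matrix of run-level fractional occupancy (rows = runs).
#' @param sex,dx between-run factors, length N.
#' @return an `anova_table` with between rows (`sex`, `diagnosis`,
#'   `sex:diagnosis`, `error_between`) and within rows (`state`, `state:sex`,
#'   `state:diagnosis`, `state:sex:diagnosis`, `error_within`).
#' @export
mixed_anova_fo <- function(fo, sex, dx) {
  fo <- as.matrix(fo)
  N <- nrow(fo); K <- ncol(fo)
  if (K < 2L) stop("design error: within factor needs at least 2 states")
  fs <- check_factors(sex, dx, N)
  f1 <- fs$f1; f2 <- fs$f2
  ctr2 <- list(f1 = "contr.sum", f2 = "contr.sum")
  # between stratum: run means carry K observations each
  mbar <- rowMeans(fo)
  Xb <- model.matrix(~ f1 * f2, contrasts.arg = ctr2)
  ab <- attr(Xb, "assign")
  ss_err_b <- K * rss_fit(Xb, mbar)
  df_err_b <- N - 4L
  ss_b <- vapply(1:3, function(term)
    K * (rss_fit(Xb[, ab != term, drop = FALSE], mbar) - rss_fit(Xb, mbar)), numeric(1))
  names(ss_b) <- c("sex", "diagnosis", "sex:diagnosis")
  # within stratum: run-centered long data; state-involving columns are
  # orthogonal to runs because each run holds every state exactly once and
  # sum-to-zero state contrasts have zero run mean
  yc <- as.numeric(t(fo - mbar)) # run-major long vector
  st <- factor(rep(seq_len(K), times = N))
  g1 <- rep(f1, each = K); g2 <- rep(f2, each = K)
  Xw <- model.matrix(~ st * g1 * g2,
                     contrasts.arg = list(st = "contr.sum", g1 = "contr.sum",
                                          g2 = "contr.sum"))
  aw <- attr(Xw, "assign")
  labs <- attr(terms(~ st * g1 * g2), "term.labels")
  wterms <- c(state = which(labs == "st"),
              `state:sex` = which(labs == "st:g1"),
              `state:diagnosis` = which(labs == "st:g2"),
              `state:sex:diagnosis` = which(labs == "st:g1:g2"))
  keep <- aw %in% c(0L, wterms) # state-involving columns (+ intercept, inert on centered y)
  Xw <- Xw[, keep, drop = FALSE]
  aw <- attr(model.matrix(~ st * g1 * g2,
                          contrasts.arg = list(st = "contr.sum", g1 = "contr.sum",
                                               g2 = "contr.sum")), "assign")[keep]
  ss_err_w <- rss_fit(Xw, yc)
  df_err_w <- (K - 1L) * (N - 4L)
  ss_w <- vapply(wterms, function(term)
    rss_fit(Xw[, aw != term, drop = FALSE], yc) - ss_err_w, numeric(1))
  eps <- 1e-12 * (sum(yc^2) + K * sum((mbar - mean(mbar))^2) + 1)
  ss_b <- ifelse(ss_b < eps, 0, ss_b)
  if (ss_err_b < eps) ss_err_b <- 0
  ss_w <- ifelse(ss_w < eps, 0, ss_w)
  if (ss_err_w < eps) ss_err_w <- 0
  stat_b <- lapply(ss_b, f_p_from_ss, df = 1L, ss_err = ss_err_b, df_err = df_err_b)
  stat_w <- lapply(ss_w, f_p_from_ss, df = K - 1L, ss_err = ss_err_w, df_err = df_err_w)
  anova_table(data.frame(
    effect = c("sex", "diagnosis", "sex:diagnosis", "error_between",
               names(wterms), "error_within"),
    SS = c(ss_b, ss_err_b, unname(ss_w), ss_err_w),
    df = c(1L, 1L, 1L, df_err_b, rep(K - 1L, 4L), df_err_w),
    F = c(vapply(stat_b, `[[`, numeric(1), "f"), NA_real_,
          vapply(stat_w, `[[`, numeric(1), "f"), NA_real_),
    p = c(vapply(stat_b, `[[`, numeric(1), "p"), NA_real_,
          vapply(stat_w, `[[`, numeric(1), "p"), NA_real_),
    partial_eta_sq = c(vapply(stat_b, `[[`, numeric(1), "eta"), NA_real_,
                       vapply(stat_w, `[[`, numeric(1), "eta"), NA_real_),
    stringsAsFactors = FALSE))
}

#' Cohen's d from group summary statistics
#'
#' Pooled-SD standardized mean difference, `(m2 - m1) / s_pooled` with
#' `s_pooled^2 = ((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2)`. The sign
#' convention is second group minus first.
#'
#' @param m1,sd1,n1 mean, SD and size of the first group.
#' @param m2,sd2,n2 mean, SD and size of the second group.
#' @return Cohen's d.
#' @export
cohens_d <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2L, n2 >= 2L, sd1 >= 0, sd2 >= 0)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (m1 == m2) return(0)
    stop("infinite effect: both SDs are zero but means differ")
  }
  (m2 - m1) / sqrt(sp2)
}

#' Per-state two-sample tests with Cohen's d
#'
#' For every state, a pooled-variance two-sample t-test of the per-run,
#' per-state metric between the two levels of a grouping factor, with
#' Cohen's d (second level minus first). Runs that never visit a state are
#' excluded for that state; states with fewer than two testable runs in
#' either group are marked untestable.
#'
#' @param values N x K matrix of per-run, per-state metric values (NA for
#'   unvisited states).
#' @param group length-N factor (or character) with exactly two levels.
#' @param holm apply Holm correction across the K tests (off by default,
#'   matching raw-p reporting).
#' @return data frame with one row per state: `state`, `m1`, `sd1`, `n1`,
#'   `m2`, `sd2`, `n2`, `p`, `cohens_d`, `testable`.
#' @export
state_wise_tests <- function(values, group, holm = FALSE) {
  values <- as.matrix(values)
  g <- factor(group)
  stopifnot(nlevels(g) == 2L, length(g) == nrow(values))
  rows <- lapply(seq_len(ncol(values)), function(s) {
    x1 <- values[g == levels(g)[1L], s]; x1 <- x1[is.finite(x1)]
    x2 <- values[g == levels(g)[2L], s]; x2 <- x2[is.finite(x2)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 2L || n2 < 2L) {
      return(data.frame(state = s, m1 = NA_real_, sd1 = NA_real_, n1 = n1,
                        m2 = NA_real_, sd2 = NA_real_, n2 = n2,
                        p = NA_real_, cohens_d = NA_real_, testable = FALSE))
    }
    m1 <- mean(x1); m2 <- mean(x2); s1 <- sd(x1); s2 <- sd(x2)
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    if (sp2 == 0) {
      p <- if (m1 == m2) 1 else 0
      d <- if (m1 == m2) 0 else sign(m2 - m1) * Inf
    } else {
      tstat <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
      p <- 2 * pt(abs(tstat), n1 + n2 - 2, lower.tail = FALSE)
      d <- (m2 - m1) / sqrt(sp2)
    }
    data.frame(state = s, m1 = m1, sd1 = s1, n1 = n1, m2 = m2, sd2 = s2, n2 = n2,
               p = p, cohens_d = d, testable = TRUE)
  })
  out <- do.call(rbind, rows)
  if (holm) out$p_holm <- stats::p.adjust(out$p, method = "holm")
  attr(out, "levels") <- levels(g)
  out
}

#' Pearson correlation between ITI mean and switching rate
#'
#' @param records data frame with columns `iti_mean` and `nt` (one row per
#'   run, after outlier screening).
#' @return list with `r`, `p`, `n`.
#' @export
iti_nt_correlation <- function(records) {
  stopifnot(all(c("iti_mean", "nt") %in% names(records)))
  ok <- is.finite(records$iti_mean) & is.finite(records$nt)
  x <- records$iti_mean[ok]; y <- records$nt[ok]
  if (length(x) < 3L) stop("correlation needs at least 3 runs after screening")
  if (sd(x) == 0 || sd(y) == 0) stop("undefined correlation: zero variance in a metric")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Matched sub-sample robustness analysis
#'
#' Draws, without replacement, from each sex-by-diagnosis cell as many runs
#' as the smallest cell contains, then reruns the two-way ANOVAs on ITI mean,
#' ITI SD and NT on the balanced subset. Seeded and reproducible.
#'
#' @param metrics data frame with columns `run_id`, `sex`, `dx`, `iti_mean`,
#'   `iti_sd`, `nt`.
#' @param seed integer seed.
#' @param ss_type passed to [two_way_anova()].
#' @return list with `n_min`, `selected` (run ids), and `tables` (named list
#'   of `anova_table`s for `iti_mean`, `iti_sd`, `nt`).
#' @export
subsample_analysis <- function(metrics, seed = 1L, ss_type = "III") {
  need <- c("run_id", "sex", "dx", "iti_mean", "iti_sd", "nt")
  stopifnot(all(need %in% names(metrics)))
  cell <- interaction(metrics$sex, metrics$dx, drop = FALSE)
  n_min <- min(table(cell))
  if (n_min < 10L) warning("smallest cell has ", n_min, " runs: sub-sample analysis is underpowered")
  idx <- with_seed(derive_seed(seed, "subsample"), {
    unlist(lapply(split(seq_len(nrow(metrics)), cell), function(i)
      if (length(i) > n_min) sort(sample(i, n_min)) else i), use.names = FALSE)
  })
  sub <- metrics[sort(idx), , drop = FALSE]
  tables <- lapply(c(iti_mean = "iti_mean", iti_sd = "iti_sd", nt = "nt"), function(v)
    two_way_anova(sub[[v]], sub$sex, sub$dx, ss_type = ss_type))
  list(n_min = n_min, selected = sub$run_id, tables = tables)
}
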