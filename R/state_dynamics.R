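#' Construct a decoded state sequence
#'
#' @param labels integer vector of state labels in 1..K.
#' @param run_id run identifier.
#' @param K number of states.
#' @param decoder decoding rule that produced the labels.
#' @return object of class `state_sequence`.
#' @export
state_sequence <- function(labels, run_id, K,
                           decoder = c("viterbi", "posterior_argmax", "truth")) {
  decoder <- match.arg(decoder)
  labels <- as.integer(labels)
  if (!length(labels)) stop("empty state sequence")
  if (any(labels < 1L | labels > K)) stop("state labels must lie in 1..K")
  structure(list(run_id = as.character(run_id), labels = labels, K = as.integer(K),
                 decoder = decoder),
            class = "state_sequence")
}

#' Decode one run under a group model
#'
#' Applies a fitted group HMM to a single (z-scored) run and expresses the
#' decoded labels in consensus state space via the group's relabeling table.
#'
#' @param params the group's [hmm_params] (or `hmm_fit`).
#' @param run a z-scored [ts_run].
#' @param relabeling optional integer vector mapping the group's local state
#'   indices to consensus labels (from [consensus_maps()]); identity if NULL.
#' @param decoder `"viterbi"` (default) or `"posterior_argmax"`.
#' @return a [state_sequence] in consensus label space.
#' @export
decode_run <- function(params, run, relabeling = NULL,
                       decoder = c("viterbi", "posterior_argmax")) {
  decoder <- match.arg(decoder)
  if (inherits(params, "hmm_fit")) params <- params$params
  stopifnot(inherits(run, "ts_run"))
  labels <- switch(decoder,
                   viterbi = viterbi(params, run$data),
                   posterior_argmax = posterior_argmax(params, run$data))
  if (!is.null(relabeling)) labels <- apply_relabeling(labels, relabeling)
  state_sequence(labels, run$run_id, params$K, decoder)
}

seq_labels <- function(x) if (inherits(x, "state_sequence")) x$labels else as.integer(x)

#' Fractional occupancy
#'
#' Proportion of time points spent in each state. At `level = "run"` one
#' K-simplex per sequence is returned (rows of a matrix); at
#' `level = "group"` occupancy is pooled over all time points of all
#' sequences, which equals the run-length-weighted mean of the run-level
#' vectors.
#'
#' @param seqs a [state_sequence], a label vector, or a list of either.
#' @param K number of states.
#' @param level `"run"` or `"group"`.
#' @return run level: N x K matrix (rows sum to 1); group level: length-K
#'   vector summing to 1.
#' @export
fractional_occupancy <- function(seqs, K, level = c("run", "group")) {
  level <- match.arg(level)
  if (inherits(seqs, "state_sequence") || !is.list(seqs)) seqs <- list(seqs)
  if (!length(seqs)) stop("empty input: no state sequences")
  counts <- t(vapply(seqs, function(s) {
    l <- seq_labels(s)
    tabulate(l, nbins = K)
  }, numeric(K)))
  if (level == "run") {
    fo <- counts / rowSums(counts)
    colnames(fo) <- paste0("fo_", seq_len(K))
    fo
  } else {
    tot <- colSums(counts)
    tot / sum(tot)
  }
}

#' Empirical transition counts and probabilities
#'
#' Counts consecutive-pair occurrences within a single sequence and converts
#' them to a row-stochastic empirical transition probability matrix. Rows with
#' no outgoing transitions are reported as `NA` (undefined), never silently
#' zero.
#'
#' @param seq a [state_sequence] or label vector.
#' @param K number of states.
#' @return list with `counts` (K x K integer), `tpm` (K x K, undefined rows
#'   NA), `undefined_rows` (integer vector).
#' @export
empirical_transitions <- function(seq, K) {
  l <- seq_labels(seq)
  T_ <- length(l)
  if (T_ < 2L) stop("degenerate input: need at least 2 time points for transitions")
  counts <- matrix(0L, K, K)
  pair <- cbind(l[-T_], l[-1L])
  tab <- table(factor(pair[, 1L], levels = seq_len(K)),
               factor(pair[, 2L], levels = seq_len(K)))
  counts[] <- as.integer(tab)
  rs <- rowSums(counts)
  tpm <- counts / ifelse(rs > 0, rs, NA_real_)
  list(counts = counts, tpm = tpm, undefined_rows = which(rs == 0))
}

#' Maximal dwell episodes of a state sequence
#'
#' Splits a sequence into maximal runs of a constant state. The final
#' (right-censored) episode is included. Episode lengths always sum to T.
#'
#' @param seq a [state_sequence] or label vector.
#' @return data frame with columns `state`, `length`, `start_index` (0-based).
#' @export
dwell_episodes <- function(seq) {
  l <- seq_labels(seq)
  if (!length(l)) stop("empty sequence")
  r <- rle(l)
  data.frame(state = r$values, length = r$lengths,
             start_index = cumsum(c(0L, r$lengths[-length(r$lengths)])))
}

#' Inter-transition interval statistics
#'
#' Per-episode dwell measures for one run. Under the default
#' `"dwell_minus_one"` convention an episode of length L contributes L - 1
#' (time points spent in the state beyond its first); under `"dwell"` it
#' contributes L. The run's ITI mean and sample SD are taken over all
#' episodes; per-state means cover only episodes of that state, and are
#' `NA` for unvisited states.
#'
#' @param episodes data frame from [dwell_episodes()].
#' @param K number of states.
#' @param convention `"dwell_minus_one"` (default) or `"dwell"`.
#' @return list with `iti_mean`, `iti_sd` (NA with a message attribute when
#'   only one episode exists), `per_state` (length-K named vector).
#' @export
iti_stats <- function(episodes, K, convention = c("dwell_minus_one", "dwell")) {
  convention <- match.arg(convention)
  if (!nrow(episodes)) stop("need at least one episode")
  v <- if (convention == "dwell") episodes$length else episodes$length - 1L
  per_state <- vapply(seq_len(K), function(s) {
    x <- v[episodes$state == s]
    if (length(x)) mean(x) else NA_real_
  }, numeric(1))
  names(per_state) <- paste0("iti_state_", seq_len(K))
  iti_sd <- if (length(v) >= 2L) sd(v) else NA_real_
  list(iti_mean = mean(v), iti_sd = iti_sd, per_state = per_state,
       n_episodes = length(v))
}

#' Number of transitions per time point
#'
#' Count of state changes divided by the sequence length T: the switching
#' rate, bounded by (T-1)/T.
#'
#' @param seq a [state_sequence] or label vector.
#' @return switching rate in `[0, (T-1)/T]`.
#' @export
number_of_transitions <- function(seq) {
  l <- seq_labels(seq)
  if (length(l) < 2L) stop("degenerate input: need at least 2 time points")
  sum(diff(l) != 0L) / length(l)
}

#' Screen a metric for outliers by pooled z-score
#'
#' Scales the values by their pooled mean and sample SD (all runs together,
#' across groups) and flags values whose absolute z-score strictly exceeds
#' the threshold. A single pass: no re-scoring after removal.
#'
#' @param values numeric vector (one value per run).
#' @param threshold_sd removal threshold in SD units (default 3).
#' @param ids optional run identifiers for the report.
#' @return list with `keep` (logical mask), `report` (data frame of removed
#'   id, value, z), and `zero_variance` flag (TRUE => nothing removed, with a
#'   warning).
#' @export
screen_outliers <- function(values, threshold_sd = 3, ids = NULL) {
  ok <- is.finite(values)
  if (sum(ok) < 3L) stop("outlier screening needs at least 3 finite values")
  if (is.null(ids)) ids <- as.character(seq_along(values))
  m <- mean(values[ok]); s <- sd(values[ok])
  if (s == 0) {
    warning("zero variance in metric: no outliers removed")
    return(list(keep = ok, report = data.frame(id = character(0), value = numeric(0),
                                               z = numeric(0)),
                zero_variance = TRUE))
  }
  z <- (values - m) / s
  removed <- ok & abs(z) > threshold_sd
  list(keep = ok & !removed,
       report = data.frame(id = ids[removed], value = values[removed],
                           z = z[removed], stringsAsFactors = FALSE),
       zero_variance = FALSE)
}

#' Per-run dynamics records for a set of decoded sequences
#'
#' Convenience wrapper computing, for every sequence, fractional occupancy,
#' number of transitions, and ITI mean/SD (overall and per state).
#'
#' @param seqs list of [state_sequence] objects.
#' @param K number of states.
#' @param convention ITI convention, see [iti_stats()].
#' @return data frame with one row per run: `run_id`, `fo_1..fo_K`, `nt`,
#'   `iti_mean`, `iti_sd`, `iti_state_1..K`, `n_episodes`.
#' @export
compute_dynamics <- function(seqs, K, convention = c("dwell_minus_one", "dwell")) {
  convention <- match.arg(convention)
  stopifnot(length(seqs) >= 1L)
  rows <- lapply(seqs, function(s) {
    ep <- dwell_episodes(s)
    iti <- iti_stats(ep, K, convention)
    fo <- fractional_occupancy(s, K, "run")
    cbind(data.frame(run_id = if (inherits(s, "state_sequence")) s$run_id else NA_character_,
                     stringsAsFactors = FALSE),
          as.data.frame(fo),
          data.frame(nt = number_of_transitions(s),
                     iti_mean = iti$iti_mean, iti_sd = iti$iti_sd,
                     n_episodes = iti$n_episodes),
          as.data.frame(t(iti$per_state)))
  })
  do.call(rbind, rows)
}
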