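#' Ground-truth configuration for a synthetic cohort
#'
#' Defines the generative world for a four-group (sex x diagnosis) cohort of
#' resting-state-like parcel time series driven by known per-group hidden
#' Markov chains. Defaults emulate the published cohort shape: group scan
#' counts 99/347/251/257, run lengths 80-230 TRs, 190 channels, five states
#' with group mean on-diagonal transition probability near 0.53, and
#' injectable sex/diagnosis effects on dwell dynamics (boys stickier than
#' girls; ADHD with larger between-run transition-matrix variability).
#'
#' @param K number of latent states (>= 2).
#' @param C number of channels (parcels).
#' @param runs_per_group integer vector of 4 scan counts, ordered
#'   `girl_ADHD`, `boy_ADHD`, `girl_control`, `boy_control`.
#' @param run_length_range `(Tmin, Tmax)` inclusive bounds for uniform-integer
#'   run lengths; `Tmin >= 10`.
#' @param on_diag_by_group per-group on-diagonal transition probability in
#'   (0,1); defaults inject the sex effect (girls 0.50, boys 0.56, mean 0.53).
#' @param state_map_templates optional K x C matrix of shared state templates;
#'   by default a deterministic block design with amplitude
#'   `2 * emission_noise_sd` (2-SD separation between states on their
#'   signature channels).
#' @param map_group_jitter_sd SD of per-group Gaussian jitter added to the
#'   templates (group-specific spatial variation of the shared states).
#' @param emission_noise_sd SD of iid Gaussian observation noise.
#' @param subject_tpm_jitter_sd per-group SD of the logit-space perturbation
#'   applied to each run's transition matrix (between-run dwell variability);
#'   defaults make ADHD twice as variable as controls, calibrated so the
#'   recovered boy-girl ITI effect lands on the d ~ 0.2-0.35 scale at the
#'   default cohort size.
#' @param seed integer master seed.
#' @return validated object of class `gt_config`.
#' @export
gt_config <- function(K = 5L, C = 190L,
                      runs_per_group = c(girl_ADHD = 99L, boy_ADHD = 347L,
                                         girl_control = 251L, boy_control = 257L),
                      run_length_range = c(80L, 230L),
                      on_diag_by_group = c(girl_ADHD = 0.50, boy_ADHD = 0.56,
                                           girl_control = 0.50, boy_control = 0.56),
                      state_map_templates = NULL,
                      map_group_jitter_sd = 0.05,
                      emission_noise_sd = 1.0,
                      subject_tpm_jitter_sd = c(girl_ADHD = 1.0, boy_ADHD = 1.0,
                                                girl_control = 0.5, boy_control = 0.5),
                      seed = 1L) {
  K <- as.integer(K); C <- as.integer(C)
  if (K < 2L) stop("invalid config: K must be >= 2")
  if (C < 1L) stop("invalid config: C must be >= 1")
  runs_per_group <- as.integer(rep_len(runs_per_group, 4L))
  if (any(runs_per_group < 1L)) stop("invalid config: runs_per_group must all be >= 1")
  names(runs_per_group) <- GROUP_LEVELS
  run_length_range <- as.integer(run_length_range)
  if (length(run_length_range) != 2L || run_length_range[1L] < 10L ||
      run_length_range[2L] < run_length_range[1L])
    stop("invalid config: run_length_range must be (Tmin, Tmax) with Tmin >= 10")
  on_diag_by_group <- rep_len(as.numeric(on_diag_by_group), 4L)
  if (any(on_diag_by_group <= 0 | on_diag_by_group >= 1))
    stop("invalid config: on_diag values must lie strictly in (0, 1)")
  names(on_diag_by_group) <- GROUP_LEVELS
  if (!is_scalar_number(emission_noise_sd) || emission_noise_sd <= 0)
    stop("invalid config: emission_noise_sd must be positive")
  if (!is_scalar_number(map_group_jitter_sd) || map_group_jitter_sd < 0)
    stop("invalid config: map_group_jitter_sd must be nonnegative")
  subject_tpm_jitter_sd <- rep_len(as.numeric(subject_tpm_jitter_sd), 4L)
  if (any(subject_tpm_jitter_sd < 0))
    stop("invalid config: subject_tpm_jitter_sd must be nonnegative")
  names(subject_tpm_jitter_sd) <- GROUP_LEVELS
  if (is.null(state_map_templates)) {
    state_map_templates <- block_templates(K, C, 2 * emission_noise_sd)
  } else {
    state_map_templates <- as.matrix(state_map_templates)
    if (!all(dim(state_map_templates) == c(K, C)))
      stop("invalid config: state_map_templates must be K x C")
  }
  structure(list(K = K, C = C, runs_per_group = runs_per_group,
                 run_length_range = run_length_range,
                 on_diag_by_group = on_diag_by_group,
                 state_map_templates = state_map_templates,
                 map_group_jitter_sd = map_group_jitter_sd,
                 emission_noise_sd = emission_noise_sd,
                 subject_tpm_jitter_sd = subject_tpm_jitter_sd,
                 seed = as.integer(seed)),
            class = "gt_config")
}

# Deterministic K x C block templates: state k elevates its own contiguous
# block of channels by `amplitude`, all other channels 0, so any two states
# differ by `amplitude` on 2 blocks of channels.
block_templates <- function(K, C, amplitude) {
  tpl <- matrix(0, K, C)
  cuts <- floor(seq(0, C, length.out = K + 1L))
  for (k in seq_len(K)) {
    if (cuts[k + 1L] > cuts[k]) tpl[k, (cuts[k] + 1L):cuts[k + 1L]] <- amplitude
  }
  tpl
}

group_tpm <- function(K, on_diag) {
  P <- matrix((1 - on_diag) / (K - 1), K, K)
  diag(P) <- on_diag
  P
}

# Row-renormalized logit-space perturbation of a row-stochastic matrix.
perturb_tpm <- function(P, sd) {
  if (sd == 0) return(P)
  E <- matrix(rnorm(length(P), 0, sd), nrow(P), ncol(P))
  Z <- log(P) + E
  t(apply(Z, 1L, function(z) { e <- exp(z - max(z)); e / sum(e) }))
}

#' Materialize a ground-truth model from a configuration
#'
#' Builds the per-group transition matrices (configured on-diagonal value,
#' remaining mass split evenly off-diagonal), the per-group emission maps
#' (template plus group jitter), and one realized transition matrix per run
#' (logit-space perturbation of the group matrix, row-renormalized). All
#' randomness derives from the config seed, so the same config yields an
#' identical model.
#'
#' @param config a [gt_config].
#' @return object of class `gt_model`: list with `config`, `group_params`
#'   (named list of [hmm_params]), `run_info` (data frame subject_id, run_id,
#'   group, T), `run_tpms` (list of per-run matrices, parallel to `run_info`).
#' @export
make_ground_truth <- function(config) {
  stopifnot(inherits(config, "gt_config"))
  K <- config$K; C <- config$C
  group_params <- list()
  run_info <- list()
  run_tpms <- list()
  for (g in GROUP_LEVELS) {
    P <- group_tpm(K, config$on_diag_by_group[[g]])
    maps <- with_seed(derive_seed(config$seed, "maps", g), {
      config$state_map_templates +
        matrix(rnorm(K * C, 0, config$map_group_jitter_sd), K, C)
    })
    vars <- matrix(config$emission_noise_sd^2, K, C)
    group_params[[g]] <- hmm_params(stationary_distribution(P), P, maps, vars)
    n <- config$runs_per_group[[g]]
    lens <- with_seed(derive_seed(config$seed, "lengths", g), {
      span <- config$run_length_range[2L] - config$run_length_range[1L] + 1L
      config$run_length_range[1L] + sample.int(span, n, replace = TRUE) - 1L
    })
    tpms <- with_seed(derive_seed(config$seed, "tpms", g), {
      lapply(seq_len(n), function(i) perturb_tpm(P, config$subject_tpm_jitter_sd[[g]]))
    })
    ids <- sprintf("%s_%03d", g, seq_len(n))
    run_info[[g]] <- data.frame(subject_id = paste0("sub_", ids),
                                run_id = paste0("run_", ids),
                                group = g, T = lens, stringsAsFactors = FALSE)
    run_tpms[[g]] <- tpms
  }
  structure(list(config = config,
                 group_params = group_params,
                 run_info = do.call(rbind, c(run_info, list(make.row.names = FALSE))),
                 run_tpms = run_tpms),
            class = "gt_model")
}

#' @export
print.gt_model <- function(x, ...) {
  cat(sprintf("<gt_model> K=%d, C=%d, %d runs (%s)\n", x$config$K, x$config$C,
              nrow(x$run_info),
              paste(x$config$runs_per_group, collapse = "/")))
  invisible(x)
}

#' Simulate one run from a ground-truth model
#'
#' Samples a hidden path from the run's Markov chain (initial distribution =
#' the stationary distribution of the run's matrix) and emits observations as
#' the active state's mean map plus iid Gaussian noise. The true path is
#' returned alongside the data so recovery can be scored exactly.
#'
#' @param model a `gt_model`.
#' @param group one of the four group keys.
#' @param T run length in time points (>= 2).
#' @param run_index index of the run within the group, selecting its realized
#'   transition matrix; NULL uses the group-level matrix.
#' @param seed integer seed for this run's randomness.
#' @param run_id,subject_id identifiers for the emitted [ts_run].
#' @return list with `run` (a [ts_run]) and `states` (a [state_sequence] of
#'   the true path, decoder `"truth"`).
#' @export
simulate_run <- function(model, group, T, run_index = NULL, seed = 1L,
                         run_id = "sim_run", subject_id = "sim_subject") {
  stopifnot(inherits(model, "gt_model"), group %in% GROUP_LEVELS, T >= 2L)
  K <- model$config$K
  P <- if (is.null(run_index)) model$group_params[[group]]$trans
       else model$run_tpms[[group]][[run_index]]
  mu <- model$group_params[[group]]$means
  noise_sd <- model$config$emission_noise_sd
  sim <- with_seed(seed, {
    init <- stationary_distribution(P)
    path <- integer(T)
    path[1L] <- sample.int(K, 1L, prob = init)
    for (t in 2L:T) path[t] <- sample.int(K, 1L, prob = P[path[t - 1L], ])
    obs <- mu[path, , drop = FALSE] +
      matrix(rnorm(T * model$config$C, 0, noise_sd), T, model$config$C)
    list(path = path, obs = obs)
  })
  list(run = ts_run(sim$obs, subject_id = subject_id, run_id = run_id),
       states = state_sequence(sim$path, run_id, K, "truth"))
}

#' Simulate a complete four-group cohort
#'
#' Materializes the ground truth, simulates every run, and builds a
#' phenotype table in exactly the format the ingest layer reads. Optionally
#' writes runs, phenotypes and the truth bundle to disk.
#'
#' @param config a [gt_config].
#' @param dir optional output directory; when given, writes
#'   `runs/<run_id>.tsv`, `phenotypes.csv`, and `truth.json`.
#' @return list with `runs` (list of [ts_run]), `phenotypes` (data frame),
#'   `truth` (the `gt_model`), `true_sequences` (list of true-path
#'   [state_sequence]s, named by run_id).
#' @export
simulate_cohort <- function(config, dir = NULL) {
  stopifnot(inherits(config, "gt_config"))
  model <- make_ground_truth(config)
  info <- model$run_info
  runs <- vector("list", nrow(info))
  seqs <- vector("list", nrow(info))
  within_idx <- stats::ave(seq_len(nrow(info)), info$group, FUN = seq_along)
  ages <- with_seed(derive_seed(config$seed, "ages"), {
    pmax(round(rnorm(nrow(info), 11.4, 2.9), 2), 6)
  })
  subtypes <- with_seed(derive_seed(config$seed, "subtypes"), {
    ifelse(grepl("ADHD", info$group),
           sample(c("hyperactive/impulsive", "inattentive", "combined"),
                  nrow(info), replace = TRUE, prob = c(0.04, 0.41, 0.55)),
           "none")
  })
  for (i in seq_len(nrow(info))) {
    sim <- simulate_run(model, info$group[i], info$T[i], run_index = within_idx[i],
                        seed = derive_seed(config$seed, "run", info$run_id[i]),
                        run_id = info$run_id[i], subject_id = info$subject_id[i])
    runs[[i]] <- sim$run
    seqs[[i]] <- sim$states
  }
  names(seqs) <- info$run_id
  phenotypes <- data.frame(
    subject_id = info$subject_id, run_id = info$run_id,
    sex = ifelse(grepl("^girl", info$group), "girl", "boy"),
    dx = ifelse(grepl("ADHD$", info$group), "ADHD", "control"),
    age = ages, subtype = subtypes, site = "synthetic",
    stringsAsFactors = FALSE)
  out <- list(runs = runs, phenotypes = phenotypes, truth = model,
              true_sequences = seqs)
  if (!is.null(dir)) write_cohort(out, dir)
  out
}

write_cohort <- function(cohort, dir) {
  run_dir <- file.path(dir, "runs")
  dir.create(run_dir, recursive = TRUE, showWarnings = FALSE)
  for (r in cohort$runs) {
    ok <- tryCatch(
      write_roi_timeseries(r, file.path(run_dir, paste0(r$run_id, ".tsv")), "tsv"),
      error = function(e) stop("failed writing run '", r$run_id, "' to ", run_dir,
                               ": ", conditionMessage(e)))
  }
  write.csv(cohort$phenotypes, file.path(dir, "phenotypes.csv"), row.names = FALSE)
  truth <- cohort$truth
  jsonlite::write_json(
    list(seed = truth$config$seed,
         K = truth$config$K, C = truth$config$C,
         on_diag_by_group = as.list(truth$config$on_diag_by_group),
         group_tpms = lapply(truth$group_params, `[[`, "trans"),
         group_maps = lapply(truth$group_params, `[[`, "means"),
         run_info = truth$run_info,
         true_paths = lapply(cohort$true_sequences, `[[`, "labels")),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a cohort directory written by [simulate_cohort()]
#'
#' @param dir directory containing `runs/` and `phenotypes.csv`.
#' @return list with `runs` and `phenotypes`.
#' @export
read_cohort <- function(dir) {
  pheno <- read_phenotypes(file.path(dir, "phenotypes.csv"))
  run_dir <- file.path(dir, "runs")
  if (!dir.exists(run_dir)) stop("no runs/ directory under ", dir)
  runs <- lapply(seq_len(nrow(pheno)), function(i) {
    path <- file.path(run_dir, paste0(pheno$run_id[i], ".tsv"))
    read_roi_timeseries(path, subject_id = pheno$subject_id[i],
                        run_id = pheno$run_id[i],
                        site = if ("site" %in% names(pheno)) pheno$site[i] else NULL)
  })
  list(runs = runs, phenotypes = pheno)
}
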