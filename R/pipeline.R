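default_config <- function() {
  list(
    cohort_dir = NULL,
    out_dir = NULL,
    seed = 1L,
    simulate = list(enabled = FALSE, K = 5L, C = 190L,
                    runs_per_group = c(99L, 347L, 251L, 257L),
                    run_length_range = c(80L, 230L),
                    on_diag_by_group = c(0.50, 0.56, 0.50, 0.56),
                    map_group_jitter_sd = 0.05,
                    emission_noise_sd = 1.0,
                    subject_tpm_jitter_sd = c(1.0, 1.0, 0.5, 0.5)),
    hmm = list(k = 5L, scan = NULL, covariance = "diagonal", restarts = 5L,
               tol = 1e-4, max_iter = 200L),
    alignment = list(k = 5L, n_init = 50L),
    dynamics = list(decoder = "viterbi", iti_convention = "dwell_minus_one",
                    outlier_sd = 3),
    stats = list(ss_type = "III")
  )
}

merge_config <- function(defaults, user, path = character(0)) {
  errors <- character(0)
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      errors <- c(errors, paste0("unknown key: ", full))
      next
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]])) {
        errors <- c(errors, paste0("key ", full, " must be a mapping"))
        next
      }
      sub <- merge_config(defaults[[key]], user[[key]], c(path, key))
      defaults[[key]] <- sub$config
      errors <- c(errors, sub$errors)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  list(config = defaults, errors = errors)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills every omitted setting with its
#' documented default, and rejects unknown keys so typos never silently fall
#' back to defaults. All schema violations are reported at once.
#'
#' @param x path to a YAML file, or a named list.
#' @return validated, fully defaulted config list of class `pipeline_config`.
#' @export
validate_config <- function(x) {
  user <- if (is.character(x)) {
    if (!file.exists(x)) stop("config file not found: ", x)
    yaml::read_yaml(x) %||% list()
  } else if (is.list(x)) x else stop("config must be a file path or a list")
  m <- merge_config(default_config(), user)
  cfg <- m$config
  errors <- m$errors
  chk <- function(cond, msg) if (!cond) errors <<- c(errors, msg)
  chk(is_scalar_number(cfg$seed), "seed must be a single integer")
  chk(cfg$hmm$covariance %in% c("diagonal", "full"),
      "hmm.covariance must be 'diagonal' or 'full'")
  chk(cfg$dynamics$decoder %in% c("viterbi", "posterior_argmax"),
      "dynamics.decoder must be 'viterbi' or 'posterior_argmax'")
  chk(cfg$dynamics$iti_convention %in% c("dwell_minus_one", "dwell"),
      "dynamics.iti_convention must be 'dwell_minus_one' or 'dwell'")
  chk(cfg$stats$ss_type %in% c("III", "II"), "stats.ss_type must be 'III' or 'II'")
  chk(is_scalar_number(cfg$dynamics$outlier_sd) && cfg$dynamics$outlier_sd > 0,
      "dynamics.outlier_sd must be positive")
  if (!is.null(cfg$cohort_dir) && !isTRUE(cfg$simulate$enabled))
    chk(dir.exists(cfg$cohort_dir),
        paste0("cohort_dir does not exist: ", cfg$cohort_dir))
  if (length(errors)) stop("invalid configuration:\n  - ",
                           paste(errors, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

stage_checksums <- function(files) {
  files <- files[file.exists(files)]
  as.list(tools::md5sum(files))
}

#' Run the full latent-state dynamics pipeline
#'
#' Orchestrates simulate (optional) -> ingest -> fit -> align -> metrics ->
#' stats, writing every stage's outputs plus a manifest (stage, outputs,
#' seed, checksums, wall time) under `out_dir`. A single global seed
#' deterministically derives every per-stage and per-group seed, so re-runs
#' are byte-identical.
#'
#' @param config a `pipeline_config` (from [validate_config()]) or something
#'   coercible to one.
#' @param verbose log stage progress to stderr.
#' @return list with `manifest` (data frame), `results` (per-stage R
#'   objects), invisibly written artifacts under `out_dir` if set.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  if (is.null(config$cohort_dir) && !isTRUE(config$simulate$enabled))
    stop("invalid configuration: cohort_dir is required unless simulate.enabled is true")
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  results <- list()
  seed <- config$seed
  t_stage <- function(name, expr) {
    bs_log(name, "start", verbose)
    t0 <- proc.time()[["elapsed"]]
    value <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    manifest[[name]] <<- data.frame(
      stage = name, seconds = round(proc.time()[["elapsed"]] - t0, 3),
      seed = seed, stringsAsFactors = FALSE)
    value
  }

  # 1. simulate (optional)
  cohort_dir <- config$cohort_dir
  if (isTRUE(config$simulate$enabled)) {
    results$simulate <- t_stage("simulate", {
      s <- config$simulate
      cfg <- gt_config(K = s$K, C = s$C, runs_per_group = s$runs_per_group,
                       run_length_range = s$run_length_range,
                       on_diag_by_group = s$on_diag_by_group,
                       map_group_jitter_sd = s$map_group_jitter_sd,
                       emission_noise_sd = s$emission_noise_sd,
                       subject_tpm_jitter_sd = s$subject_tpm_jitter_sd,
                       seed = derive_seed(seed, "simulate"))
      if (is.null(cohort_dir)) {
        if (is.null(out_dir)) stop("simulate needs cohort_dir or out_dir")
        cohort_dir <- file.path(out_dir, "cohort")
      }
      simulate_cohort(cfg, dir = cohort_dir)
    })
  } else {
    manifest[["simulate"]] <- data.frame(stage = "simulate", seconds = 0,
                                         seed = seed, stringsAsFactors = FALSE)
  }

  # 2. ingest: read, z-score, assemble groups
  groups <- t_stage("ingest", {
    cohort <- if (!is.null(results$simulate))
      list(runs = results$simulate$runs, phenotypes = results$simulate$phenotypes)
    else read_cohort(cohort_dir)
    z <- lapply(cohort$runs, zscore_run)
    assemble_groups(z, cohort$phenotypes)
  })
  results$groups <- groups

  # 3. fit per group
  fits <- t_stage("fit", {
    lapply(groups, function(gd) {
      obs <- group_data(gd)
      h <- config$hmm
      if (!is.null(h$scan)) {
        sc <- scan_states(obs, gd$boundaries$length, k_min = h$scan[1L],
                          k_max = h$scan[2L], covariance = h$covariance,
                          n_restarts = h$restarts, max_iter = h$max_iter,
                          tol = h$tol, seed = derive_seed(seed, "fit", gd$group_key))
        k <- select_elbow(sc)$k
        list(scan = sc,
             fit = sc$entries[[which(vapply(sc$entries, `[[`, integer(1), "K") == k)]])
      } else {
        list(scan = NULL,
             fit = em_fit(obs, gd$boundaries$length, K = h$k,
                          covariance = h$covariance, n_restarts = h$restarts,
                          max_iter = h$max_iter, tol = h$tol,
                          seed = derive_seed(seed, "fit", gd$group_key)))
      }
    })
  })
  results$fits <- fits
  fit_params <- lapply(fits, function(f)
    if (inherits(f$fit, "hmm_fit")) f$fit$params else f$fit$params)

  # 4. align states across groups
  aligned <- t_stage("align", {
    maps <- lapply(GROUP_LEVELS, function(g) extract_state_maps(fit_params[[g]], g))
    asg <- cluster_state_maps(maps, k = config$alignment$k,
                              n_init = config$alignment$n_init,
                              seed = derive_seed(seed, "align"))
    cons <- if (asg$valid) consensus_maps(maps, asg) else NULL
    list(maps = maps, assignment = asg, consensus = cons)
  })
  results$aligned <- aligned
  if (is.null(aligned$consensus))
    stop("pipeline stage 'align' failed: cluster assignment is not valid; ",
         "see results$aligned$assignment$violations")

  # 5. metrics: decode every run, compute dynamics, screen outliers
  metrics <- t_stage("metrics", {
    K <- config$alignment$k
    per_group <- lapply(GROUP_LEVELS, function(g) {
      gd <- groups[[g]]
      if (!length(gd$runs)) return(NULL)
      relab <- aligned$consensus$relabeling[[g]]
      seqs <- lapply(gd$runs, function(r)
        decode_run(fit_params[[g]], r, relab, decoder = config$dynamics$decoder))
      dyn <- compute_dynamics(seqs, K, convention = config$dynamics$iti_convention)
      dyn$group <- g
      dyn$sex <- gd$sex
      dyn$dx <- gd$dx
      dyn
    })
    dyn <- do.call(rbind, per_group)
    scr_iti <- screen_outliers(dyn$iti_mean, config$dynamics$outlier_sd, dyn$run_id)
    scr_sd <- screen_outliers(dyn$iti_sd, config$dynamics$outlier_sd, dyn$run_id)
    scr_nt <- screen_outliers(dyn$nt, config$dynamics$outlier_sd, dyn$run_id)
    dyn$outlier_iti <- !(scr_iti$keep & scr_sd$keep)
    dyn$outlier_nt <- !scr_nt$keep
    dyn
  })
  results$metrics <- metrics

  # 6. stats: factorial ANOVAs, per-state tests, correlation, sub-sample
  stats_out <- t_stage("stats", {
    K <- config$alignment$k
    iti <- metrics[!metrics$outlier_iti, , drop = FALSE]
    nt <- metrics[!metrics$outlier_nt, , drop = FALSE]
    per_state <- as.matrix(iti[, paste0("iti_state_", seq_len(K)), drop = FALSE])
    list(
      anova_iti_mean = two_way_anova(iti$iti_mean, iti$sex, iti$dx, config$stats$ss_type),
      anova_iti_sd = two_way_anova(iti$iti_sd, iti$sex, iti$dx, config$stats$ss_type),
      anova_nt = two_way_anova(nt$nt, nt$sex, nt$dx, config$stats$ss_type),
      anova_fo_mixed = mixed_anova_fo(
        as.matrix(metrics[, paste0("fo_", seq_len(K)), drop = FALSE]),
        metrics$sex, metrics$dx),
      statewise_sex_iti = state_wise_tests(per_state,
                                           factor(iti$sex, levels = SEX_LEVELS)),
      correlation = iti_nt_correlation(metrics[!metrics$outlier_iti & !metrics$outlier_nt, ]),
      subsample = subsample_analysis(iti, seed = derive_seed(seed, "stats"),
                                     ss_type = config$stats$ss_type))
  })
  results$stats <- stats_out

  if (!is.null(out_dir)) {
    write.csv(metrics, file.path(out_dir, "dynamics.csv"), row.names = FALSE)
    write.csv(as.data.frame(aligned$consensus$consensus),
              file.path(out_dir, "consensus_maps.csv"))
    for (nm in names(stats_out)) {
      obj <- stats_out[[nm]]
      if (is.data.frame(obj))
        write.csv(obj, file.path(out_dir, paste0(nm, ".csv")), row.names = FALSE)
    }
    jsonlite::write_json(stats_out$correlation,
                         file.path(out_dir, "correlation.json"), auto_unbox = TRUE)
    jsonlite::write_json(aligned$consensus$relabeling,
                         file.path(out_dir, "relabeling.json"))
  }

  man <- do.call(rbind, c(manifest, list(make.row.names = FALSE)))
  if (!is.null(out_dir)) {
    outs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
    outs <- outs[!grepl("manifest\\.json$", outs)]
    jsonlite::write_json(list(stages = man, checksums = stage_checksums(outs)),
                         file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  }
  list(manifest = man, results = results)
}
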