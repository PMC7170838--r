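# End-to-end orchestration: simulate (or ingest) -> quality filter ->
# triplicate averaging -> VAE train/reconstruct -> features -> Lasso screen
# -> exhaustive AICc search -> with/without-Monot1-2 ANOVA -> report.

#' Pipeline configuration
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"ingest"`
#'   (read waveform and covariate tables from disk).
#' @param sim A [sim_config()] (simulate mode).
#' @param input_table,covariate_table CSV paths (ingest mode).
#' @param quality_threshold Quality filter threshold (default 7.5).
#' @param average_mode `"traces"` (average waveforms, then compute features)
#'   or `"parameters"` (compute features per replicate, then average them).
#' @param features_on `"reconstructed"` (compute features on VAE-denoised
#'   traces; default) or `"raw"`.
#' @param vae_epochs,vae_batch_size,vae_learning_rate,vae_beta VAE training
#'   settings.
#' @param k_screen Number of Lasso candidates (default 20).
#' @param top_k AICc leaderboard size.
#' @param n_frames Traversal animation frames.
#' @param make_animation Write the traversal animation when an output
#'   directory is given.
#' @param monot_method Passed to [monot12()].
#' @param seed Master seed; fixes the simulator, VAE initialization and
#'   training, and therefore every reported number.
#' @return Object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "ingest"),
                       sim = sim_config(),
                       input_table = NULL, covariate_table = NULL,
                       quality_threshold = 7.5,
                       average_mode = c("traces", "parameters"),
                       features_on = c("reconstructed", "raw"),
                       vae_epochs = 500, vae_batch_size = 16,
                       vae_learning_rate = 1e-3, vae_beta = NULL,
                       k_screen = 20, top_k = 10, n_frames = 11,
                       make_animation = TRUE,
                       monot_method = c("adverse", "arclength"),
                       seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "ingest" &&
      (is.null(input_table) || is.null(covariate_table))) {
    stop("ingest mode requires input_table and covariate_table")
  }
  structure(list(mode = mode, sim = sim,
                 input_table = input_table,
                 covariate_table = covariate_table,
                 quality_threshold = quality_threshold,
                 average_mode = match.arg(average_mode),
                 features_on = match.arg(features_on),
                 vae_epochs = vae_epochs, vae_batch_size = vae_batch_size,
                 vae_learning_rate = vae_learning_rate, vae_beta = vae_beta,
                 k_screen = k_screen, top_k = top_k, n_frames = n_frames,
                 make_animation = make_animation,
                 monot_method = match.arg(monot_method),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value YAML; keys mirror the arguments of [run_config()], with
#' simulator settings nested under `sim`.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$sim)) raw$sim <- do.call(sim_config, raw$sim)
  do.call(run_config, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order under one master seed and performs the
#' headline comparison: the optimal model versus the same model with Monot1-2
#' removed (or, when Monot1-2 was not selected, versus the model with it
#' added), via [anova_nested()]. With `outdir` set, writes a JSON + markdown
#' report, the univariate and leaderboard tables, a VAE checkpoint, and the
#' traversal animation; partial outputs are removed if a stage fails.
#'
#' @param config A [run_config()].
#' @param outdir Optional output directory.
#' @param seed Overrides `config$seed` when given.
#' @return Object of class `report_bundle`.
#' @export
run_pipeline <- function(config, outdir = NULL, seed = config$seed) {
  stopifnot(inherits(config, "run_config"))
  created <- character(0)
  on.exit({
    if (length(created) > 0) unlink(created)
  })
  note_file <- function(p) created <<- c(created, p)

  cohort <- NULL
  if (config$mode == "simulate") {
    cfg <- config$sim
    cfg$seed <- as.integer(seed)
    input <- .stage("simulate", {
      cohort <- simulate_cohort(cfg)
      list(ws = cohort$records, cov = cohort$covariates)
    })
  } else {
    input <- .stage("ingest", {
      list(ws = read_waveform_table(config$input_table),
           cov = read_covariate_table(config$covariate_table))
    })
  }
  ws <- input$ws
  n_simulated <- n_records(ws)
  all_eyes <- unique(ws$meta$eye_id)

  wf <- .stage("quality_filter",
               filter_by_quality(ws, config$quality_threshold))
  n_filtered <- n_records(wf)

  # VAE is trained on the averaged per-eye traces (one clean estimate per
  # eye) in trace-averaging mode, or on the surviving replicates otherwise.
  wa <- .stage("average", average_replicates(wf, expected_eyes = all_eyes))
  n_eyes_used <- n_records(wa)

  vae_traces <- if (config$average_mode == "traces") wa$traces else wf$traces
  model <- .stage("vae_train", {
    arch <- vae_arch(input_dim = ncol(vae_traces))
    m <- init_vae(arch, seed = seed + 1L)
    train_vae(m, vae_traces, epochs = config$vae_epochs,
              batch_size = config$vae_batch_size,
              learning_rate = config$vae_learning_rate,
              seed = seed + 2L, beta = config$vae_beta)
  })

  features <- .stage("features", {
    if (config$average_mode == "traces") {
      tr <- if (config$features_on == "reconstructed") {
        reconstruct(model, wa$traces)
      } else wa$traces
      feature_table(tr, eye_id = wa$meta$eye_id,
                    monot_method = config$monot_method)
    } else {
      tr <- if (config$features_on == "reconstructed") {
        reconstruct(model, wf$traces)
      } else wf$traces
      per_rep <- feature_table(tr, eye_id = wf$meta$eye_id,
                               monot_method = config$monot_method)
      eye <- factor(per_rep$eye_id, levels = unique(per_rep$eye_id))
      vals <- as.matrix(per_rep[-1])
      avg <- rowsum(vals, eye, reorder = FALSE) / as.vector(table(eye))
      cbind(data.frame(eye_id = levels(eye), stringsAsFactors = FALSE),
            as.data.frame(avg))
    }
  })

  design <- .stage("design_matrix",
                   assemble_design_matrix(features, input$cov))
  candidates <- .stage("lasso_screen",
                       lasso_screen(design$X, design$y, k = config$k_screen))
  selection <- .stage("exhaustive_search",
                      exhaustive_aicc_search(design$X, design$y, candidates,
                                             top_k = config$top_k))
  univariate <- .stage("univariate_scan",
                       univariate_scan(design$X, design$y))

  # Headline comparison: optimal model with vs without Monot1-2.
  ablation <- .stage("monot12_ablation", {
    best <- selection$best
    if ("monot12" %in% best$subset) {
      small <- refit_subset(design$X, design$y,
                            setdiff(best$subset, "monot12"))
      large <- best
      direction <- "monot12_removed_from_best"
    } else {
      small <- best
      large <- refit_subset(design$X, design$y, c(best$subset, "monot12"))
      direction <- "monot12_added_to_best"
    }
    cmp <- anova_nested(small, large)
    list(direction = direction, with_aicc = large$aicc,
         without_aicc = small$aicc,
         delta_aicc = small$aicc - large$aicc,
         anova_p = cmp$p, F = cmp$F,
         with_fit = large, without_fit = small)
  })

  traversal <- .stage("latent_traversal", {
    codes <- vae_encode(model, wa$traces)
    praa <- input$cov$PRAA[match(wa$meta$eye_id, input$cov$eye_id)]
    axis <- fit_praa_axis(codes$mu, praa)
    frames <- traverse(model, axis, n_frames = config$n_frames)
    list(axis = axis, frames = frames)
  })

  paths <- list()
  if (!is.null(outdir)) {
    .stage("report_output", {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      paths$report_json <- file.path(outdir, "report.json")
      paths$report_md <- file.path(outdir, "report.md")
      paths$selection_json <- file.path(outdir, "selection.json")
      paths$leaderboard_csv <- file.path(outdir, "aicc_leaderboard.csv")
      paths$univariate_csv <- file.path(outdir, "univariate.csv")
      paths$checkpoint <- file.path(outdir, "vae_checkpoint.json")
      for (p in paths) note_file(p)
      write_selection_result(selection, paths$selection_json,
                             paths$leaderboard_csv)
      write.csv(univariate, paths$univariate_csv, row.names = FALSE)
      save_vae_checkpoint(model, paths$checkpoint)
      if (config$make_animation) {
        paths$animation <- file.path(outdir, "traversal.tiff")
        note_file(paths$animation)
        note_file(file.path(outdir, "traversal_frames.csv"))
        export_animation(traversal$frames, paths$animation)
      }
    })
  }

  report <- structure(list(
    counts = c(simulated_or_read = n_simulated, after_quality_filter = n_filtered,
               eyes_analyzed = n_eyes_used),
    univariate = univariate,
    selection = selection,
    ablation = ablation[c("direction", "with_aicc", "without_aicc",
                          "delta_aicc", "anova_p", "F")],
    fits = list(with_monot12 = ablation$with_fit,
                without_monot12 = ablation$without_fit),
    axis = traversal$axis,
    model = model,
    design = design,
    truth = if (!is.null(cohort)) cohort$truth else NULL,
    paths = paths,
    manifest = list(seed = seed, mode = config$mode,
                    features_on = config$features_on,
                    average_mode = config$average_mode,
                    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  ), class = "report_bundle")

  if (!is.null(outdir)) {
    .stage("report_write", {
      .write_report_files(report, paths$report_json, paths$report_md)
    })
  }
  on.exit()  # success: keep outputs
  report
}

.write_report_files <- function(report, json_path, md_path) {
  sel <- report$selection
  payload <- list(
    counts = as.list(report$counts),
    best_subset = sel$best$subset,
    best_coefficients = sel$best$coefficients,
    best_aicc = sel$best$aicc,
    n_models_evaluated = sel$n_models_evaluated,
    ablation = report$ablation,
    seed = report$manifest$seed,
    timestamp = report$manifest$timestamp
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
  ct <- sel$best$coefficients
  lines <- c(
    "# PRAA waveform analysis report", "",
    sprintf("- records: %s", paste(names(report$counts), report$counts,
                                   sep = " = ", collapse = ", ")),
    sprintf("- optimal model: PRAA ~ %s (AICc = %.4g)",
            paste(sel$best$subset, collapse = " + "), sel$best$aicc),
    sprintf("- with vs without Monot1-2: delta AICc = %.4g, ANOVA p = %.4g (%s)",
            report$ablation$delta_aicc, report$ablation$anova_p,
            report$ablation$direction),
    "", "## Optimal model coefficients", "",
    "| term | estimate | SE | p |", "|---|---|---|---|",
    sprintf("| %s | %.4g | %.4g | %.4g |",
            ct$term, ct$estimate, ct$std_error, ct$p_value)
  )
  writeLines(lines, md_path)
  invisible(NULL)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("PRAA pipeline report (seed ", x$manifest$seed, ")\n", sep = "")
  cat("Counts:", paste(names(x$counts), x$counts, sep = " = ",
                       collapse = ", "), "\n")
  cat("Optimal model: PRAA ~ ",
      paste(x$selection$best$subset, collapse = " + "),
      sprintf(" (AICc = %.4g)\n", x$selection$best$aicc), sep = "")
  cat(sprintf("With vs without Monot1-2: delta AICc = %.4g, ANOVA p = %.4g\n",
              x$ablation$delta_aicc, x$ablation$anova_p))
  invisible(x)
}

#' Repeat the pipeline over seeds and summarize recovery of planted effects
#'
#' Runs [run_pipeline()] for `n_seeds` consecutive seeds on a simulate-mode
#' configuration and tabulates, per design column, how often it entered the
#' selected subset, together with the mean coefficient estimate (and bias)
#' for the planted predictors.
#'
#' @param config A simulate-mode [run_config()].
#' @param n_seeds Number of seeds (>= 2).
#' @return List with `selection_frequency` (data.frame) and `coefficients`
#'   (data.frame for planted predictors), of class `recovery_summary`.
#' @export
recovery_experiment <- function(config, n_seeds) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode != "simulate") {
    stop("recovery_experiment requires a simulate-mode config")
  }
  if (n_seeds < 2) stop("n_seeds must be >= 2")
  seeds <- config$seed + seq_len(n_seeds) - 1L
  runs <- lapply(seeds, function(s) run_pipeline(config, seed = s))

  all_cols <- colnames(runs[[1]]$design$X)
  freq <- vapply(all_cols, function(v) {
    mean(vapply(runs, function(r) v %in% r$selection$best$subset, logical(1)))
  }, numeric(1))
  truth_coefs <- runs[[1]]$truth$praa_coefs
  planted <- planted_support(runs[[1]]$truth)
  coef_rows <- lapply(planted, function(v) {
    est <- vapply(runs, function(r) {
      ct <- r$selection$best$coefficients
      if (v %in% ct$term) ct$estimate[ct$term == v] else NA_real_
    }, numeric(1))
    data.frame(variable = v, truth = unname(truth_coefs[v]),
               mean_estimate = mean(est, na.rm = TRUE),
               bias = mean(est, na.rm = TRUE) - unname(truth_coefs[v]),
               n_selected = sum(!is.na(est)),
               stringsAsFactors = FALSE)
  })
  structure(list(
    selection_frequency = data.frame(variable = all_cols,
                                     frequency = unname(freq),
                                     planted = all_cols %in% planted,
                                     row.names = NULL,
                                     stringsAsFactors = FALSE),
    coefficients = do.call(rbind, coef_rows),
    seeds = seeds
  ), class = "recovery_summary")
}

#' @export
print.recovery_summary <- function(x, ...) {
  cat("Recovery over", length(x$seeds), "seeds\n")
  sf <- x$selection_frequency
  print(sf[order(-sf$frequency), ][seq_len(min(10, nrow(sf))), ],
        row.names = FALSE)
  cat("\nPlanted coefficients:\n")
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}
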