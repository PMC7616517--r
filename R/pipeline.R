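#' Read / write trial tables as delimited text
#'
#' @param path TSV or CSV file (auto-detected from the first line).
#' @return a validated trial table.
#' @export
read_trial_table <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  trials <- utils::read.table(path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE, quote = "\"",
                              encoding = "UTF-8")
  validate_trials(trials)
  trials
}

#' @rdname read_trial_table
#' @param trials a trial table.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Serialize a fitted model as a Table-1-style JSON report
#'
#' Fixed-effect ANOVA (Type III, Satterthwaite), coefficient table,
#' variance components, marginal/conditional R-squared, group-specific
#' density slopes, pairwise type contrasts and convergence diagnostics.
#'
#' @param fit a [fit_sneigh_lmm()] object.
#' @param criticism optional [model_criticism()] result to include.
#' @return a list ready for [jsonlite::write_json()].
#' @export
model_fit_report <- function(fit, criticism = NULL) {
  model <- fit$model
  an <- anova_type3(fit)
  vc <- lme4::VarCorr(model)
  b <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  vc_part <- as.matrix(vc$participant)
  rep <- list(
    n_obs = nrow(fit$data),
    n_participants = nlevels(fit$data$participant),
    n_stimuli = nlevels(fit$data$stimulus),
    converged = fit$converged,
    singular = fit$singular,
    messages = fit$messages,
    fixed_effects = data.frame(term = names(b), estimate = unname(b),
                               se = unname(se), z = unname(b / se)),
    anova = cbind(term = rownames(an), as.data.frame(an)),
    variance_components = list(
      stimulus_intercept = list(variance = unname(as.matrix(vc$stimulus)[1, 1]),
                                sd = sqrt(unname(as.matrix(vc$stimulus)[1, 1]))),
      participant_intercept = list(variance = vc_part[1, 1],
                                   sd = sqrt(vc_part[1, 1])),
      sneigh_slope = list(variance = vc_part[2, 2], sd = sqrt(vc_part[2, 2]),
                          correlation = stats::cov2cor(vc_part)[1, 2]),
      residual = list(variance = stats::sigma(model)^2,
                      sd = stats::sigma(model))
    ),
    r2 = as.list(r2_nakagawa(fit)),
    simple_slopes = simple_slopes(fit),
    posthoc_type = posthoc_type(fit)
  )
  if (!is.null(criticism)) {
    rep$criticism <- list(
      n_removed = criticism$n_removed,
      fraction_removed = criticism$fraction_removed,
      anova = cbind(term = rownames(anova_type3(criticism$refit)),
                    as.data.frame(anova_type3(criticism$refit))),
      simple_slopes = simple_slopes(criticism$refit)
    )
  }
  rep
}

read_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (grepl("[.]ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is required for YAML configs", call. = FALSE)
      config <- yaml::read_yaml(config)
    } else {
      config <- jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  config
}

#' Run the full pipeline: density, cleaning, model, report
#'
#' Orchestrates the stages end to end from a config (YAML/JSON path or
#' list). The config either points at real inputs (`inputs:` with `vectors`,
#' `frequencies`, `trials` and optionally `stimuli`) or carries a
#' `simulation:` block of [generative_config()] overrides. Stages
#' communicate via files in `out_dir` (density.tsv, trials.tsv, clean.tsv,
#' cleaning_report.json, fit.json), so each stage is independently
#' inspectable, and every run appends a record to `manifest.json` with
#' input hashes, the config snapshot, per-stage row counts, the package
#' version and the seed.
#'
#' @param config path to a YAML/JSON config file, or an equivalent list.
#' @param out_dir output directory (defaults to `config$out_dir`).
#' @return invisibly, a list with `manifest`, `density`, `cleaning` report,
#'   `fit`, optional `criticism`, and the output `paths`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_pipeline_config(config)
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no out_dir configured",
                                               call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()

  k <- cfg$sneigh$k %||% 5L
  n_top <- cfg$sneigh$n_top %||% 20000L
  seed <- cfg$seed %||% 1L
  input_files <- character(0)

  if (!is.null(cfg$simulation) || is.null(cfg$inputs)) {
    sim <- do.call(generative_config,
                   c(as.list(cfg$simulation), list(seed = seed)))
    emb <- generate_embedding_space(sim)
    space <- emb$space
    freq <- emb$freq
    n_stim <- 3L * sim$design$words_per_type
    stimuli <- freq$word[seq_len(n_stim)]
    vec_path <- file.path(out_dir, "embedding.vec")
    write_word2vec_text(space, vec_path)
    reference <- build_reference_vocabulary(freq, space,
                                            min(n_top, length(space)),
                                            k = k, quiet = TRUE)
    density <- compute_density_table(stimuli, space, reference, k = k)
    trials <- generate_trials(sim, density)
    simulated <- TRUE
  } else {
    if (any(!c("vectors", "frequencies", "trials") %in% names(cfg$inputs)))
      stop("inputs config needs 'vectors', 'frequencies' and 'trials'",
           call. = FALSE)
    input_files <- unlist(cfg$inputs)
    missing <- input_files[!file.exists(input_files)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    space <- read_word2vec_text(cfg$inputs$vectors, quiet = TRUE)
    freq <- read_frequency_list(cfg$inputs$frequencies,
                                word_column = cfg$inputs$word_column %||% "word",
                                freq_column = cfg$inputs$freq_column %||% "frequency",
                                quiet = TRUE)
    trials <- read_trial_table(cfg$inputs$trials)
    stimuli <- sort(unique(trials$stimulus[trials$lexicality == "word"]))
    reference <- build_reference_vocabulary(freq, space, n_top, k = k,
                                            quiet = TRUE)
    density <- compute_density_table(stimuli, space, reference, k = k)
    simulated <- FALSE
  }

  paths <- list(
    density = file.path(out_dir, "density.tsv"),
    trials = file.path(out_dir, "trials.tsv"),
    clean = file.path(out_dir, "clean.tsv"),
    cleaning_report = file.path(out_dir, "cleaning_report.json"),
    fit = file.path(out_dir, "fit.json"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_density_table(density, paths$density)
  write_trial_table(trials, paths$trials)

  cl <- clean_trials(trials,
                     threshold_sd = cfg$cleaning$threshold_sd %||% 2.5,
                     rt_floor = cfg$cleaning$rt_floor %||% 300,
                     sd_window = cfg$cleaning$sd_window %||% 3)
  write_trial_table(cl$trials, paths$clean)
  jsonlite::write_json(unclass(cl$report), paths$cleaning_report,
                       auto_unbox = TRUE, digits = NA, force = TRUE)

  fit <- fit_sneigh_lmm(cl$trials, density = density,
                        reml = cfg$model$reml %||% TRUE)
  crit <- if (isTRUE(cfg$model$criticism))
    model_criticism(fit, cfg$model$criticism_threshold %||% 2.5)
  report <- model_fit_report(fit, crit)
  jsonlite::write_json(report, paths$fit, auto_unbox = TRUE, digits = NA,
                       force = TRUE, dataframe = "rows")

  manifest_entry <- list(
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    package_version = as.character(utils::packageVersion("semdense")),
    seed = seed,
    simulated = simulated,
    config = cfg,
    input_hashes = if (length(input_files))
      as.list(tools::md5sum(input_files)) else list(),
    stage_counts = list(
      density_rows = nrow(density),
      trials_rows = nrow(trials),
      clean_rows = nrow(cl$trials),
      model_obs = report$n_obs
    ),
    sneigh = list(k = k, n_top = n_top),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  manifest <- if (file.exists(paths$manifest))
    jsonlite::read_json(paths$manifest) else list()
  manifest <- c(manifest, list(manifest_entry))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, force = TRUE)

  invisible(list(manifest = manifest_entry, density = density,
                 cleaning = cl$report, fit = fit, criticism = crit,
                 report = report, paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
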