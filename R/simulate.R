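# evaluate code under a temporary RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generative configuration for the synthetic world
#'
#' All parameters of the synthetic embedding space and of the generative
#' reaction-time model. The RT-model defaults are the published estimates of
#' the study this package reproduces: per-group density slopes -0.37 (EB)
#' and -0.25 (SC), duration slope 0.25, participant-intercept SD 0.13,
#' stimulus-intercept SD 0.06, participant density-slope SD 0.11 with
#' intercept-slope correlation -0.50, trial error probability 0.0175, and a
#' residual SD calibrated (see [calibrate_residual_sd()]) so the implied
#' conditional R-squared is 0.50. The design default is 20 participants per
#' group, 39 words per type (117 stimuli) and 2 presentations per word.
#' Values the study does not print (intercept, group and type effects,
#' duration distribution, embedding geometry) are fixed, documented choices.
#'
#' @param ... overrides as named nested lists or `section.field` names, e.g.
#'   `generative_config(design = list(n_per_group = 10), seed = 42)`.
#' @return list of class `generative_config`.
#' @export
generative_config <- function(...) {
  cfg <- list(
    seed = 1L,
    embedding = list(
      n_words = 1000L, dim = 50L, n_clusters = 10L,
      spread_range = c(0.3, 1.2), center_scale = 1.0
    ),
    design = list(
      n_per_group = 20L, words_per_type = 39L, presentations = 2L,
      duration_meanlog = log(700), duration_sdlog = 0.15,
      include_pseudowords = FALSE
    ),
    rt_model = list(
      intercept = 5.5,
      group_effect = 0.065,      # sum-coded EB coefficient (EB = +1)
      slope_eb = -0.37, slope_sc = -0.25,
      type_effects = c(abstract = 0.0172, multimodal = -0.0088,
                       visual = -0.0084),
      duration_slope = 0.25,
      sd_participant = 0.13, sd_stimulus = 0.06,
      sd_slope = 0.11, cor_intercept_slope = -0.50,
      sd_residual = NULL,        # NULL = calibrate for conditional R2
      target_conditional_r2 = 0.50
    ),
    error_model = list(
      error_prob = 0.0175,
      pseudoword_error_prob = 0.0175,
      pseudoword_rt_meanlog = log(1250), pseudoword_rt_sdlog = 0.25
    )
  )
  dots <- list(...)
  # duplicated section names are allowed and applied in order
  for (i in seq_along(dots)) {
    nm <- names(dots)[i]
    if (is.list(dots[[i]]) && nm %in% names(cfg) && is.list(cfg[[nm]]))
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], dots[[i]])
    else cfg[[nm]] <- dots[[i]]
  }
  validate_generative_config(cfg)
}

validate_generative_config <- function(cfg) {
  rt <- cfg$rt_model
  sds <- c(rt$sd_participant, rt$sd_stimulus, rt$sd_slope,
           if (!is.null(rt$sd_residual)) rt$sd_residual)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (abs(rt$cor_intercept_slope) > 1)
    stop("intercept-slope correlation must lie in [-1, 1]", call. = FALSE)
  probs <- c(cfg$error_model$error_prob, cfg$error_model$pseudoword_error_prob)
  if (any(probs < 0 | probs > 1))
    stop("error probabilities must lie in [0, 1]", call. = FALSE)
  te <- rt$type_effects
  if (length(te) != 3L || is.null(names(te)))
    stop("type_effects must be a named length-3 vector", call. = FALSE)
  structure(cfg, class = "generative_config")
}

#' Generate a clustered synthetic embedding space and frequency list
#'
#' Words are drawn from Gaussian clusters whose within-cluster spreads
#' differ, so k-nearest-neighbor density varies systematically across the
#' space: words in tight clusters have near neighbors (high mean cosine),
#' words in loose clusters do not. An accompanying Zipf-like frequency list
#' covers the same vocabulary. Fully seed-deterministic.
#'
#' @param cfg a [generative_config()].
#' @return list with `space` (an [embedding_space()]), `freq` (a
#'   [frequency_list()]) and `cluster` (integer cluster id per word).
#' @export
generate_embedding_space <- function(cfg) {
  stopifnot(inherits(cfg, "generative_config"))
  e <- cfg$embedding
  if (e$dim < 2L) stop("embedding dimension must be >= 2", call. = FALSE)
  if (e$n_words <= e$n_clusters || e$n_clusters < 1L)
    stop("need n_words > n_clusters >= 1", call. = FALSE)
  with_seed(cfg$seed, {
    spreads <- seq(e$spread_range[1L], e$spread_range[2L],
                   length.out = e$n_clusters)
    centers <- matrix(stats::rnorm(e$n_clusters * e$dim, sd = e$center_scale),
                      nrow = e$n_clusters)
    cluster <- rep(seq_len(e$n_clusters), length.out = e$n_words)
    vecs <- centers[cluster, , drop = FALSE] +
      matrix(stats::rnorm(e$n_words * e$dim), nrow = e$n_words) *
      spreads[cluster]
    words <- sprintf("w%05d", seq_len(e$n_words))
    space <- embedding_space(words, vecs, normalize_nfc = FALSE)
    # Zipf-like frequencies over a random permutation of the vocabulary,
    # so frequency rank is independent of cluster geometry
    perm <- sample.int(e$n_words)
    freq <- frequency_list(words[perm],
                           1e6 / seq_len(e$n_words)^1.0)
    list(space = space, freq = freq, cluster = cluster)
  })
}

# sum-to-zero group code: EB = +1, SC = -1 (matches contr.sum on EB, SC)
group_code <- function(group) ifelse(group == "EB", 1, -1)

#' Generate lexical-decision trials from the generative RT model
#'
#' Draws, per participant, correlated intercept and density-slope random
#' effects; per stimulus, a random intercept and a log-normal audio
#' duration; and per trial a Gaussian residual. The linear predictor is
#' `intercept + group_effect * code(group) + slope_group * sneigh +
#' type_effect + duration_slope * log(duration)`, exponentiated to
#' milliseconds. Accuracy flags are Bernoulli draws from the error model.
#' Optionally emits matched pseudoword trials (with their own RT
#' distribution) so the cleaning denominators can be exercised; pseudowords
#' never enter the RT model.
#'
#' @param cfg a [generative_config()]; `cfg$rt_model$sd_residual = NULL`
#'   triggers calibration via [calibrate_residual_sd()].
#' @param density a `density_table` covering the stimuli to use; the first
#'   `3 * words_per_type` words are assigned types abstract / multimodal /
#'   visual in rotation.
#' @return a trial table (see [validate_trials()]) with an `sneigh` column.
#' @export
generate_trials <- function(cfg, density) {
  stopifnot(inherits(cfg, "generative_config"))
  d <- cfg$design; rt <- cfg$rt_model; em <- cfg$error_model
  n_stim <- 3L * d$words_per_type
  if (nrow(density) < n_stim)
    stop("density table has ", nrow(density), " words; design needs ",
         n_stim, call. = FALSE)
  stim <- density$word[seq_len(n_stim)]
  sneigh <- density$sneigh[seq_len(n_stim)]
  types <- rep(c("abstract", "multimodal", "visual"),
               length.out = n_stim)
  te <- rt$type_effects
  te <- te - mean(te)  # enforce exact sum-to-zero

  sd_res <- rt$sd_residual
  if (is.null(sd_res))
    sd_res <- calibrate_residual_sd(cfg, density, quiet = TRUE)

  with_seed(cfg$seed + 1L, {
    duration <- stats::rlnorm(n_stim, d$duration_meanlog, d$duration_sdlog)
    if (any(duration <= 0)) stop("non-positive generated duration",
                                 call. = FALSE)
    w_stim <- stats::rnorm(n_stim, 0, rt$sd_stimulus)

    participants <- sprintf("p%03d", seq_len(2L * d$n_per_group))
    group <- rep(c("EB", "SC"), each = d$n_per_group)
    # bivariate normal participant (intercept, slope) effects
    rho <- rt$cor_intercept_slope
    z1 <- stats::rnorm(length(participants))
    z2 <- stats::rnorm(length(participants))
    u0 <- rt$sd_participant * z1
    u1 <- rt$sd_slope * (rho * z1 + sqrt(1 - rho^2) * z2)

    grid <- expand.grid(p = seq_along(participants), s = seq_len(n_stim),
                        presentation = seq_len(d$presentations))
    slope <- ifelse(group[grid$p] == "EB", rt$slope_eb, rt$slope_sc)
    eta <- rt$intercept +
      rt$group_effect * group_code(group[grid$p]) +
      (slope + u1[grid$p]) * sneigh[grid$s] +
      te[types[grid$s]] +
      rt$duration_slope * log(duration[grid$s]) +
      u0[grid$p] + w_stim[grid$s]
    log_rt <- eta + stats::rnorm(nrow(grid), 0, sd_res)
    correct <- stats::runif(nrow(grid)) >= em$error_prob

    trials <- data.frame(
      participant = participants[grid$p],
      group = group[grid$p],
      stimulus = stim[grid$s],
      type = types[grid$s],
      lexicality = "word",
      presentation = grid$presentation,
      accuracy = ifelse(correct, "correct", "incorrect"),
      rt = exp(log_rt),
      duration = duration[grid$s],
      sneigh = sneigh[grid$s],
      stringsAsFactors = FALSE
    )

    if (isTRUE(d$include_pseudowords)) {
      pgrid <- expand.grid(p = seq_along(participants), s = seq_len(n_stim),
                           presentation = seq_len(d$presentations))
      pdur <- stats::rlnorm(n_stim, d$duration_meanlog, d$duration_sdlog)
      prt <- stats::rlnorm(nrow(pgrid), em$pseudoword_rt_meanlog,
                           em$pseudoword_rt_sdlog)
      pcorrect <- stats::runif(nrow(pgrid)) >= em$pseudoword_error_prob
      pseudo <- data.frame(
        participant = participants[pgrid$p],
        group = group[pgrid$p],
        stimulus = paste0("x", stim[pgrid$s]),
        type = NA_character_,
        lexicality = "pseudoword",
        presentation = pgrid$presentation,
        accuracy = ifelse(pcorrect, "correct", "incorrect"),
        rt = prt,
        duration = pdur[pgrid$s],
        sneigh = NA_real_,
        stringsAsFactors = FALSE
      )
      trials <- rbind(trials, pseudo)
    }
    rownames(trials) <- NULL
    trials
  })
}

#' Calibrate the residual SD for a target conditional R-squared
#'
#' The published table reports the random-effect variances and the
#' marginal/conditional R-squared but not the residual variance. Given the
#' other components and the realized design (density values, durations,
#' fixed effects), this solves for the residual variance that makes the
#' implied conditional R-squared equal the target:
#' `var_e = (var_fixed + var_random) * (1 - R2c) / R2c`.
#'
#' @param cfg a [generative_config()].
#' @param density a `density_table` for the stimuli.
#' @param quiet suppress the log message.
#' @return the calibrated residual SD (log-ms units).
#' @export
calibrate_residual_sd <- function(cfg, density, quiet = FALSE) {
  stopifnot(inherits(cfg, "generative_config"))
  d <- cfg$design; rt <- cfg$rt_model
  n_stim <- 3L * d$words_per_type
  sneigh <- density$sneigh[seq_len(n_stim)]
  types <- rep(c("abstract", "multimodal", "visual"), length.out = n_stim)
  te <- rt$type_effects; te <- te - mean(te)
  # expected log-duration spread contributes to the fixed-effect variance
  with_seed(cfg$seed + 1L, {
    duration <- stats::rlnorm(n_stim, d$duration_meanlog, d$duration_sdlog)
  })
  groups <- c("EB", "SC")
  eta <- as.vector(vapply(groups, function(g) {
    slope <- if (g == "EB") rt$slope_eb else rt$slope_sc
    rt$group_effect * group_code(g) + slope * sneigh + te[types] +
      rt$duration_slope * log(duration)
  }, numeric(n_stim)))
  vf <- stats::var(eta)
  vr <- rt$sd_stimulus^2 + rt$sd_participant^2 +
    2 * rt$cor_intercept_slope * rt$sd_participant * rt$sd_slope *
    mean(sneigh) +
    rt$sd_slope^2 * mean(sneigh^2)
  r2c <- rt$target_conditional_r2
  ve <- (vf + vr) * (1 - r2c) / r2c
  sd_res <- sqrt(ve)
  if (!quiet)
    message(sprintf(paste0("calibrated residual SD = %.4f (fixed var %.4f, ",
                           "random var %.4f, target conditional R2 %.2f)"),
                    sd_res, vf, vr, r2c))
  sd_res
}

# generative fixed-effect vector in the fitted (sum-coded) parameterization
generative_fixef <- function(cfg) {
  rt <- cfg$rt_model
  te <- rt$type_effects; te <- te - mean(te)
  c("(Intercept)" = rt$intercept,
    "group1" = rt$group_effect,
    "sneigh" = (rt$slope_eb + rt$slope_sc) / 2,
    "type1" = unname(te["abstract"]),
    "type2" = unname(te["multimodal"]),
    "log_duration" = rt$duration_slope,
    "group1:sneigh" = (rt$slope_eb - rt$slope_sc) / 2,
    "group1:type1" = 0,
    "group1:type2" = 0)
}

#' Simulation-based parameter recovery / null calibration experiment
#'
#' Builds one synthetic embedding space and density table, then repeatedly
#' generates trials, cleans them, fits the mixed model, and records the
#' fixed-effect estimates, the per-group density slopes with Wald 95% CIs,
#' and the p value of the group-by-density interaction. Summaries report
#' bias, RMSE, CI coverage against the generative values and the
#' interaction rejection rate at `alpha`.
#'
#' @param cfg a [generative_config()].
#' @param n_replicates number of simulated experiments.
#' @param seed integer; master seed for the replicate stream.
#' @param satterthwaite logical; if `TRUE` the interaction p value uses the
#'   Satterthwaite F test (needed for calibrated type-I error at small n),
#'   otherwise the faster normal-approximation Wald test.
#' @param clean logical; run the cleaning cascade on each replicate
#'   (default `TRUE`).
#' @param alpha rejection level for the interaction test.
#' @param progress print a dot per replicate.
#' @return list of class `recovery_report`: `replicates` (one row per
#'   replicate), `summary` (per-parameter mean, bias, RMSE, coverage,
#'   Monte-Carlo SE), `rejection_rate`, `n_converged`, `generative`.
#' @export
recovery_experiment <- function(cfg, n_replicates, seed = cfg$seed,
                                satterthwaite = FALSE, clean = TRUE,
                                alpha = 0.05, progress = FALSE) {
  stopifnot(inherits(cfg, "generative_config"), n_replicates >= 1)
  emb <- generate_embedding_space(cfg)
  n_stim <- 3L * cfg$design$words_per_type
  stimuli <- emb$freq$word[seq_len(n_stim)]
  density <- compute_density_table(stimuli, emb$space, emb$space, k = 5L)
  if (is.null(cfg$rt_model$sd_residual))
    cfg$rt_model$sd_residual <- calibrate_residual_sd(cfg, density,
                                                      quiet = TRUE)
  gen <- generative_fixef(cfg)
  gen_slopes <- c(EB = cfg$rt_model$slope_eb, SC = cfg$rt_model$slope_sc)

  rows <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    cfg_r <- cfg
    cfg_r$seed <- (seed + 7919L * r) %% 2147483647L
    trials <- generate_trials(cfg_r, density)
    dat <- if (clean) clean_trials(trials)$trials else log_transforms(
      trials[is_correct(trials$accuracy) & trials$lexicality == "word", ])
    rec <- tryCatch({
      fit <- fit_sneigh_lmm(dat)
      b <- lme4::fixef(fit$model)
      se <- sqrt(diag(as.matrix(stats::vcov(fit$model))))
      sl <- simple_slopes_fast(fit)
      p_int <- if (satterthwaite) {
        a <- anova_type3(fit)
        a["group:sneigh", "Pr(>F)"]
      } else {
        w <- (b["group1:sneigh"] / se["group1:sneigh"])^2
        stats::pchisq(w, df = 1, lower.tail = FALSE)
      }
      out <- c(b, stats::setNames(se, paste0("se_", names(se))),
               slope_EB = unname(sl$b[sl$group == "EB"]),
               slope_SC = unname(sl$b[sl$group == "SC"]),
               se_slope_EB = unname(sl$se[sl$group == "EB"]),
               se_slope_SC = unname(sl$se[sl$group == "SC"]),
               p_interaction = unname(p_int),
               converged = as.numeric(fit$converged),
               singular = as.numeric(fit$singular))
      as.data.frame(as.list(out), check.names = FALSE)
    }, error = function(e) NULL)
    rows[[r]] <- rec
    if (progress) cat(if (is.null(rec)) "x" else ".")
  }
  if (progress) cat("\n")
  reps <- do.call(rbind, rows)
  if (is.null(reps)) stop("no replicate produced a fit", call. = FALSE)

  par_names <- names(gen)
  summ <- do.call(rbind, lapply(par_names, function(nm) {
    est <- reps[[nm]]; se <- reps[[paste0("se_", nm)]]
    cover <- mean(abs(est - gen[[nm]]) <= 1.96 * se)
    data.frame(parameter = nm, generative = gen[[nm]],
               mean_estimate = mean(est), bias = mean(est) - gen[[nm]],
               rmse = sqrt(mean((est - gen[[nm]])^2)),
               mc_se = stats::sd(est) / sqrt(length(est)),
               ci_coverage = cover, stringsAsFactors = FALSE)
  }))
  for (g in c("EB", "SC")) {
    est <- reps[[paste0("slope_", g)]]
    se <- reps[[paste0("se_slope_", g)]]
    summ <- rbind(summ, data.frame(
      parameter = paste0("slope_", g), generative = gen_slopes[[g]],
      mean_estimate = mean(est), bias = mean(est) - gen_slopes[[g]],
      rmse = sqrt(mean((est - gen_slopes[[g]])^2)),
      mc_se = stats::sd(est) / sqrt(length(est)),
      ci_coverage = mean(abs(est - gen_slopes[[g]]) <= 1.96 * se),
      stringsAsFactors = FALSE))
  }
  rownames(summ) <- NULL
  structure(
    list(replicates = reps, summary = summ,
         rejection_rate = mean(reps$p_interaction < alpha),
         alpha = alpha,
         n_converged = sum(reps$converged > 0), n_run = nrow(reps),
         n_requested = n_replicates,
         generative = list(fixef = gen, slopes = gen_slopes, config = cfg)),
    class = "recovery_report"
  )
}

# simple slopes without the Satterthwaite machinery (Wald SEs only)
simple_slopes_fast <- function(fit) {
  V <- as.matrix(stats::vcov(fit$model))
  b <- lme4::fixef(fit$model)
  out <- do.call(rbind, lapply(levels(fit$data$group), function(g) {
    L <- slope_contrast(fit, g)
    est <- drop(crossprod(L, b))
    se <- sqrt(drop(t(L) %*% V %*% L))
    data.frame(group = g, b = est, se = se, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery experiment:", x$n_run, "of", x$n_requested,
      "replicates fitted,", x$n_converged, "converged\n")
  cat(sprintf("Interaction rejection rate at alpha = %.2f: %.3f\n",
              x$alpha, x$rejection_rate))
  print(x$summary, digits = 3)
  invisible(x)
}
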