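test_that("the generator is seed-deterministic end to end", {
  cfg <- small_config(seed = 51)
  e1 <- generate_embedding_space(cfg)
  e2 <- generate_embedding_space(cfg)
  expect_identical(e1$space$vectors, e2$space$vectors)
  expect_identical(e1$freq, e2$freq)

  # byte-identical .vec output
  p1 <- withr::local_tempfile(fileext = ".vec")
  p2 <- withr::local_tempfile(fileext = ".vec")
  write_word2vec_text(e1$space, p1)
  write_word2vec_text(e2$space, p2)
  expect_identical(readLines(p1), readLines(p2))

  density <- compute_density_table(e1$freq$word[1:24], e1$space, e1$space,
                                   k = 5)
  t1 <- generate_trials(cfg, density)
  t2 <- generate_trials(cfg, density)
  expect_identical(t1, t2)

  # a different seed changes the draws but not the structure
  cfg2 <- small_config(seed = 52)
  t3 <- generate_trials(cfg2, density)
  expect_identical(dim(t3), dim(t1))
  expect_false(identical(t3$rt, t1$rt))
})

test_that("tight clusters produce denser neighborhoods than loose ones", {
  cfg <- generative_config(
    embedding = list(n_words = 120L, dim = 20L, n_clusters = 2L,
                     spread_range = c(0.01, 1.0)),
    seed = 53
  )
  emb <- generate_embedding_space(cfg)
  density <- compute_density_table(emb$space$vocabulary, emb$space,
                                   emb$space, k = 5)
  tight <- density$sneigh[emb$cluster == 1L]
  loose <- density$sneigh[emb$cluster == 2L]
  expect_gt(mean(tight), mean(loose))
})

test_that("a one-cluster space of k+1 words defines density everywhere", {
  cfg <- generative_config(
    embedding = list(n_words = 6L, dim = 5L, n_clusters = 1L),
    seed = 54
  )
  emb <- generate_embedding_space(cfg)
  density <- compute_density_table(emb$space$vocabulary, emb$space,
                                   emb$space, k = 5)
  expect_equal(nrow(density), 6L)
  expect_true(all(is.finite(density$sneigh)))
})

test_that("generator guards reject degenerate configurations", {
  expect_error(generative_config(rt_model = list(sd_participant = -1)),
               ">= 0")
  expect_error(generative_config(rt_model = list(cor_intercept_slope = 1.5)),
               "correlation")
  expect_error(generative_config(error_model = list(error_prob = 2)),
               "probabilities")
  cfg <- small_config(embedding = list(dim = 1L))
  expect_error(generate_embedding_space(cfg), "dimension")
  cfg2 <- small_config(embedding = list(n_words = 3L, n_clusters = 4L))
  expect_error(generate_embedding_space(cfg2), "n_words > n_clusters")
})

test_that("the noise-free limit is an exact deterministic function", {
  cfg <- small_config(
    seed = 55,
    rt_model = list(sd_participant = 0, sd_stimulus = 0, sd_slope = 0,
                    cor_intercept_slope = 0, sd_residual = 0),
    error_model = list(error_prob = 0)
  )
  emb <- generate_embedding_space(cfg)
  density <- compute_density_table(emb$freq$word[1:24], emb$space, emb$space,
                                   k = 5)
  trials <- generate_trials(cfg, density)
  expect_true(all(trials$accuracy == "correct"))

  # recompute log RT by hand from the configured fixed effects
  rt <- cfg$rt_model
  te <- rt$type_effects - mean(rt$type_effects)
  slope <- ifelse(trials$group == "EB", rt$slope_eb, rt$slope_sc)
  code <- ifelse(trials$group == "EB", 1, -1)
  eta <- rt$intercept + rt$group_effect * code + slope * trials$sneigh +
    te[trials$type] + rt$duration_slope * log(trials$duration)
  expect_equal(log(trials$rt), unname(eta), tolerance = 1e-12)
})

test_that("simulated log RT means match the linear predictor (Monte Carlo)", {
  cfg <- generative_config(
    embedding = list(n_words = 100L, dim = 10L, n_clusters = 2L),
    design = list(n_per_group = 400L, words_per_type = 2L),
    rt_model = list(sd_participant = 0, sd_stimulus = 0, sd_slope = 0,
                    cor_intercept_slope = 0, sd_residual = 0.2),
    error_model = list(error_prob = 0),
    seed = 56
  )
  emb <- generate_embedding_space(cfg)
  density <- compute_density_table(emb$freq$word[1:6], emb$space, emb$space,
                                   k = 5)
  trials <- generate_trials(cfg, density)  # 800 participants x 6 x 2 = 9600

  rt <- cfg$rt_model
  te <- rt$type_effects - mean(rt$type_effects)
  for (s in unique(trials$stimulus)) {
    for (g in c("EB", "SC")) {
      sel <- trials$stimulus == s & trials$group == g
      n <- sum(sel)
      slope <- if (g == "EB") rt$slope_eb else rt$slope_sc
      eta <- rt$intercept + rt$group_effect * (if (g == "EB") 1 else -1) +
        slope * trials$sneigh[sel][1] + te[trials$type[sel][1]] +
        rt$duration_slope * log(trials$duration[sel][1])
      mc_se <- 0.2 / sqrt(n)
      expect_lt(abs(mean(log(trials$rt[sel])) - eta), 4 * mc_se)
    }
  }
})

test_that("error flags hit the configured rate within binomial error", {
  cfg <- small_config(seed = 57, error_model = list(error_prob = 0.1),
                      design = list(n_per_group = 20L))
  emb <- generate_embedding_space(cfg)
  density <- compute_density_table(emb$freq$word[1:24], emb$space, emb$space,
                                   k = 5)
  trials <- generate_trials(cfg, density)
  n <- nrow(trials)
  p_hat <- mean(trials$accuracy == "incorrect")
  expect_lt(abs(p_hat - 0.1), 4 * sqrt(0.1 * 0.9 / n))

  cfg0 <- small_config(seed = 57, error_model = list(error_prob = 0))
  t0 <- generate_trials(cfg0, density)
  expect_true(all(t0$accuracy == "correct"))
})

test_that("residual calibration hits the target conditional R2", {
  cfg <- generative_config(seed = 58,
                           design = list(n_per_group = 30L))
  emb <- generate_embedding_space(cfg)
  density <- compute_density_table(emb$freq$word[1:117], emb$space, emb$space,
                                   k = 5)
  expect_message(sd_res <- calibrate_residual_sd(cfg, density),
                 "calibrated residual SD")
  cfg$rt_model$sd_residual <- sd_res
  trials <- generate_trials(cfg, density)
  fit <- fit_sneigh_lmm(clean_trials(trials)$trials)
  r2 <- r2_nakagawa(fit)
  # one realization at 60 participants: conditional R2 near the 0.50 target
  expect_lt(abs(r2["conditional"] - 0.50), 0.08)
})

test_that("a single-replicate recovery run is byte-reproducible", {
  cfg <- small_config(seed = 59)
  r1 <- recovery_experiment(cfg, n_replicates = 1, seed = 59)
  r2 <- recovery_experiment(cfg, n_replicates = 1, seed = 59)
  expect_identical(r1$replicates, r2$replicates)
  expect_identical(r1$summary, r2$summary)
  expect_equal(r1$n_run, 1L)
  expect_true(all(c("slope_EB", "slope_SC", "p_interaction") %in%
                    names(r1$replicates)))
})
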