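# one moderately sized simulated dataset shared across this file
fit_fixture <- local({
  value <- NULL
  function() {
    if (is.null(value)) {
      cfg <- generative_config(
        embedding = list(n_words = 400L, dim = 30L, n_clusters = 6L),
        design = list(n_per_group = 10L, words_per_type = 12L),
        seed = 41
      )
      emb <- generate_embedding_space(cfg)
      density <- compute_density_table(emb$freq$word[1:36], emb$space,
                                       emb$space, k = 5)
      trials <- generate_trials(cfg, density)
      dat <- clean_trials(trials)$trials
      value <<- list(cfg = cfg, density = density,
                     fit = fit_sneigh_lmm(dat))
    }
    value
  }
})

test_that("Satterthwaite df reproduce closed-form balanced-design values", {
  # between-cluster covariate in a balanced two-level design: classical
  # df = J - 2 (J clusters, 2 fixed parameters)
  set.seed(42)
  J <- 14; m <- 5
  g <- factor(rep(seq_len(J), each = m))
  x <- rep(rnorm(J), each = m)
  y <- 1 + 0.8 * x + rep(rnorm(J, sd = 0.9), each = m) + rnorm(J * m, sd = 0.6)
  fm <- lme4::lmer(y ~ x + (1 | g), data = data.frame(y, x, g))
  prep <- semdense:::satterthwaite_prep(fm)
  expect_equal(semdense:::satterthwaite_df_1d(prep, c(0, 1)), J - 2,
               tolerance = 1e-3)
  expect_equal(semdense:::satterthwaite_df_1d(prep, c(1, 0)), J - 1,
               tolerance = 0.35)

  # the 1-df F test agrees with the squared t test
  t1 <- semdense:::contest_1d(prep, c(0, 1))
  f1 <- semdense:::contest_md(prep, matrix(c(0, 1), nrow = 1))
  expect_equal(f1$F, t1$t^2, tolerance = 1e-10)
  expect_equal(f1$ddf, t1$df, tolerance = 1e-6)
})

test_that("Satterthwaite t test matches the published sleepstudy reference", {
  fm <- lme4::lmer(Reaction ~ Days + (Days | Subject), lme4::sleepstudy)
  prep <- semdense:::satterthwaite_prep(fm)
  r <- semdense:::contest_1d(prep, c(0, 1))
  # the standard Satterthwaite result for this model: t(17) = 6.77
  expect_equal(r$df, 17, tolerance = 0.02)
  expect_equal(r$t, 6.771, tolerance = 1e-3)
})

test_that("the fitted model recovers its own parameterization", {
  fx <- fit_fixture()
  fit <- fx$fit
  an <- anova_type3(fit)
  expect_equal(rownames(an),
               c("group", "sneigh", "type", "log_duration",
                 "group:sneigh", "group:type"))
  expect_true(all(an$NumDF == c(1, 1, 2, 1, 1, 2)))
  expect_true(all(an$DenDF > 0))
  expect_true(all(an$`F value` >= 0))

  # 1-df terms: F equals the squared Wald t of the matching coefficient
  b <- lme4::fixef(fit$model)
  se <- sqrt(diag(as.matrix(vcov(fit$model))))
  expect_equal(an["group:sneigh", "F value"],
               unname((b["group1:sneigh"] / se["group1:sneigh"])^2),
               tolerance = 1e-8)

  # Sum Sq / Mean Sq follow the F = MS / sigma^2 convention
  expect_equal(an$`Mean Sq`, an$`F value` * sigma(fit$model)^2,
               tolerance = 1e-10)
  expect_equal(an$`Sum Sq`, an$`Mean Sq` * an$NumDF, tolerance = 1e-10)
})

test_that("simple slopes match refitting with each group as reference", {
  fx <- fit_fixture()
  fit <- fx$fit
  sl <- simple_slopes(fit)
  expect_equal(sl$group, c("EB", "SC"))

  # reparameterization oracle: treatment coding with EB (then SC) as the
  # reference level makes the sneigh coefficient that group's slope
  for (g in c("EB", "SC")) {
    dat <- fit$data
    dat$group <- stats::relevel(factor(as.character(dat$group),
                                       levels = c("EB", "SC")), ref = g)
    fm <- lme4::lmer(log_rt ~ group * sneigh + group * type + log_duration +
                       (sneigh | participant) + (1 | stimulus), data = dat)
    expect_equal(sl$b[sl$group == g], unname(lme4::fixef(fm)["sneigh"]),
                 tolerance = 1e-5)
  }

  # slope difference equals the interaction coefficient under sum coding
  b <- lme4::fixef(fit$model)
  expect_equal(sl$b[sl$group == "EB"] - sl$b[sl$group == "SC"],
               unname(2 * b["group1:sneigh"]), tolerance = 1e-10)
  expect_true(all(sl$p_z > 0 & sl$p_z <= 1))
})

test_that("F tests are invariant to treatment vs sum factor coding", {
  fx <- fit_fixture()
  fit <- fx$fit
  an_sum <- anova_type3(fit)

  dat <- fit$data
  dat$group <- factor(as.character(dat$group))
  dat$type <- factor(as.character(dat$type))  # default treatment contrasts
  fm <- lme4::lmer(log_rt ~ group * sneigh + group * type + log_duration +
                     (sneigh | participant) + (1 | stimulus), data = dat)
  prep <- semdense:::satterthwaite_prep(fm)
  # Type-III hypothesis for group:sneigh under treatment coding is the
  # single interaction coefficient
  cn <- names(lme4::fixef(fm))
  L <- as.numeric(cn == "groupSC:sneigh")
  f_trt <- semdense:::contest_md(prep, matrix(L, nrow = 1))
  expect_equal(f_trt$F, an_sum["group:sneigh", "F value"], tolerance = 1e-6)
  expect_equal(f_trt$ddf, an_sum["group:sneigh", "DenDF"], tolerance = 1e-3)
})

test_that("type contrasts recover a generated concreteness advantage", {
  fx <- fit_fixture()
  ph <- posthoc_type(fx$fit)
  expect_equal(ph$contrast,
               c("abstract - multimodal", "abstract - visual",
                 "visual - multimodal"))
  te <- fx$cfg$rt_model$type_effects
  gen <- c(te["abstract"] - te["multimodal"], te["abstract"] - te["visual"],
           te["visual"] - te["multimodal"])
  # recovery within 3 SEs each (single dataset, sampling error applies)
  expect_true(all(abs(ph$estimate - gen) < 3 * ph$se))
  # contrast identity: (a-m) - (a-v) = v-m
  expect_equal(ph$estimate[3], ph$estimate[1] - ph$estimate[2],
               tolerance = 1e-10)
})

test_that("model criticism is a fixed point on clean data and repairs outliers", {
  fx <- fit_fixture()
  fit <- fx$fit

  # large threshold: nothing removed, refit reproduces the original
  cr0 <- model_criticism(fit, threshold_sd = 50)
  expect_equal(cr0$n_removed, 0L)
  expect_equal(lme4::fixef(cr0$refit$model), lme4::fixef(fit$model),
               tolerance = 1e-8)

  # inject 5 gross outliers into the data and check they are trimmed
  dat <- fit$data
  set.seed(43)
  idx <- sample.int(nrow(dat), 5)
  dat$log_rt[idx] <- dat$log_rt[idx] + 3          # ~ e^3 fold slower
  refit <- fit_sneigh_lmm(dat)
  cr <- model_criticism(refit, threshold_sd = 2.5)
  removed <- setdiff(rownames(dat), rownames(cr$refit$data))
  expect_gte(sum(rownames(dat)[idx] %in% removed), 4)

  # trimming moves the average slope back toward the generative value
  gen_mean <- (fx$cfg$rt_model$slope_eb + fx$cfg$rt_model$slope_sc) / 2
  b_dirty <- unname(lme4::fixef(refit$model)["sneigh"])
  b_crit <- unname(lme4::fixef(cr$refit$model)["sneigh"])
  b_clean <- unname(lme4::fixef(fit$model)["sneigh"])
  expect_lt(abs(b_crit - b_clean), abs(b_dirty - b_clean))
  expect_true(is.finite(gen_mean))
})

test_that("R2 obeys its limits and bounds", {
  fx <- fit_fixture()
  r2 <- r2_nakagawa(fx$fit)
  expect_true(r2["marginal"] >= 0 && r2["conditional"] <= 1)
  expect_gte(r2["conditional"], r2["marginal"])

  # near-noiseless data: both R2 approach 1
  cfg <- small_config(
    seed = 44,
    rt_model = list(sd_participant = 1e-4, sd_stimulus = 1e-4,
                    sd_slope = 0, cor_intercept_slope = 0,
                    sd_residual = 1e-4),
    error_model = list(error_prob = 0)
  )
  emb <- generate_embedding_space(cfg)
  density <- compute_density_table(emb$freq$word[1:24], emb$space, emb$space,
                                   k = 5)
  trials <- log_transforms(generate_trials(cfg, density))
  fit <- fit_sneigh_lmm(trials)
  r2b <- r2_nakagawa(fit)
  expect_gt(r2b["marginal"], 0.999)
  expect_gt(r2b["conditional"], 0.999)
})

test_that("model fitting fails loudly on malformed analysis data", {
  fx <- fit_fixture()
  dat <- fx$fit$data
  expect_error(fit_sneigh_lmm(dat[dat$group == "EB", ]), "both groups")
  expect_error(fit_sneigh_lmm(dat[dat$type != "visual", ]), "three word types")
  d1 <- dat; d1$sneigh <- NULL
  expect_error(fit_sneigh_lmm(d1), "lacks column")
  expect_error(fit_sneigh_lmm(d1, density = fx$density[1:3, ]),
               "no density value")
  d2 <- dat; d2$sneigh[1] <- NA
  expect_error(fit_sneigh_lmm(d2), "missing values")
})
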