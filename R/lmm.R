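#' Fit the semantic-neighborhood-density mixed model
#'
#' Fits, with `lme4`, the crossed random-effects model
#' `log_rt ~ group * sneigh + group * type + log_duration +
#' (sneigh | participant) + (1 | stimulus)`:
#' log reaction time as a function of group (early blind vs sighted),
#' semantic neighborhood density (raw cosine scale, uncentered, so slopes
#' are directly interpretable on that scale), word type, and log stimulus
#' duration, with correlated by-participant intercepts and density slopes
#' and by-stimulus intercepts. Factors use sum-to-zero contrasts so the
#' Type-III F table is well defined; group-specific slopes and pairwise
#' type contrasts are recovered as linear combinations, so the coding is
#' internal only.
#'
#' @param trials a cleaned, log-transformed word-trial table (see
#'   [clean_trials()]); must contain `log_rt`, `group`, `type`,
#'   `log_duration`, `participant`, `stimulus`, and either a `sneigh` column
#'   or be joined against `density`.
#' @param density optional `density_table` supplying `sneigh` per stimulus.
#' @param reml logical; REML estimation (default) or ML.
#' @param center_sneigh center the density predictor (default `FALSE`;
#'   affects the intercept only).
#' @return An object of class `sneigh_fit`: list with the `lmerMod` `model`,
#'   the analysis `data`, convergence diagnostics (`converged`, `singular`,
#'   `messages`) and a cache environment for the Satterthwaite quantities.
#' @export
fit_sneigh_lmm <- function(trials, density = NULL, reml = TRUE,
                           center_sneigh = FALSE) {
  data <- as.data.frame(trials)
  if (!is.null(density)) {
    idx <- match(data$stimulus, density$word)
    if (anyNA(idx)) {
      miss <- unique(data$stimulus[is.na(idx)])
      stop("no density value for stimuli: ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    data$sneigh <- density$sneigh[idx]
  }
  needed <- c("log_rt", "group", "type", "sneigh", "log_duration",
              "participant", "stimulus")
  miss <- setdiff(needed, names(data))
  if (length(miss))
    stop("model data lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (anyNA(data[needed]))
    stop("model data contains missing values", call. = FALSE)

  data$group <- factor(as.character(data$group), levels = c("EB", "SC"))
  data$type <- factor(as.character(data$type),
                      levels = c("abstract", "multimodal", "visual"))
  if (any(is.na(data$group)) || any(is.na(data$type)))
    stop("group must be EB/SC and type abstract/multimodal/visual",
         call. = FALSE)
  if (nlevels(droplevels(data$group)) < 2L)
    stop("both groups must be represented", call. = FALSE)
  if (nlevels(droplevels(data$type)) < 3L)
    stop("all three word types must be represented", call. = FALSE)
  data$participant <- factor(data$participant)
  data$stimulus <- factor(data$stimulus)
  stats::contrasts(data$group) <- stats::contr.sum(2)
  stats::contrasts(data$type) <- stats::contr.sum(3)
  if (center_sneigh) data$sneigh <- data$sneigh - mean(data$sneigh)

  form <- log_rt ~ group * sneigh + group * type + log_duration +
    (sneigh | participant) + (1 | stimulus)

  messages <- character(0)
  model <- withCallingHandlers(
    lme4::lmer(form, data = data, REML = reml),
    warning = function(w) {
      messages <<- c(messages, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      messages <<- c(messages, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  X <- lme4::getME(model, "X")
  if (qr(X)$rank < ncol(X))
    stop("fixed-effect design is rank deficient; aliased columns: ",
         paste(colnames(X)[-seq_len(qr(X)$rank)], collapse = ", "),
         call. = FALSE)
  singular <- lme4::isSingular(model)
  conv <- !any(grepl("failed to converge", messages, fixed = TRUE))
  if (!conv)
    warning("model did not converge: ", paste(messages, collapse = "; "),
            call. = FALSE)
  if (singular)
    messages <- c(messages, "singular random-effects fit (boundary estimate)")

  structure(
    list(model = model, data = data, reml = reml,
         converged = conv, singular = singular, messages = messages,
         cache = new.env(parent = emptyenv())),
    class = "sneigh_fit"
  )
}

#' @export
print.sneigh_fit <- function(x, ...) {
  cat("Semantic neighborhood density mixed model (",
      if (x$reml) "REML" else "ML", ")\n", sep = "")
  cat("  observations:", nrow(x$data),
      " participants:", nlevels(x$data$participant),
      " stimuli:", nlevels(x$data$stimulus), "\n")
  if (!x$converged) cat("  ** convergence failure reported **\n")
  if (x$singular) cat("  ** singular random-effects fit **\n")
  print(anova_type3(x))
  invisible(x)
}

# cached Satterthwaite preparation
satt_prep <- function(fit) {
  stopifnot(inherits(fit, "sneigh_fit"))
  if (is.null(fit$cache$prep))
    fit$cache$prep <- satterthwaite_prep(fit$model)
  fit$cache$prep
}

#' Type-III F table with Satterthwaite denominator df
#'
#' With sum-to-zero factor coding, each model term's Type-III hypothesis is
#' that its coefficient block is zero; each block is tested by an F statistic
#' whose denominator degrees of freedom use the Satterthwaite approximation.
#' `Mean Sq` is `F * sigma^2` so the table reads like a classical ANOVA.
#'
#' @param fit a [fit_sneigh_lmm()] object.
#' @return data.frame with `Sum Sq`, `Mean Sq`, `NumDF`, `DenDF`, `F value`,
#'   `Pr(>F)`, one row per fixed-effect term.
#' @export
anova_type3 <- function(fit) {
  prep <- satt_prep(fit)
  X <- lme4::getME(fit$model, "X")
  asgn <- attr(X, "assign")
  labels <- attr(stats::terms(fit$model, fixed.only = TRUE), "term.labels")
  p <- length(prep$beta)
  out <- do.call(rbind, lapply(seq_along(labels), function(i) {
    cols <- which(asgn == i)
    L <- diag(p)[cols, , drop = FALSE]
    contest_md(prep, L)
  }))
  sigma2 <- prep$sigma^2
  res <- data.frame(
    `Sum Sq` = out$F * sigma2 * out$ndf,
    `Mean Sq` = out$F * sigma2,
    NumDF = out$ndf, DenDF = out$ddf,
    `F value` = out$F, `Pr(>F)` = out$p,
    row.names = labels, check.names = FALSE
  )
  class(res) <- c("anova", "data.frame")
  attr(res, "heading") <- "Type III Analysis of Variance Table with Satterthwaite's method"
  res
}

# model-matrix rows for prediction points, using the fitted contrasts
fixed_rows <- function(fit, newdata) {
  tt <- stats::delete.response(stats::terms(fit$model, fixed.only = TRUE))
  contr <- list(group = stats::contrasts(fit$data$group),
                type = stats::contrasts(fit$data$type))
  mf <- stats::model.frame(tt, newdata, xlev = list(
    group = levels(fit$data$group), type = levels(fit$data$type)))
  stats::model.matrix(tt, mf, contrasts.arg = contr)
}

# contrast of the fixed-effect predictor averaged over type levels
slope_contrast <- function(fit, group) {
  grid <- expand.grid(group = group,
                      type = levels(fit$data$type),
                      log_duration = 0, sneigh = c(0, 1),
                      stringsAsFactors = FALSE)
  X <- fixed_rows(fit, grid)
  colMeans(X[grid$sneigh == 1, , drop = FALSE]) -
    colMeans(X[grid$sneigh == 0, , drop = FALSE])
}

#' Group-specific simple slopes of semantic neighborhood density
#'
#' The per-group slope of log RT on SNeigh, as a linear combination of the
#' fixed effects (averaged over word types), with its standard error from
#' the coefficient covariance. Reported with both the normal-approximation
#' z test and the Satterthwaite t test, since published tables use z.
#'
#' @param fit a [fit_sneigh_lmm()] object.
#' @return data.frame with one row per group: `b`, `se`, `z`, `p_z`, `df`,
#'   `p_t`, and the Wald 95% CI.
#' @export
simple_slopes <- function(fit) {
  prep <- satt_prep(fit)
  out <- do.call(rbind, lapply(levels(fit$data$group), function(g) {
    L <- slope_contrast(fit, g)
    r <- contest_1d(prep, L)
    data.frame(group = g, b = r$estimate, se = r$se, z = r$t,
               p_z = 2 * stats::pnorm(abs(r$t), lower.tail = FALSE),
               df = r$df, p_t = r$p,
               ci_lower = r$estimate - 1.96 * r$se,
               ci_upper = r$estimate + 1.96 * r$se,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise word-type contrasts on estimated marginal means
#'
#' Estimated marginal means of the three word types (averaged over groups,
#' at the mean density and mean log duration of the analysis data), and
#' their three pairwise differences with unadjusted p values, as published
#' post-hoc tables report them.
#'
#' @param fit a [fit_sneigh_lmm()] object.
#' @return data.frame of contrasts: `estimate`, `se`, `z`, `p_z`, `df`,
#'   `p_t`.
#' @export
posthoc_type <- function(fit) {
  prep <- satt_prep(fit)
  types <- levels(fit$data$type)
  emm_row <- function(tp) {
    grid <- expand.grid(group = levels(fit$data$group), type = tp,
                        log_duration = mean(fit$data$log_duration),
                        sneigh = mean(fit$data$sneigh),
                        stringsAsFactors = FALSE)
    colMeans(fixed_rows(fit, grid))
  }
  rows <- lapply(types, emm_row)
  names(rows) <- types
  pairs <- list(c("abstract", "multimodal"), c("abstract", "visual"),
                c("visual", "multimodal"))
  out <- do.call(rbind, lapply(pairs, function(pr) {
    L <- rows[[pr[1L]]] - rows[[pr[2L]]]
    r <- contest_1d(prep, L)
    data.frame(contrast = paste(pr[1L], "-", pr[2L]),
               estimate = r$estimate, se = r$se, z = r$t,
               p_z = 2 * stats::pnorm(abs(r$t), lower.tail = FALSE),
               df = r$df, p_t = r$p, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Model criticism: refit after trimming large standardized residuals
#'
#' Drops observations whose conditional residuals, standardized by the
#' estimated residual SD, exceed `threshold_sd` in absolute value, and
#' refits. A guard against overly influential outliers; the refit should
#' tell the same story as the original fit.
#'
#' @param fit a converged [fit_sneigh_lmm()] object.
#' @param threshold_sd residual threshold in residual-SD units (default 2.5).
#' @return list of class `sneigh_criticism`: `original`, `refit`,
#'   `n_removed`, `fraction_removed`.
#' @export
model_criticism <- function(fit, threshold_sd = 2.5) {
  stopifnot(inherits(fit, "sneigh_fit"))
  std <- stats::residuals(fit$model) / stats::sigma(fit$model)
  keep <- abs(std) <= threshold_sd
  sub <- fit$data[keep, , drop = FALSE]
  cells <- table(sub$group, sub$type)
  if (any(cells == 0))
    stop("residual trimming emptied a group x type cell; cannot refit",
         call. = FALSE)
  refit <- fit_sneigh_lmm(sub, density = NULL, reml = fit$reml)
  structure(
    list(original = fit, refit = refit,
         n_removed = sum(!keep),
         fraction_removed = mean(!keep)),
    class = "sneigh_criticism"
  )
}

#' @export
print.sneigh_criticism <- function(x, ...) {
  cat(sprintf("Model criticism: removed %d observations (%.2f%%)\n",
              x$n_removed, 100 * x$fraction_removed))
  print(anova_type3(x$refit))
  invisible(x)
}

#' Marginal and conditional R-squared for the mixed model
#'
#' Variance explained by the fixed effects alone (marginal) and by fixed
#' plus random effects (conditional), relative to the total of fixed,
#' random and residual variance. The fixed-effect variance is the variance
#' of the fixed-effect linear predictor over the data; random-slope terms
#' contribute through the mean quadratic form of their design rows with the
#' estimated covariance matrix.
#'
#' @param fit a [fit_sneigh_lmm()] object (or a bare `lmerMod`).
#' @return named numeric vector `c(marginal =, conditional =)`.
#' @export
r2_nakagawa <- function(fit) {
  model <- if (inherits(fit, "sneigh_fit")) fit$model else fit
  stopifnot(inherits(model, "lmerMod"))
  X <- lme4::getME(model, "X")
  vf <- stats::var(drop(X %*% lme4::fixef(model)))
  vc <- lme4::VarCorr(model)
  mml <- lme4::getME(model, "mmList")
  vr <- 0
  for (i in seq_along(vc)) {
    S <- as.matrix(vc[[i]])
    Z <- as.matrix(mml[[i]])
    vr <- vr + mean(rowSums((Z %*% S) * Z))
  }
  ve <- stats::sigma(model)^2
  total <- vf + vr + ve
  if (total <= 0) stop("zero total variance", call. = FALSE)
  c(marginal = vf / total, conditional = (vf + vr) / total)
}
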