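.term_table <- function(coefs) {
  # coefs: matrix with columns estimate, se, t, p (p may be absent)
  out <- as.data.frame(coefs)
  if (ncol(out) == 3L) {
    colnames(out) <- c("estimate", "se", "t")
    out$p <- 2 * stats::pnorm(-abs(out$t))
  } else {
    out <- out[, c(1L, 2L, ncol(out) - 1L, ncol(out))]
    colnames(out) <- c("estimate", "se", "t", "p")
  }
  out
}

.lrt <- function(ll_full, ll_null, df) {
  chi2 <- max(0, 2 * (ll_full - ll_null))
  structure(list(chi2 = chi2, df = as.integer(df),
                 p_value = stats::pchisq(chi2, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Likelihood ratio test: X2 = %.3f, df = %d, p = %s\n",
              x$chi2, x$df, format.pval(x$p_value)))
  invisible(x)
}

.playback_fit <- function(terms, logLik, n_obs, fitted, residuals,
                          random_effects = NULL, model = NULL,
                          singular = FALSE) {
  structure(list(terms = terms, log_likelihood = logLik, n_obs = n_obs,
                 fitted = fitted, residuals = residuals,
                 random_effects = random_effects, model = model,
                 singular = singular),
            class = "playback_fit")
}

#' @export
print.playback_fit <- function(x, ...) {
  cat(sprintf("<playback_fit: n = %d, logLik = %.2f%s>\n", x$n_obs,
              x$log_likelihood,
              if (!is.null(x$random_effects))
                sprintf(", subject intercept var = %.3f",
                        x$random_effects["subject_sd"] ^ 2) else ""))
  print(round(x$terms, 4))
  invisible(x)
}

#' @export
coef.playback_fit <- function(object, ...) {
  stats::setNames(object$terms$estimate, rownames(object$terms))
}

#' @export
residuals.playback_fit <- function(object, ...) object$residuals

.drop_skipped <- function(t) {
  if (!is.null(t$skipped)) t <- t[!t$skipped, , drop = FALSE]
  t[!is.na(t$look_time), , drop = FALSE]
}

#' Fit a condition model of looking time
#'
#' The three planned condition contrasts of the playback analysis, each a
#' Gaussian linear model of looking time with treatment contrasts and the
#' two control covariates (conflict intensity and trial presentation
#' order), tested by likelihood ratio against the control-only null:
#'
#' * `which = 1`: conditions 1 vs 2, 3, 4 (reference condition 1);
#' * `which = 2`: condition 3 vs 4 (reference condition 3);
#' * `which = 3`: condition 5 vs 6 (reference condition 5).
#'
#' Both models are ordinary maximum-likelihood Gaussian fits, so the LRT
#' statistic `2 (llF - llN)` is referred to a chi-square with df equal to
#' the number of condition dummies.
#'
#' @param trials a trial table (see [gen_trials()]); skipped trials are
#'   dropped.
#' @param which which planned comparison, 1, 2 or 3.
#' @return list with elements `fit` (a `playback_fit`) and `lrt` (an
#'   `lrt_result`).
#' @export
fit_condition_model <- function(trials, which = 1) {
  stopifnot(which %in% 1:3)
  conds <- list(c(1, 2, 3, 4), c(3, 4), c(5, 6))[[which]]
  t <- .drop_skipped(trials)
  t <- t[t$condition %in% conds, , drop = FALSE]
  counts <- table(factor(t$condition, levels = conds))
  if (any(counts < 2))
    stop(sprintf("condition(s) with fewer than 2 trials: %s",
                 paste(conds[counts < 2], collapse = ", ")), call. = FALSE)
  t$condition <- factor(t$condition, levels = conds)
  full <- stats::lm(look_time ~ condition + trial_order + conflict_intensity,
                    data = t)
  if (any(is.na(stats::coef(full))))
    stop(sprintf("rank-deficient design; aliased term(s): %s",
                 paste(names(stats::coef(full))[is.na(stats::coef(full))],
                       collapse = ", ")), call. = FALSE)
  null <- stats::lm(look_time ~ trial_order + conflict_intensity, data = t)
  sm <- summary(full)$coefficients
  fit <- .playback_fit(.term_table(sm), as.numeric(stats::logLik(full)),
                       nrow(t), stats::fitted(full), stats::residuals(full),
                       model = full)
  list(fit = fit,
       lrt = .lrt(stats::logLik(full), stats::logLik(null),
                  length(conds) - 1L))
}

#' Fit the dyadic-relationship mixed model of looking time
#'
#' Linear mixed model of looking time on the social covariates of the
#' playback dyad — friendship between the callers (z-scored), their
#' relatedness (0/1), the absolute difference in their Elo ratings
#' (z-scored) and the subject's eigenvector centrality — plus trial
#' presentation order, with a random intercept per subject. Fitted by
#' maximum likelihood (not REML) so the likelihood-ratio test against the
#' control-only null (trial order + random intercept) is valid across
#' fixed-effect structures. Fixed-effect p-values use Satterthwaite
#' degrees of freedom. A singular random-effect fit falls back to the
#' fixed-effects model with a warning.
#'
#' @param trials a trial table; skipped trials are dropped.
#' @return list with `fit` (a `playback_fit`) and `lrt` (an `lrt_result`,
#'   df = 4).
#' @export
fit_relationship_model <- function(trials) {
  t <- .drop_skipped(trials)
  if (min(table(t$subject_id)) < 2)
    warning("some subjects have fewer than 2 trials; the random intercept ",
            "may be poorly estimable", call. = FALSE)
  form_full <- look_time ~ friendship_between_callers +
    relatedness_between_callers + elo_diff + subject_centrality +
    trial_order + (1 | subject_id)
  form_null <- look_time ~ trial_order + (1 | subject_id)
  full <- suppressMessages(lmerTest::lmer(form_full, data = t, REML = FALSE))
  if (lme4::isSingular(full, tol = 1e-5)) {
    warning("singular random-intercept fit; falling back to the ",
            "fixed-effects model", call. = FALSE)
    fx <- stats::lm(look_time ~ friendship_between_callers +
                      relatedness_between_callers + elo_diff +
                      subject_centrality + trial_order, data = t)
    nl <- stats::lm(look_time ~ trial_order, data = t)
    fit <- .playback_fit(.term_table(summary(fx)$coefficients),
                         as.numeric(stats::logLik(fx)), nrow(t),
                         stats::fitted(fx), stats::residuals(fx),
                         model = fx, singular = TRUE)
    return(list(fit = fit, lrt = .lrt(stats::logLik(fx), stats::logLik(nl),
                                      4L)))
  }
  null <- suppressMessages(lme4::lmer(form_null, data = t, REML = FALSE))
  sm <- summary(full)$coefficients  # estimate, se, df, t, p
  terms <- data.frame(estimate = sm[, "Estimate"],
                      se = sm[, "Std. Error"],
                      t = sm[, "t value"],
                      p = sm[, "Pr(>|t|)"], row.names = rownames(sm))
  vc <- as.data.frame(lme4::VarCorr(full))
  re <- c(subject_sd = vc$sdcor[vc$grp == "subject_id"][1],
          residual_sd = vc$sdcor[vc$grp == "Residual"][1])
  fit <- .playback_fit(terms, as.numeric(stats::logLik(full)), nrow(t),
                       stats::fitted(full), stats::residuals(full),
                       random_effects = re, model = full)
  list(fit = fit, lrt = .lrt(stats::logLik(full), stats::logLik(null), 4L))
}

#' Variance inflation factors of a design matrix
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing predictor
#' `j` on all remaining predictors (with intercept). Perfectly collinear
#' predictors are reported as `Inf`.
#'
#' @param design numeric matrix or data.frame of predictors (no intercept
#'   column).
#' @return named numeric vector of VIFs.
#' @export
vif <- function(design) {
  X <- as.matrix(design)
  if (ncol(X) < 2L) stop("need at least 2 predictors", call. = FALSE)
  vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    rss <- sum(fit$residuals ^ 2)
    tss <- sum((X[, j] - mean(X[, j])) ^ 2)
    if (tss == 0) return(Inf)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L), USE.NAMES = FALSE) |>
    stats::setNames(colnames(X))
}

#' Residual normality diagnostics for a fitted model
#'
#' Returns the material of a normal QQ inspection plus summary shape
#' statistics: theoretical and sample quantiles, skewness, excess
#' kurtosis, and a Shapiro-Wilk statistic and p-value (for 3 to 5000
#' residuals). Optionally writes a QQ plot to a PNG file.
#'
#' @param fit a `playback_fit` (or anything with a `residuals` element).
#' @param plot_file optional path of a PNG to write.
#' @return list `qq` (data.frame `theoretical, sample`), `skewness`,
#'   `kurtosis` (excess), `shapiro_w`, `shapiro_p`, `zero_variance`.
#' @export
residual_checks <- function(fit, plot_file = NULL) {
  r <- if (inherits(fit, "playback_fit")) fit$residuals else
    stats::residuals(fit)
  if (stats::sd(r) == 0) {
    return(list(qq = data.frame(theoretical = numeric(0),
                                sample = numeric(0)),
                skewness = NA_real_, kurtosis = NA_real_,
                shapiro_w = NA_real_, shapiro_p = NA_real_,
                zero_variance = TRUE))
  }
  qq <- stats::qqnorm(r, plot.it = FALSE)
  ord <- order(qq$x)
  sw <- if (length(r) >= 3 && length(r) <= 5000)
    stats::shapiro.test(r) else list(statistic = NA_real_, p.value = NA_real_)
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 480, height = 480)
    stats::qqnorm(r); stats::qqline(r)
    grDevices::dev.off()
  }
  list(qq = data.frame(theoretical = qq$x[ord], sample = qq$y[ord]),
       skewness = e1071::skewness(r, type = 2),
       kurtosis = e1071::kurtosis(r, type = 2),
       shapiro_w = unname(sw$statistic), shapiro_p = sw$p.value,
       zero_variance = FALSE)
}
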