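#' Filter a feature table by the discriminant-analysis inclusion rule
#'
#' A caller is eligible for the discriminant analysis only if its number of
#' call units exceeds the number of parameters entering the analysis (the
#' class-size condition for a well-posed within-class covariance).
#'
#' @param tab a feature table with a `caller_id` column.
#' @param n_params number of parameters (features) in the analysis.
#' @return the table restricted to eligible callers, with attribute
#'   `eligible_callers`.
#' @export
check_inclusion <- function(tab, n_params = 5) {
  counts <- table(tab$caller_id)
  eligible <- names(counts)[counts > n_params]
  if (length(eligible) < 2L)
    stop(sprintf(paste("analysis infeasible: only %d caller(s) have more than",
                       "%d units"), length(eligible), n_params), call. = FALSE)
  out <- tab[tab$caller_id %in% eligible, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "eligible_callers") <- eligible
  out
}

# Fast pooled-covariance Gaussian discriminant core. X: n x p matrix,
# idx: integer class index in 1..k. Returns linear score parameters.
.lda_core <- function(X, idx, k, ridge = 1e-8) {
  n <- nrow(X)
  nk <- tabulate(idx, k)
  if (any(nk == 0L))
    stop("a class has no training units", call. = FALSE)
  M <- rowsum(X, idx) / nk
  SS <- crossprod(X) - crossprod(sqrt(nk) * M)
  W <- SS / (n - k)
  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch)) {
    W <- W + diag(ridge * mean(diag(W)) + 1e-12, ncol(W))
    ch <- chol(W)
  }
  Wi <- chol2inv(ch)
  A <- M %*% Wi                                   # k x p
  list(M = M, W = W, Wi = Wi, A = A,
       const = -0.5 * rowSums(A * M) + log(nk / n), nk = nk)
}

.lda_scores <- function(core, X) {
  tcrossprod(X, core$A) + rep(core$const, each = nrow(X))
}

# Predicted class index; score ties broken towards the lowest class index.
.lda_predict_idx <- function(core, X) {
  max.col(.lda_scores(core, X), ties.method = "first")
}

.feature_matrix <- function(tab, feats = feature_names) {
  missing <- setdiff(feats, colnames(tab))
  if (length(missing) > 0L)
    stop(sprintf("feature column(s) missing from table: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  as.matrix(tab[, feats, drop = FALSE])
}

#' Fit a linear discriminant model of caller identity
#'
#' Gaussian equal-covariance (pooled within-class) linear discriminant
#' analysis with empirical priors: a unit is assigned to the class
#' maximising `x' W^-1 m_k - m_k' W^-1 m_k / 2 + log pi_k`. A small ridge
#' is added to the pooled covariance diagonal only when it is numerically
#' singular. Score ties are broken towards the lowest caller id.
#'
#' @param tab a feature table with `caller_id` and the five feature columns.
#' @param features feature column names to use.
#' @param ridge relative ridge applied on near-singularity.
#' @return an object of class `"caller_lda"` with elements `classes`,
#'   `class_means`, `pooled_within_cov`, `priors`, `discriminant_axes`,
#'   `features`.
#' @export
fit_lda <- function(tab, features = feature_names, ridge = 1e-8) {
  classes <- sort(unique(tab$caller_id))
  if (length(classes) < 2L) stop("need at least 2 classes", call. = FALSE)
  X <- .feature_matrix(tab, features)
  idx <- match(tab$caller_id, classes)
  core <- .lda_core(X, idx, length(classes), ridge)
  # Fisher axes: eigenvectors of W^-1 B (between-class scatter)
  gm <- colMeans(X)
  Bm <- sweep(core$M, 2L, gm)
  B <- crossprod(sqrt(core$nk) * Bm) / nrow(X)
  ax <- eigen(core$Wi %*% B)
  keep <- seq_len(min(length(classes) - 1L, ncol(X)))
  structure(list(classes = classes, class_means = core$M,
                 pooled_within_cov = core$W, priors = core$nk / nrow(X),
                 discriminant_axes = Re(ax$vectors[, keep, drop = FALSE]),
                 features = features, .core = core),
            class = "caller_lda")
}

#' @export
print.caller_lda <- function(x, ...) {
  cat(sprintf("<caller_lda: %d classes, %d features>\n",
              length(x$classes), length(x$features)))
  invisible(x)
}

#' Predict caller identities from a fitted discriminant model
#'
#' @param object a [fit_lda()] model.
#' @param newdata a feature table with the model's feature columns.
#' @param ... unused.
#' @return character vector of predicted caller ids.
#' @export
predict.caller_lda <- function(object, newdata, ...) {
  X <- .feature_matrix(newdata, object$features)
  object$classes[.lda_predict_idx(object$.core, X)]
}

#' Classify a feature table and report accuracies
#'
#' @param model a [fit_lda()] model.
#' @param tab a labelled feature table.
#' @return list with `predicted`, `accuracy` (overall fraction correct) and
#'   `per_class_accuracy` (named, within each true class).
#' @export
classify <- function(model, tab) {
  pred <- predict(model, tab)
  correct <- pred == tab$caller_id
  per <- tapply(correct, factor(tab$caller_id, levels = model$classes), mean)
  list(predicted = pred, accuracy = mean(correct),
       per_class_accuracy = per)
}

.bout_map <- function(labels, bout_ids) {
  m <- tapply(labels, bout_ids, function(z) {
    u <- unique(z)
    if (length(u) != 1L)
      stop("data integrity error: a bout spans more than one caller",
           call. = FALSE)
    u
  })
  m  # named by bout id
}

#' Permute caller labels at the bout level
#'
#' Draws a uniformly random permutation of the bout-to-caller assignment
#' vector and propagates it to units, so that all units of a bout share one
#' (permuted) caller and the multiset of bouts per caller is preserved.
#' Uses the current RNG stream.
#'
#' @param labels per-unit caller ids.
#' @param bout_ids per-unit bout ids; every bout must map to one caller.
#' @return per-unit permuted caller ids.
#' @export
permute_nested <- function(labels, bout_ids) {
  bm <- .bout_map(labels, bout_ids)
  new_bm <- stats::setNames(sample(as.vector(bm)), names(bm))
  as.vector(new_bm[as.character(bout_ids)])
}

.null_summary <- function(perm_acc, observed) {
  p <- (sum(perm_acc >= observed) + 1) / (length(perm_acc) + 1)
  list(p_value = p, null_mean = mean(perm_acc),
       null_ci = stats::quantile(perm_acc, c(0.025, 0.975), names = FALSE))
}

.loo_accuracy <- function(X, labels, classes, holdout_groups, ridge = 1e-8) {
  idx <- match(labels, classes)
  groups <- unique(holdout_groups)
  pred <- integer(nrow(X))
  for (g in groups) {
    out <- holdout_groups == g
    core <- .lda_core(X[!out, , drop = FALSE], idx[!out], length(classes),
                      ridge)
    pred[out] <- .lda_predict_idx(core, X[out, , drop = FALSE])
  }
  pred == idx
}

.pdfa_engine <- function(tab, n_perm, seed, features, mode, holdout, ridge) {
  if (n_perm < 100)
    warning("fewer than 100 permutations gives a coarse null", call. = FALSE)
  classes <- sort(unique(tab$caller_id))
  k <- length(classes)
  if (k < 2L) stop("need at least 2 callers", call. = FALSE)
  bm <- .bout_map(tab$caller_id, tab$bout_id)
  if (length(bm) == k)
    stop(paste("permutation infeasible: every caller has a single bout, so",
               "permuted datasets are class relabelings with identical",
               "accuracy"), call. = FALSE)
  X <- .feature_matrix(tab, features)
  bout_levels <- names(bm)
  bout_idx <- match(as.character(tab$bout_id), bout_levels)
  bm_vec <- as.vector(bm)

  score_fun <- if (mode == "plain") {
    function(idx) {
      core <- .lda_core(X, idx, k, ridge)
      .lda_predict_idx(core, X) == idx
    }
  } else {
    groups <- if (holdout == "unit") seq_len(nrow(tab)) else tab$bout_id
    function(idx) .loo_accuracy(X, classes[idx], classes, groups, ridge)
  }

  obs_idx <- match(tab$caller_id, classes)
  obs_correct <- score_fun(obs_idx)
  observed <- mean(obs_correct)
  per_obs <- stats::setNames(
    as.vector(rowsum(obs_correct + 0, obs_idx) / tabulate(obs_idx, k)),
    classes)

  set.seed(seed)
  perm_acc <- numeric(n_perm)
  per_perm <- matrix(NA_real_, n_perm, k, dimnames = list(NULL, classes))
  for (i in seq_len(n_perm)) {
    # same draw as permute_nested(): one uniform shuffle of the bout labels
    idx <- match(sample(bm_vec), classes)[bout_idx]
    corr <- score_fun(idx)
    perm_acc[i] <- mean(corr)
    per_perm[i, ] <- rowsum(corr + 0, idx) / tabulate(idx, k)
  }
  ns <- .null_summary(perm_acc, observed)
  per_p <- vapply(classes, function(cl)
    (sum(per_perm[, cl] >= per_obs[[cl]]) + 1) / (n_perm + 1), numeric(1L))
  structure(list(observed_accuracy = observed,
                 per_class_accuracy = per_obs,
                 per_class_p = per_p,
                 permuted_accuracies = perm_acc,
                 p_value = ns$p_value, null_mean = ns$null_mean,
                 null_ci = ns$null_ci, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), mode = mode,
                 holdout = if (mode == "cross_validated") holdout else NA),
            class = "pdfa_result")
}

#' Permuted discriminant function analysis of caller identity
#'
#' Tests whether call units can be classified to their caller above chance
#' while respecting the non-independence of units within calling bouts.
#' The observed accuracy is the resubstitution accuracy of the pooled-
#' covariance linear discriminant. The chance distribution is built from
#' `n_perm` datasets in which the bout-to-caller assignment is permuted
#' uniformly (units of a bout stay together and the bouts-per-caller
#' multiset is preserved), each refitted and rescored identically. The
#' p-value is `(r + 1) / (n_perm + 1)` where `r` counts permuted accuracies
#' at or above the observed one; per-caller p-values are computed the same
#' way against the per-class null accuracies.
#'
#' @param tab feature table with `caller_id`, `bout_id` and the feature
#'   columns; should already pass [check_inclusion()].
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation stream.
#' @param features feature column names.
#' @param ridge relative ridge on a singular pooled covariance.
#' @return an object of class `"pdfa_result"`: observed and per-class
#'   accuracies, the permuted accuracy distribution, `p_value`, `null_mean`
#'   and 95% null quantile interval.
#' @seealso [pdfa_crossvalidated()] for the leave-one-out variant.
#' @export
pdfa_test <- function(tab, n_perm = 5000, seed = 1, features = feature_names,
                      ridge = 1e-8) {
  .pdfa_engine(tab, n_perm, seed, features, mode = "plain", holdout = "unit",
               ridge = ridge)
}

#' Cross-validated permuted discriminant function analysis
#'
#' As [pdfa_test()], but the observed accuracy is a leave-one-out accuracy:
#' with `holdout = "unit"` the discriminant is trained on all units but
#' one and scored on the held-out unit; `holdout = "bout"` holds out whole
#' bouts, which avoids leaking bout-level information between training and
#' test. The permutation null applies the identical leave-one-out scoring
#' to each permuted dataset.
#'
#' @inheritParams pdfa_test
#' @param holdout `"unit"` (leave one unit out) or `"bout"` (leave one
#'   bout out).
#' @return an object of class `"pdfa_result"` with `mode =
#'   "cross_validated"`.
#' @export
pdfa_crossvalidated <- function(tab, n_perm = 5000, seed = 1,
                                holdout = c("unit", "bout"),
                                features = feature_names, ridge = 1e-8) {
  holdout <- match.arg(holdout)
  .pdfa_engine(tab, n_perm, seed, features, mode = "cross_validated",
               holdout = holdout, ridge = ridge)
}

#' @export
print.pdfa_result <- function(x, ...) {
  cat(sprintf("Permuted discriminant function analysis (%s%s)\n",
              x$mode,
              if (identical(x$mode, "cross_validated"))
                paste0(", holdout = ", x$holdout) else ""))
  cat(sprintf("  observed accuracy : %.1f%%\n", 100 * x$observed_accuracy))
  cat(sprintf("  chance accuracy   : %.1f%% [95%% CI: %.1f-%.1f%%], %d permutations\n",
              100 * x$null_mean, 100 * x$null_ci[1], 100 * x$null_ci[2],
              x$n_perm))
  cat(sprintf("  p-value           : %s\n", format.pval(x$p_value)))
  invisible(x)
}

#' @export
summary.pdfa_result <- function(object, ...) {
  print(object)
  cat("  per-caller accuracy (p):\n")
  for (cl in names(object$per_class_accuracy))
    cat(sprintf("    %-6s %5.1f%%  (p = %s)\n", cl,
                100 * object$per_class_accuracy[[cl]],
                format.pval(object$per_class_p[[cl]])))
  invisible(object)
}
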