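#' Fit a logistic marker-panel model
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares (IRLS), with an optional ridge penalty on the
#' non-intercept coefficients. Iteration stops when the largest
#' coefficient change falls below 1e-8 or after 100 iterations.
#' Quasi-separation — the classical failure mode of small marker panels,
#' where the likelihood is maximized at infinite coefficients — is
#' detected from the diverging coefficient norm; the model is then flagged
#' `converged = FALSE` rather than silently reporting inflated
#' coefficients, and a small ridge (`penalty = 1e-4`, say) can be used to
#' stabilize the fit.
#'
#' @param features Numeric matrix or data frame, samples x markers, with
#'   column names.
#' @param labels Class label per sample; exactly two classes, each with
#'   >= 2 samples.
#' @param positive_class The class modelled as outcome 1; default the
#'   lexicographically later class label.
#' @param penalty Ridge strength >= 0 (0 = plain maximum likelihood).
#' @return A `panel_model`: intercept, named `coefficients`,
#'   `positive_class`, `converged` flag, `selection_trace` (empty here;
#'   filled by [stepwise_select()]), log-likelihood, `aic`, `n_iter`.
#' @seealso [predict_prob()], [stepwise_select()]
#' @export
fit_logistic <- function(features, labels, positive_class = NULL,
                         penalty = 0) {
  features <- as.matrix(features)
  if (ncol(features) > 0L && is.null(colnames(features)))
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) != 2L)
    stop("labels must contain exactly 2 classes (got ",
         length(cls), ")", call. = FALSE)
  if (min(table(labels)) < 2L)
    stop("each class needs >= 2 samples", call. = FALSE)
  if (is.null(positive_class)) positive_class <- cls[2]
  if (!positive_class %in% cls)
    stop("positive_class '", positive_class, "' not among labels",
         call. = FALSE)
  y <- as.numeric(labels == positive_class)
  X <- cbind(`(Intercept)` = 1, features)
  p <- ncol(X)
  # never penalize the intercept; the 1e-12 floor keeps the normal
  # equations solvable on rank-deficient designs (e.g. a constant-zero
  # feature) without materially perturbing the ML solution
  pen <- c(0, rep(max(penalty, 1e-12), p - 1L))
  beta <- rep(0, p)
  converged <- FALSE
  diverged <- FALSE
  iter <- 0L
  for (iter in seq_len(100L)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- tryCatch(
      drop(solve(XtW %*% X + diag(pen, p), XtW %*% z)),
      error = function(e) rep(NA_real_, p))
    if (anyNA(beta_new)) { diverged <- TRUE; break }
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (sqrt(sum(beta^2)) > 1e4) { diverged <- TRUE; break }
    if (delta < 1e-8) { converged <- TRUE; break }
  }
  if (diverged && penalty > 0)
    message("quasi-separation detected; returning the ridge-penalized fit")
  eta <- drop(X %*% beta)
  ll <- sum(y * eta - log1p(exp(eta)))
  structure(list(intercept = unname(beta[1]),
                 coefficients = stats::setNames(beta[-1],
                                                colnames(features)),
                 positive_class = positive_class,
                 converged = converged && !diverged,
                 penalty = penalty,
                 log_lik = ll,
                 aic = -2 * ll + 2 * p,
                 n_iter = iter,
                 selection_trace = list()),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat("panel_model (P = ", x$positive_class, "): intercept ",
      format(x$intercept, digits = 4), "\n", sep = "")
  if (length(x$coefficients) > 0L)
    print(round(x$coefficients, 4))
  else cat("(intercept-only)\n")
  cat(if (x$converged) "converged" else "NOT converged (quasi-separation?)",
      "; AIC ", format(x$aic, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Forward stepwise marker selection
#'
#' Starts from the intercept-only model and greedily adds the marker that
#' most improves the criterion — lower AIC, or a likelihood-ratio test
#' p-value below `alpha_enter` — until no candidate improves it. The full
#' decision trace is recorded on the returned model.
#'
#' @inheritParams fit_logistic
#' @param criterion `"aic"` (default) or `"lrt_p"`.
#' @param alpha_enter Entry threshold for the LRT criterion, default 0.05.
#' @return A `panel_model` restricted to the selected markers, with
#'   `selection_trace` listing each step's candidate scores and decision.
#' @export
stepwise_select <- function(features, labels, criterion = c("aic", "lrt_p"),
                            positive_class = NULL, penalty = 0,
                            alpha_enter = 0.05) {
  criterion <- match.arg(criterion)
  features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  null_feat <- features[, 0, drop = FALSE]
  current <- fit_logistic(null_feat, labels, positive_class, penalty)
  selected <- character()
  trace <- list()
  repeat {
    remaining <- setdiff(colnames(features), selected)
    if (length(remaining) == 0L) break
    fits <- lapply(remaining, function(v)
      fit_logistic(features[, c(selected, v), drop = FALSE], labels,
                   positive_class, penalty))
    names(fits) <- remaining
    if (criterion == "aic") {
      scores <- vapply(fits, `[[`, numeric(1), "aic")
      best <- names(which.min(scores))
      improves <- scores[best] < current$aic
    } else {
      scores <- vapply(fits, function(f)
        stats::pchisq(2 * (f$log_lik - current$log_lik), df = 1,
                      lower.tail = FALSE), numeric(1))
      best <- names(which.min(scores))
      improves <- scores[best] < alpha_enter
    }
    trace[[length(trace) + 1L]] <-
      list(step = length(trace) + 1L, candidate_scores = scores,
           added = if (improves) best else NA_character_,
           criterion = criterion)
    if (!improves) break
    selected <- c(selected, best)
    current <- fits[[best]]
  }
  current$selection_trace <- trace
  current
}

#' Predicted class probability of a panel model
#'
#' @param model A `panel_model`.
#' @param features Samples x markers matrix or data frame whose columns
#'   cover every coefficient of the model.
#' @return Numeric vector of probabilities of `model$positive_class`, one
#'   per row of `features`.
#' @export
predict_prob <- function(model, features) {
  stopifnot(inherits(model, "panel_model"))
  features <- as.matrix(features)
  genes <- names(model$coefficients)
  missing <- setdiff(genes, colnames(features))
  if (length(missing) > 0L)
    stop("feature column(s) missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  score <- rep(model$intercept, nrow(features)) +
    if (length(genes) > 0L)
      drop(features[, genes, drop = FALSE] %*% model$coefficients)
    else 0
  stats::plogis(score)
}

#' ROC curve and AUC
#'
#' Computes the full ROC curve over all score thresholds and the area
#' under it by the trapezoidal rule, under which tied scores contribute
#' one half — so the AUC equals the normalized Mann-Whitney U statistic,
#' `U / (n_pos * n_neg)`. Optionally attaches a stratified percentile
#' bootstrap confidence interval (see [auc_bootstrap_ci()]).
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Class label per score; both classes must be present.
#' @param positive_class Label counted as positive; default the
#'   lexicographically later one.
#' @param ci If `TRUE`, compute a bootstrap CI (requires `seed`).
#' @param n_boot,level,seed Passed to [auc_bootstrap_ci()].
#' @return A `roc_result`: `thresholds` (decreasing; first is `Inf`),
#'   `fpr`, `tpr` (non-decreasing along the curve), `auc`, and — when
#'   `ci` — `ci_low`, `ci_high`, `n_boot`, `seed`.
#' @export
roc_auc <- function(scores, labels, positive_class = NULL, ci = FALSE,
                    n_boot = 2000, level = 0.95, seed = NULL) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (length(cls) < 2L)
    stop("both classes must be present", call. = FALSE)
  if (length(cls) > 2L) stop("more than two classes", call. = FALSE)
  if (is.null(positive_class)) positive_class <- cls[2]
  pos <- labels == positive_class
  n_pos <- sum(pos); n_neg <- sum(!pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(scores[pos] >= t), numeric(1))
  fp <- vapply(thr, function(t) sum(scores[!pos] >= t), numeric(1))
  tpr <- c(0, tp / n_pos); fpr <- c(0, fp / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  res <- structure(list(thresholds = c(Inf, thr), fpr = fpr, tpr = tpr,
                        auc = auc, ci_low = NA_real_, ci_high = NA_real_,
                        n_boot = 0L, seed = seed,
                        positive_class = positive_class),
                   class = "roc_result")
  if (ci) {
    interval <- auc_bootstrap_ci(scores, labels, positive_class,
                                 n_boot = n_boot, level = level,
                                 seed = seed)
    res$ci_low <- interval[1]; res$ci_high <- interval[2]
    res$n_boot <- as.integer(n_boot)
  }
  res
}

#' @export
print.roc_result <- function(x, ...) {
  cat("roc_result: AUC = ", format(x$auc, digits = 4), sep = "")
  if (!is.na(x$ci_low))
    cat(" (95% CI ", format(x$ci_low, digits = 4), " to ",
        format(x$ci_high, digits = 4), ", ", x$n_boot, " bootstraps)",
        sep = "")
  cat("\n")
  invisible(x)
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Resamples positives and negatives separately (stratified bootstrap, so
#' every resample contains both classes), recomputes the trapezoidal AUC
#' for each resample and returns the percentile interval. Deterministic
#' under `seed`.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap resamples, >= 100. Default 2000.
#' @param level Confidence level, default 0.95.
#' @param seed Integer seed (required).
#' @return Length-2 numeric vector `c(ci_low, ci_high)`.
#' @export
auc_bootstrap_ci <- function(scores, labels, positive_class = NULL,
                             n_boot = 2000, level = 0.95, seed = NULL) {
  if (n_boot < 100) stop("`n_boot` must be >= 100", call. = FALSE)
  if (is.null(seed)) stop("`seed` is required", call. = FALSE)
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  if (is.null(positive_class)) positive_class <- cls[2]
  ipos <- which(labels == positive_class)
  ineg <- which(labels != positive_class)
  with_seed(seed, {
    aucs <- vapply(seq_len(n_boot), function(i) {
      idx <- c(sample(ipos, length(ipos), replace = TRUE),
               sample(ineg, length(ineg), replace = TRUE))
      roc_auc(scores[idx], labels[idx], positive_class)$auc
    }, numeric(1))
    alpha <- (1 - level) / 2
    unname(stats::quantile(aucs, c(alpha, 1 - alpha), type = 7))
  })
}

#' Comparative-Ct relative quantification
#'
#' Converts qPCR cycle-threshold measurements to relative expression by
#' the comparative (delta-delta Ct) method: per row,
#' `dCt = ct_target - ct_reference`; per gene,
#' `ddCt = dCt - mean(dCt of the calibrator class)`; relative quantity
#' `= 2^(-ddCt)`. A sample at its gene's calibrator mean therefore has
#' relative quantity 1.
#'
#' @param ct Data frame with columns `sample_id`, `class`, `gene`,
#'   `ct_target`, `ct_reference` (see [generate_ct_table()]).
#' @param calibrator Class label used as the calibrator; must be present.
#' @return The input with added columns `delta_ct`, `delta_delta_ct`,
#'   `rel_expr`.
#' @export
ddct_relative_expression <- function(ct, calibrator = "classB") {
  need <- c("sample_id", "class", "gene", "ct_target", "ct_reference")
  if (!all(need %in% names(ct)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyNA(ct$ct_reference))
    stop("missing reference Ct for sample '",
         ct$sample_id[which(is.na(ct$ct_reference))[1]], "'",
         call. = FALSE)
  if (!calibrator %in% ct$class)
    stop("calibrator class '", calibrator, "' not present", call. = FALSE)
  ct$delta_ct <- ct$ct_target - ct$ct_reference
  cal_mean <- tapply(ct$delta_ct[ct$class == calibrator],
                     ct$gene[ct$class == calibrator], mean)
  absent <- setdiff(unique(ct$gene), names(cal_mean))
  if (length(absent) > 0L)
    stop("no calibrator measurements for gene(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  ct$delta_delta_ct <- ct$delta_ct - unname(cal_mean[ct$gene])
  ct$rel_expr <- 2^(-ct$delta_delta_ct)
  ct
}
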