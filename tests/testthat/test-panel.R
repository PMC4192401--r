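sim_logistic <- function(n, beta0, beta, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * length(beta)), n,
              dimnames = list(NULL, paste0("x", seq_along(beta))))
  p <- plogis(beta0 + drop(X %*% beta))
  y <- ifelse(runif(n) < p, "pos", "neg")
  list(X = X, y = y)
}

test_that("IRLS agrees with glm on well-behaved data", {
  d <- sim_logistic(200, -0.5, c(1, -0.7), seed = 1)
  fit <- fit_logistic(d$X, d$y, positive_class = "pos")
  ref <- glm(I(d$y == "pos") ~ d$X, family = binomial())
  expect_true(fit$converged)
  expect_equal(fit$intercept, unname(coef(ref)[1]), tolerance = 1e-6)
  expect_equal(unname(fit$coefficients), unname(coef(ref)[-1]),
               tolerance = 1e-6)
  expect_equal(fit$aic, ref$aic, tolerance = 1e-6)
})

test_that("degenerate designs behave: zero feature, separation, bad labels", {
  y <- rep(c("a", "b"), each = 10)
  fit0 <- fit_logistic(matrix(0, 20, 1, dimnames = list(NULL, "z")), y)
  expect_equal(fit0$intercept, 0, tolerance = 1e-6)
  expect_equal(unname(fit0$coefficients), 0, tolerance = 1e-6)
  # perfectly separable feature: ML diverges and is flagged
  xsep <- matrix(c(1:10, 21:30), ncol = 1, dimnames = list(NULL, "x"))
  fit_sep <- fit_logistic(xsep, y, penalty = 0)
  expect_false(fit_sep$converged)
  fit_ridge <- fit_logistic(xsep, y, penalty = 1e-2)
  expect_true(is.finite(fit_ridge$coefficients["x"]))
  expect_error(fit_logistic(xsep, rep("a", 20)), "2 classes")
  expect_error(fit_logistic(xsep, c("a", rep("b", 19))), ">= 2 samples")
})

test_that("coefficients are recovered within 3 SEs on simulated data", {
  beta0 <- -0.3; beta <- c(0.8, -1.2)
  d <- sim_logistic(2000, beta0, beta, seed = 2)
  fit <- fit_logistic(d$X, d$y, positive_class = "pos")
  ref <- glm(I(d$y == "pos") ~ d$X, family = binomial())
  se <- sqrt(diag(vcov(ref)))
  est <- c(fit$intercept, fit$coefficients)
  expect_true(all(abs(est - c(beta0, beta)) < 3 * se))
})

test_that("estimator bias shrinks as n grows", {
  beta <- c(1, -1)
  bias_at <- function(n) {
    errs <- vapply(1:5, function(i) {
      d <- sim_logistic(n, 0, beta, seed = 100 * n + i)
      f <- fit_logistic(d$X, d$y, positive_class = "pos")
      sum(abs(f$coefficients - beta))
    }, numeric(1))
    mean(errs)
  }
  expect_lt(bias_at(5000), bias_at(500))
})

test_that("forward stepwise keeps signal and drops noise", {
  d <- sim_logistic(500, 0, c(1.5), seed = 1)
  X <- cbind(d$X, noise = rnorm(500))
  colnames(X) <- c("signal", "noise")
  for (crit in c("aic", "lrt_p")) {
    fit <- stepwise_select(X, d$y, criterion = crit,
                           positive_class = "pos")
    expect_equal(names(fit$coefficients), "signal")
    expect_gt(length(fit$selection_trace), 0)
  }
  # no informative feature: intercept-only
  Xnull <- matrix(rnorm(400), 200, 2, dimnames = list(NULL, c("a", "b")))
  ynull <- rep(c("pos", "neg"), 100)
  fit0 <- stepwise_select(Xnull, ynull, positive_class = "pos")
  expect_equal(length(fit0$coefficients), 0)
  # all features informative and independent: all selected
  d3 <- sim_logistic(1500, 0, c(1.5, -1.5, 1.2), seed = 5)
  fit3 <- stepwise_select(d3$X, d3$y, positive_class = "pos")
  expect_setequal(names(fit3$coefficients), c("x1", "x2", "x3"))
})

test_that("predicted probabilities follow the logistic closed form", {
  m0 <- fit_logistic(matrix(0, 10, 1, dimnames = list(NULL, "z")),
                     rep(c("a", "b"), 5))
  m0$coefficients <- numeric(0)  # intercept-only view
  m0$intercept <- 0
  expect_equal(predict_prob(m0, matrix(rnorm(5), 5, 1,
                                       dimnames = list(NULL, "z"))),
               rep(0.5, 5))
  # printed-intercept check: logistic(-0.634) with all markers at zero
  m <- m0; m$intercept <- -0.634
  m$coefficients <- c(mk1 = 13.701, mk2 = -230.17, mk3 = -512.468)
  feats <- matrix(0, 1, 3, dimnames = list(NULL, c("mk1", "mk2", "mk3")))
  expect_equal(predict_prob(m, feats), plogis(-0.634))
  expect_equal(predict_prob(m, feats), 0.3466, tolerance = 1e-3)
  # large positive score saturates to 1
  feats2 <- matrix(c(1000, 0, 0), 1, 3,
                   dimnames = list(NULL, c("mk1", "mk2", "mk3")))
  expect_equal(predict_prob(m, feats2), 1)
  expect_error(predict_prob(m, feats[, 1:2, drop = FALSE]), "mk3")
})

test_that("ROC handles separation, ties and the worked example", {
  expect_equal(roc_auc(c(1, 2, 3, 11, 12), rep(c("n", "p"), c(3, 2)))$auc,
               1)
  expect_equal(roc_auc(rep(5, 10), rep(c("n", "p"), 5))$auc, 0.5)
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c("n", "n", "p", "p"),
               positive_class = "p")
  expect_equal(r$auc, 0.75)
  expect_true(!is.unsorted(r$fpr) && !is.unsorted(r$tpr))
  expect_error(roc_auc(1:4, rep("p", 4)), "both classes")
})

test_that("trapezoidal AUC equals the normalized Mann-Whitney U", {
  set.seed(6)
  for (rep in 1:25) {
    n <- sample(10:50, 1)
    scores <- sample(1:8, n, replace = TRUE)  # heavy ties
    labels <- sample(c("n", "p"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    auc <- roc_auc(scores, labels, positive_class = "p")$auc
    expect_equal(auc, oracle_auc(scores, labels, "p"), tolerance = 1e-12)
    # label flip antisymmetry and monotone-transform invariance
    expect_equal(roc_auc(scores, labels, positive_class = "n")$auc,
                 1 - auc, tolerance = 1e-12)
    expect_equal(roc_auc(exp(scores / 2), labels,
                         positive_class = "p")$auc, auc,
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  set.seed(7)
  scores <- rnorm(60)
  labels <- rep(c("n", "p"), 30)
  scores[labels == "p"] <- scores[labels == "p"] + 1
  expect_equal(roc_auc(scores, labels, positive_class = "p")$auc,
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              levels = c("n", "p"),
                                              direction = "<",
                                              quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("bootstrap CI is deterministic, degenerate on separation, sane", {
  scores <- c(1:10, 21:30)
  labels <- rep(c("n", "p"), each = 10)
  ci <- auc_bootstrap_ci(scores, labels, positive_class = "p",
                         n_boot = 200, seed = 8)
  expect_equal(ci, c(1, 1))
  set.seed(9)
  s2 <- rnorm(40); l2 <- rep(c("n", "p"), 20)
  s2[l2 == "p"] <- s2[l2 == "p"] + 1
  ci_a <- auc_bootstrap_ci(s2, l2, n_boot = 300, seed = 10)
  ci_b <- auc_bootstrap_ci(s2, l2, n_boot = 300, seed = 10)
  expect_identical(ci_a, ci_b)
  auc <- roc_auc(s2, l2, positive_class = "p")$auc
  expect_lte(ci_a[1], auc); expect_gte(ci_a[2], auc)
  expect_error(auc_bootstrap_ci(s2, l2, n_boot = 50, seed = 1), "100")
  roc <- roc_auc(s2, l2, ci = TRUE, n_boot = 300, seed = 10)
  expect_equal(c(roc$ci_low, roc$ci_high), ci_a)
})

test_that("bootstrap interval covers a known AUC at roughly nominal rate", {
  # reduced replication: 20 outer draws from a shifted-normal model whose
  # true AUC is pnorm(1/sqrt(2)) ~ 0.760
  true_auc <- pnorm(1 / sqrt(2))
  covered <- vapply(1:20, function(i) {
    set.seed(400 + i)
    s <- rnorm(120); l <- rep(c("n", "p"), 60)
    s[l == "p"] <- s[l == "p"] + 1
    ci <- auc_bootstrap_ci(s, l, n_boot = 200, seed = i)
    ci[1] <= true_auc && true_auc <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.8)
})

test_that("delta-delta-Ct quantification matches its defining identities", {
  ct <- data.frame(sample_id = c("s1", "s2", "s3", "s4"),
                   class = c("classA", "classA", "classB", "classB"),
                   gene = "g",
                   ct_target = c(20, 21, 24, 25),
                   ct_reference = c(18, 18, 18, 18))
  rq <- ddct_relative_expression(ct, calibrator = "classB")
  # calibrator mean dCt = 6.5; a calibrator sample at the mean has RQ 1
  expect_equal(rq$delta_delta_ct[3], -0.5)
  expect_equal(rq$rel_expr, 2^(-rq$delta_delta_ct))
  ct2 <- ct; ct2$ct_target <- c(17.5, 17.5, 18.5, 18.5)
  rq2 <- ddct_relative_expression(ct2, calibrator = "classB")
  expect_equal(rq2$rel_expr[1], 2)            # ddCt = -1 -> RQ 2
  expect_equal(rq2$rel_expr[3], 1)            # at calibrator mean -> RQ 1
  expect_true(all(rq2$rel_expr > 0))
  ct3 <- ct; ct3$ct_reference[2] <- NA
  expect_error(ddct_relative_expression(ct3), "s2")
  expect_error(ddct_relative_expression(ct, calibrator = "classC"),
               "classC")
})
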