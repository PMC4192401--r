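#' Per-gene two-sample t-test
#'
#' Two-sided t-test of every gene between two sample classes, vectorized
#' over rows. The Welch variant (unequal variances, Satterthwaite degrees
#' of freedom) is the default, matching R's own `t.test()`; the pooled
#' Student variant is available by flag.
#'
#' Degenerate rows follow the usual conventions: when both groups have
#' zero variance and equal means the p-value is 1; zero variance with
#' unequal means gives p = 0 (infinite t).
#'
#' @param x An [expr_matrix()] on the log2 scale.
#' @param group_a,group_b Class labels to contrast (each with >= 2
#'   samples).
#' @param variant `"welch"` (default) or `"student"`.
#' @return Named numeric vector of two-sided p-values, one per gene.
#' @export
gene_t_test <- function(x, group_a, group_b,
                        variant = c("welch", "student")) {
  stopifnot(inherits(x, "expr_matrix"))
  variant <- match.arg(variant)
  a <- x$values[, class_samples(x, group_a), drop = FALSE]
  b <- x$values[, class_samples(x, group_b), drop = FALSE]
  n1 <- ncol(a); n2 <- ncol(b)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs >= 2 samples (got ", n1, " and ", n2, ")",
         call. = FALSE)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- rowSums((a - m1)^2) / (n1 - 1)
  v2 <- rowSums((b - m2)^2) / (n2 - 1)
  if (variant == "welch") {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(se2))
  }
  tstat <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  # zero variance in both groups: p = 1 on equal means, 0 otherwise
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  stats::setNames(p, rownames(x$values))
}

#' Select differentially expressed genes for one contrast
#'
#' A gene is a DEG when its fold change satisfies
#' `fold_change >= fc_threshold` or `fold_change <= 1/fc_threshold`
#' (equivalently |log2 FC| >= log2 of the threshold) *and* its t-test
#' p-value is below `p_threshold`. Fold change is the ratio of geometric
#' means, computed as 2^(difference of log2 group means). No
#' multiple-testing correction is applied by default (raw p < 0.05);
#' Benjamini-Hochberg is available via `adjust = "BH"`.
#'
#' @inheritParams gene_t_test
#' @param fc_threshold Fold-change threshold >= 1, default 2.
#' @param p_threshold P-value threshold in (0, 1), default 0.05.
#' @param adjust `"none"` (default) or `"BH"`; with BH the threshold is
#'   applied to the adjusted p-values.
#' @return Data frame of DEG records: `gene_id`, `log2_fc` (group_a minus
#'   group_b), `fold_change`, `p_value`, `direction` (`"up"` iff
#'   log2_fc > 0, relative to `group_a`), `contrast`.
#' @export
select_degs <- function(x, group_a, group_b, fc_threshold = 2,
                        p_threshold = 0.05,
                        variant = c("welch", "student"),
                        adjust = c("none", "BH")) {
  stopifnot(fc_threshold >= 1, p_threshold > 0, p_threshold <= 1)
  adjust <- match.arg(adjust)
  p <- gene_t_test(x, group_a, group_b, variant)
  p_sel <- if (adjust == "BH") stats::p.adjust(p, "BH") else p
  lfc <- rowMeans(x$values[, class_samples(x, group_a), drop = FALSE]) -
    rowMeans(x$values[, class_samples(x, group_b), drop = FALSE])
  keep <- abs(lfc) >= log2(fc_threshold) & p_sel < p_threshold
  out <- data.frame(gene_id = names(p)[keep],
                    log2_fc = unname(lfc[keep]),
                    fold_change = 2^unname(lfc[keep]),
                    p_value = unname(p[keep]),
                    direction = ifelse(lfc[keep] > 0, "up", "down"),
                    contrast = rep(paste0(group_a, "_vs_", group_b),
                                   sum(keep)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Two-step differential-expression selection
#'
#' The study design compares each patient class against the shared control
#' arm first, then the two classes against each other. The final DEG set
#' is the class-A-vs-class-B DEGs restricted to genes that also passed the
#' control step; how the two control-step sets are combined is a recorded
#' parameter (`"union"` by default).
#'
#' @inheritParams select_degs
#' @param control_label,a_label,b_label The three class labels.
#' @param control_logic How the two x-vs-control DEG sets gate the final
#'   contrast: `"union"`, `"intersection"`, `"a_only"`, `"b_only"`.
#' @return DEG data frame for the a-vs-b contrast (see [select_degs()]),
#'   restricted to the control-step gate, with a `meta` attribute
#'   recording per-step counts, thresholds and the set logic used.
#' @export
two_step_degs <- function(x, control_label = "control",
                          a_label = "classA", b_label = "classB",
                          fc_threshold = 2, p_threshold = 0.05,
                          variant = c("welch", "student"),
                          control_logic = c("union", "intersection",
                                            "a_only", "b_only")) {
  control_logic <- match.arg(control_logic)
  variant <- match.arg(variant)
  for (lab in c(control_label, a_label, b_label)) class_samples(x, lab)
  deg_a <- select_degs(x, a_label, control_label, fc_threshold,
                       p_threshold, variant)
  deg_b <- select_degs(x, b_label, control_label, fc_threshold,
                       p_threshold, variant)
  deg_ab <- select_degs(x, a_label, b_label, fc_threshold, p_threshold,
                        variant)
  gate <- switch(control_logic,
                 union = union(deg_a$gene_id, deg_b$gene_id),
                 intersection = intersect(deg_a$gene_id, deg_b$gene_id),
                 a_only = deg_a$gene_id,
                 b_only = deg_b$gene_id)
  out <- deg_ab[deg_ab$gene_id %in% gate, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "meta") <- list(
    n_a_vs_control = nrow(deg_a), n_b_vs_control = nrow(deg_b),
    n_a_vs_b = nrow(deg_ab), n_final = nrow(out),
    control_logic = control_logic, fc_threshold = fc_threshold,
    p_threshold = p_threshold, variant = variant)
  out
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two groups. The U statistic for group a is
#' computed from midranks, so tied cross-group pairs contribute 0.5. The
#' p-value is exact (network algorithm) when the smaller group has at most
#' 8 observations and there are no ties, and otherwise uses the normal
#' approximation with the tie-correction term; two identical samples give
#' p = 1 by that convention.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @return List with `U` (for group a) and `p_value` (two-sided).
#' @export
mann_whitney <- function(values_a, values_b) {
  if (length(values_a) == 0L || length(values_b) == 0L)
    stop("both groups must be non-empty", call. = FALSE)
  n1 <- length(values_a); n2 <- length(values_b)
  r <- rank(c(values_a, values_b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  has_ties <- anyDuplicated(c(values_a, values_b)) > 0
  if (!has_ties && min(n1, n2) <= 8) {
    p <- stats::wilcox.test(values_a, values_b, exact = TRUE)$p.value
  } else {
    ties <- table(c(values_a, values_b))
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - n1 * n2 / 2) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
  }
  list(U = U, p_value = p)
}

#' Hierarchical clustering of genes or samples
#'
#' Agglomerative clustering for the heatmap view, over rows (genes) or
#' columns (samples), with correlation (`1 - Pearson r`) or Euclidean
#' distance and average or complete linkage. Returns the standard
#' `hclust` object (merge list, heights, leaf order).
#'
#' @param x An [expr_matrix()] or numeric matrix.
#' @param axis `"rows"` or `"columns"`.
#' @param distance `"one_minus_pearson"` or `"euclidean"`.
#' @param linkage `"average"` or `"complete"`.
#' @return An object of class `hclust`.
#' @seealso [dendrogram_newick()] for Newick export.
#' @export
hierarchical_cluster <- function(x, axis = c("rows", "columns"),
                                 distance = c("one_minus_pearson",
                                              "euclidean"),
                                 linkage = c("average", "complete")) {
  axis <- match.arg(axis); distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  m <- if (inherits(x, "expr_matrix")) x$values else x
  if (axis == "columns") m <- t(m)
  if (nrow(m) < 2L)
    stop("need >= 2 items on the clustered axis", call. = FALSE)
  if (distance == "one_minus_pearson") {
    sds <- apply(m, 1, stats::sd)
    if (any(sds == 0))
      stop("correlation distance undefined for constant row '",
           rownames(m)[which(sds == 0)[1]], "'", call. = FALSE)
    d <- stats::as.dist(1 - stats::cor(t(m)))
  } else {
    d <- stats::dist(m)
  }
  stats::hclust(d, method = linkage)
}

#' Export a dendrogram as a Newick string
#'
#' @param hc An `hclust` object from [hierarchical_cluster()].
#' @return Single Newick string (with branch lengths from merge heights).
#' @export
dendrogram_newick <- function(hc) {
  stopifnot(inherits(hc, "hclust"))
  ape::write.tree(ape::as.phylo(hc))
}
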