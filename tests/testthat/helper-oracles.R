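# Independent brute-force oracles and small fixture builders used across
# the suite. Everything here is deliberately naive (triple loops, full
# enumeration) so it stays independent of the package's code paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Erdos-Renyi-style random edge list over n named nodes
random_edge_df <- function(n, p_edge) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- t(utils::combn(nodes, 2))
  keep <- stats::runif(nrow(pairs)) < p_edge
  data.frame(gene_a = pairs[keep, 1], gene_b = pairs[keep, 2],
             stringsAsFactors = FALSE)
}

# adjacency matrix of a coexpression_network
adjacency_of <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n, dimnames = list(net$nodes, net$nodes))
  for (i in seq_len(nrow(net$edges))) {
    A[net$edges$gene_a[i], net$edges$gene_b[i]] <- 1L
    A[net$edges$gene_b[i], net$edges$gene_a[i]] <- 1L
  }
  A
}

# brute-force degree and local clustering coefficient from the adjacency
oracle_degree <- function(A, v) sum(A[v, ])

oracle_cc <- function(A, v) {
  nb <- names(which(A[v, ] == 1L))
  k <- length(nb)
  if (k < 2) return(0)
  links <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    links <- links + A[nb[i], nb[j]]
  2 * links / (k * (k - 1))
}

# brute-force Mann-Whitney U for group a with half credit for ties
oracle_U <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  us <- apply(idx, 2, function(i) oracle_U(pooled[i], pooled[-i]))
  u_obs <- oracle_U(a, b)
  mu <- n1 * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# brute-force AUC by pair counting with half credit for ties
oracle_auc <- function(scores, labels, positive) {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  oracle_U(sp, sn) / (length(sp) * length(sn))
}

# a star network: `center` joined to k numbered leaves
star_network <- function(center, k, class_label = "class",
                         prefix = "leaf") {
  if (k == 0)
    return(coexpression_network(
      data.frame(gene_a = character(), gene_b = character()),
      nodes = center, class_label = class_label))
  coexpression_network(
    data.frame(gene_a = center, gene_b = paste0(prefix, seq_len(k)),
               stringsAsFactors = FALSE),
    class_label = class_label)
}

# small deterministic expression matrix with given class means and noise
toy_expr <- function(gene_means, n_per_class = 5, noise_sd = 0.01,
                     classes = c("classA", "classB", "control"),
                     seed = 7) {
  # gene_means: genes x classes matrix of log2 means
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    cols <- NULL
    vals <- NULL
    for (cl in classes) {
      m <- gene_means[, cl, drop = TRUE]
      block <- matrix(stats::rnorm(length(m) * n_per_class, mean = m,
                                   sd = noise_sd),
                      nrow = length(m))
      vals <- cbind(vals, block)
      cols <- c(cols, paste0(cl, "_", seq_len(n_per_class)))
    }
    rownames(vals) <- rownames(gene_means)
    colnames(vals) <- cols
    expr_matrix(vals, setNames(rep(classes, each = n_per_class), cols))
  })
}
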