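#' Construct a co-expression network object
#'
#' Low-level constructor for the per-class network container. Edges are
#' undirected and stored once with the two endpoints in lexicographic
#' order; self-edges are rejected; the stored sign is the sign of the
#' correlation. Most users build networks from data with
#' [build_network()] — this constructor mainly serves programmatic graph
#' assembly.
#'
#' @param edges Data frame with columns `gene_a`, `gene_b` and optionally
#'   `r`, `p` (defaults `r = 1`, `p = 0`). Zero-row input allowed.
#' @param nodes Character vector of node names; defaults to the genes
#'   appearing in `edges`, but may include isolated nodes.
#' @param class_label Label of the sample class the network describes.
#' @param params Named list of construction parameters stored as
#'   provenance metadata.
#' @return An object of class `coexpression_network`.
#' @export
coexpression_network <- function(edges, nodes = NULL,
                                 class_label = "class", params = list()) {
  if (nrow(edges) > 0L) {
    if (!all(c("gene_a", "gene_b") %in% names(edges)))
      stop("`edges` needs columns gene_a, gene_b", call. = FALSE)
    if (is.null(edges$r)) edges$r <- 1
    if (is.null(edges$p)) edges$p <- 0
    if (any(edges$gene_a == edges$gene_b))
      stop("self-edges are not allowed", call. = FALSE)
    swap <- edges$gene_a > edges$gene_b
    tmp <- edges$gene_a[swap]
    edges$gene_a[swap] <- edges$gene_b[swap]
    edges$gene_b[swap] <- tmp
    if (anyDuplicated(edges[c("gene_a", "gene_b")]))
      stop("duplicate edge", call. = FALSE)
    edges$sign <- ifelse(edges$r >= 0, "positive", "negative")
    edges <- edges[c("gene_a", "gene_b", "r", "p", "sign")]
  } else {
    edges <- data.frame(gene_a = character(), gene_b = character(),
                        r = numeric(), p = numeric(), sign = character(),
                        stringsAsFactors = FALSE)
  }
  nodes <- sort(unique(c(nodes, edges$gene_a, edges$gene_b)))
  rownames(edges) <- NULL
  structure(list(class_label = class_label, nodes = nodes, edges = edges,
                 params = params),
            class = "coexpression_network")
}

#' @export
print.coexpression_network <- function(x, ...) {
  cat("coexpression_network [", x$class_label, "]: ", length(x$nodes),
      " nodes, ", nrow(x$edges), " edges (",
      sum(x$edges$sign == "negative"), " negative)\n", sep = "")
  invisible(x)
}

#' Build a class-specific co-expression network
#'
#' For every pair of the given genes, the Pearson correlation over the
#' samples of one class is computed together with the two-sided p-value of
#' the correlation t-test (df = n - 2). An edge joins a pair when
#' `|r| >= r_threshold` *and* `p < p_threshold`; negative correlations
#' form (negatively signed) edges too. Genes that are constant within the
#' class have undefined correlations and are excluded from the node set
#' with a warning. Genes with no passing edge remain as isolated nodes
#' (degree 0), so they are still scored by [delta_degree()].
#'
#' @param x An [expr_matrix()].
#' @param class_label Class whose samples define the network (>= 3
#'   samples, since the correlation test needs df = n - 2 >= 1).
#' @param genes Genes over which to build the network, typically the DEG
#'   set; default all genes of `x`.
#' @param r_threshold Absolute-correlation threshold in (0, 1], default
#'   0.8.
#' @param p_threshold Correlation-test p threshold, default 0.05.
#' @return A [coexpression_network()] with the thresholds, class and
#'   sample size recorded in `$params`.
#' @export
build_network <- function(x, class_label, genes = rownames(x$values),
                          r_threshold = 0.8, p_threshold = 0.05) {
  stopifnot(inherits(x, "expr_matrix"))
  if (r_threshold <= 0 || r_threshold > 1)
    stop("`r_threshold` must be in (0, 1]", call. = FALSE)
  absent <- setdiff(genes, rownames(x$values))
  if (length(absent) > 0L)
    stop("gene(s) not in matrix: ",
         paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
  samples <- class_samples(x, class_label)
  n <- length(samples)
  if (n < 3L)
    stop("class '", class_label, "' has ", n,
         " samples; correlation networks need >= 3", call. = FALSE)
  m <- x$values[genes, samples, drop = FALSE]
  const <- apply(m, 1, function(v) stats::var(v) == 0)
  if (any(const)) {
    warning("excluding ", sum(const),
            " constant gene(s) with undefined correlation: ",
            paste(utils::head(genes[const], 5), collapse = ", "),
            call. = FALSE)
    m <- m[!const, , drop = FALSE]
  }
  keep_genes <- rownames(m)
  edges <- data.frame(gene_a = character(), gene_b = character(),
                      r = numeric(), p = numeric())
  if (nrow(m) >= 2L) {
    cmat <- stats::cor(t(m))
    df <- n - 2
    ut <- which(upper.tri(cmat), arr.ind = TRUE)
    r <- cmat[ut]
    # guard |r| = 1: t is infinite, p = 0
    tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
    pass <- abs(r) >= r_threshold & p < p_threshold
    edges <- data.frame(gene_a = keep_genes[ut[pass, 1]],
                        gene_b = keep_genes[ut[pass, 2]],
                        r = r[pass], p = p[pass],
                        stringsAsFactors = FALSE)
  }
  coexpression_network(edges, nodes = keep_genes,
                       class_label = class_label,
                       params = list(r_threshold = r_threshold,
                                     p_threshold = p_threshold,
                                     n_samples = n))
}

# named degree vector over all nodes
node_degrees <- function(network) {
  deg <- stats::setNames(integer(length(network$nodes)), network$nodes)
  if (nrow(network$edges) > 0L) {
    tab <- table(c(network$edges$gene_a, network$edges$gene_b))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Degree centrality of a gene
#'
#' The number of edges incident to the gene in the network.
#'
#' @param network A [coexpression_network()].
#' @param gene Gene identifier; must be a node of the network.
#' @return Integer degree.
#' @export
degree_centrality <- function(network, gene) {
  stopifnot(inherits(network, "coexpression_network"))
  if (!gene %in% network$nodes)
    stop("gene '", gene, "' is not a node of the network", call. = FALSE)
  unname(node_degrees(network)[gene])
}

#' Local clustering coefficient of a gene
#'
#' The fraction of the gene's neighbor pairs that are themselves
#' connected: `2 * E_N / (k * (k - 1))` with `k` the degree and `E_N` the
#' number of edges among the neighbors. Edge signs are ignored. Nodes with
#' degree below 2 have coefficient 0 by convention.
#'
#' @inheritParams degree_centrality
#' @return Real value in [0, 1].
#' @export
clustering_coefficient <- function(network, gene) {
  stopifnot(inherits(network, "coexpression_network"))
  if (!gene %in% network$nodes)
    stop("gene '", gene, "' is not a node of the network", call. = FALSE)
  e <- network$edges
  nb <- c(e$gene_b[e$gene_a == gene], e$gene_a[e$gene_b == gene])
  k <- length(nb)
  if (k < 2L) return(0)
  among <- sum(e$gene_a %in% nb & e$gene_b %in% nb)
  2 * among / (k * (k - 1))
}

#' Degree and clustering coefficient for every node
#'
#' @param network A [coexpression_network()].
#' @return Data frame with columns `gene_id`, `degree`,
#'   `clustering_coefficient`, one row per node.
#' @export
node_metrics <- function(network) {
  stopifnot(inherits(network, "coexpression_network"))
  deg <- node_degrees(network)
  cc <- vapply(network$nodes, clustering_coefficient,
               numeric(1), network = network)
  data.frame(gene_id = network$nodes, degree = unname(deg),
             clustering_coefficient = unname(cc),
             stringsAsFactors = FALSE)
}

#' Locate differential co-expression candidates
#'
#' Genes that are well-connected, locally clustered hubs — degree at or
#' above `degree_min` and clustering coefficient at or above `cc_min` —
#' in *at least one* of the two class networks. A one-network filter is
#' required because a differential hub is, by definition, nearly isolated
#' in the other class's network. The qualifying network(s) are recorded.
#'
#' @param net_a,net_b The two class [coexpression_network()]s.
#' @param degree_min Minimum degree, default 10.
#' @param cc_min Minimum clustering coefficient, default 0.2.
#' @return Data frame with columns `gene_id`, `in_a`, `in_b` (logical:
#'   passed the filter in that network), sorted by `gene_id`.
#' @export
locate_candidates <- function(net_a, net_b, degree_min = 10,
                              cc_min = 0.2) {
  qual <- function(net) {
    nm <- node_metrics(net)
    nm$gene_id[nm$degree >= degree_min &
                 nm$clustering_coefficient >= cc_min]
  }
  qa <- qual(net_a); qb <- qual(net_b)
  genes <- sort(union(qa, qb))
  data.frame(gene_id = genes, in_a = genes %in% qa, in_b = genes %in% qb,
             stringsAsFactors = FALSE)
}

#' Between-class degree difference of a gene
#'
#' The core-gene selection statistic: the absolute difference of a gene's
#' degrees in the two class networks. A gene absent from a network's node
#' set contributes degree 0, so near-isolated genes are still scored. The
#' statistic is symmetric in the two networks.
#'
#' @param gene Gene identifier (vectorized).
#' @param net_a,net_b The two class [coexpression_network()]s.
#' @return Non-negative integer(s) `|degree_a - degree_b|`.
#' @export
delta_degree <- function(gene, net_a, net_b) {
  da <- node_degrees(net_a); db <- node_degrees(net_b)
  get0 <- function(deg, g) ifelse(is.na(deg[g]), 0L, deg[g])
  abs(unname(get0(da, gene)) - unname(get0(db, gene)))
}

#' Select core genes by degree difference
#'
#' Ranks candidate differential co-expression genes by their
#' between-class degree difference and keeps those with
#' `delta_degree >= ddeg_min`. Ordering is degree difference descending,
#' ties broken by the larger of the two degrees descending, then gene id
#' ascending.
#'
#' @param candidates Candidate genes: a character vector or the data
#'   frame returned by [locate_candidates()].
#' @param net_a,net_b The two class [coexpression_network()]s.
#' @param ddeg_min Minimum degree difference, default 8.
#' @param de_records Optional DEG data frame (see [select_degs()]) used to
#'   annotate each core gene's regulation style (`up`/`down`).
#' @param descriptions Optional named character vector of gene
#'   descriptions.
#' @return Data frame of core-gene records: `gene_id`, `description`,
#'   `style`, `degree_a`, `degree_b`, `delta_degree`, ranked as above.
#' @export
select_core_genes <- function(candidates, net_a, net_b, ddeg_min = 8,
                              de_records = NULL, descriptions = NULL) {
  genes <- if (is.data.frame(candidates)) candidates$gene_id
           else as.character(candidates)
  if (length(genes) == 0L)
    return(data.frame(gene_id = character(), description = character(),
                      style = character(), degree_a = integer(),
                      degree_b = integer(), delta_degree = integer(),
                      stringsAsFactors = FALSE))
  da <- node_degrees(net_a); db <- node_degrees(net_b)
  deg_a <- ifelse(is.na(da[genes]), 0L, da[genes])
  deg_b <- ifelse(is.na(db[genes]), 0L, db[genes])
  dd <- abs(deg_a - deg_b)
  style <- rep(NA_character_, length(genes))
  if (!is.null(de_records))
    style <- de_records$direction[match(genes, de_records$gene_id)]
  desc <- rep("", length(genes))
  if (!is.null(descriptions)) {
    hit <- genes %in% names(descriptions)
    desc[hit] <- descriptions[genes[hit]]
  }
  out <- data.frame(gene_id = genes, description = desc, style = style,
                    degree_a = as.integer(deg_a),
                    degree_b = as.integer(deg_b),
                    delta_degree = as.integer(dd),
                    stringsAsFactors = FALSE)
  out <- out[out$delta_degree >= ddeg_min, , drop = FALSE]
  ord <- order(-out$delta_degree, -pmax(out$degree_a, out$degree_b),
               out$gene_id)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# igraph view of a network (used for GraphML export and cross-checks)
as_igraph <- function(network) {
  stopifnot(inherits(network, "coexpression_network"))
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$nodes)
}
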