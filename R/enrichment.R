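#' Build a gene-set collection
#'
#' @param sets Named list of character vectors (term id -> genes).
#' @param background Character vector: the gene universe. Set genes
#'   outside the background are dropped with a warning; sets left empty
#'   are removed.
#' @param term_names Optional named character vector of human-readable
#'   term names (defaults to the term ids).
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(sets, background, term_names = NULL) {
  if (length(sets) == 0L || is.null(names(sets)))
    stop("`sets` must be a non-empty named list", call. = FALSE)
  background <- unique(as.character(background))
  cleaned <- lapply(sets, function(g) intersect(unique(g), background))
  dropped <- sum(lengths(sets)) - sum(lengths(cleaned))
  if (dropped > 0L)
    warning(dropped, " set gene(s) outside the background were dropped",
            call. = FALSE)
  keep <- lengths(cleaned) > 0L
  if (!all(keep))
    warning(sum(!keep), " empty set(s) removed", call. = FALSE)
  cleaned <- cleaned[keep]
  if (is.null(term_names))
    term_names <- stats::setNames(names(cleaned), names(cleaned))
  structure(list(sets = cleaned,
                 term_names = term_names[names(cleaned)],
                 background = background),
            class = "gene_set_collection")
}

#' Read gene sets from a GMT file
#'
#' The GMT dialect: one tab-separated line per set — term id, description,
#' then member genes.
#'
#' @param path Path to the GMT file.
#' @param background Gene universe for [gene_set_collection()]; defaults
#'   to the union of all set genes.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L)
    stop("malformed GMT line ", bad[1], ": fewer than 3 fields",
         call. = FALSE)
  ids <- vapply(parts, `[[`, character(1), 1L)
  descs <- vapply(parts, `[[`, character(1), 2L)
  sets <- stats::setNames(lapply(parts, function(p) p[-(1:2)]), ids)
  if (is.null(background)) background <- unique(unlist(sets))
  gene_set_collection(sets, background, stats::setNames(descs, ids))
}

#' Hypergeometric over-representation analysis
#'
#' Tests a gene list for enrichment in each set of a collection with the
#' upper-tail hypergeometric test, `P(X >= k)` for `k` hits out of a list
#' of `n` genes against a set of size `K` in a background of `N`
#' (equivalently Fisher's exact test, one-sided). Results carry
#' `-log10(p)` and the Benjamini-Hochberg FDR across the tested terms,
#' sorted by p ascending with ties broken by term id. The EASE variant
#' (testing with `k - 1` hits, a conservative adjustment used by some
#' annotation servers) is available by flag.
#'
#' @param gene_list Character vector of genes of interest. Genes outside
#'   the collection's background are dropped with a warning.
#' @param collection A [gene_set_collection()].
#' @param ease If `TRUE`, apply the EASE adjustment (score `k - 1`).
#' @return Data frame of enrichment records: `term_id`, `term_name`, `k`,
#'   `K`, `n`, `N`, `p_value`, `neg_log10_p`, `bh_fdr`.
#' @export
hypergeom_enrich <- function(gene_list, collection, ease = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  gene_list <- unique(as.character(gene_list))
  outside <- setdiff(gene_list, collection$background)
  if (length(outside) > 0L) {
    warning(length(outside), " list gene(s) outside the background ",
            "were dropped", call. = FALSE)
    gene_list <- setdiff(gene_list, outside)
  }
  if (length(gene_list) == 0L)
    stop("no gene of the list is in the background", call. = FALSE)
  N <- length(collection$background)
  n <- length(gene_list)
  k <- vapply(collection$sets,
              function(s) length(intersect(s, gene_list)), integer(1))
  K <- lengths(collection$sets)
  q <- if (ease) pmax(k - 1L, 0L) else k
  # upper tail P(X >= q): phyper with lower.tail = FALSE is P(X > q - 1)
  p <- stats::phyper(q - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = names(collection$sets),
                    term_name = unname(collection$term_names),
                    k = unname(k), K = unname(K), n = n, N = N,
                    p_value = unname(p),
                    neg_log10_p = -log10(unname(p)),
                    bh_fdr = unname(stats::p.adjust(p, "BH")),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
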