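#' Read an expression matrix and its sample classes from TSV
#'
#' The canonical tabular layout: the matrix file has a header row of
#' sample ids and a first column of gene ids; the class file has two
#' columns `sample_id` and `class`. Both are tab-separated, UTF-8, '.'
#' decimal.
#'
#' @param path Path to the expression TSV.
#' @param class_path Path to the two-column sample-class TSV.
#' @return An [expr_matrix()].
#' @export
read_expression_tsv <- function(path, class_path) {
  nf <- utils::count.fields(path, sep = "\t", quote = "")
  if (length(unique(nf)) > 1L)
    stop("ragged row at line ", which(nf != nf[1])[1], " of ", path,
         call. = FALSE)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("expression file needs a gene column plus >= 1 sample",
         call. = FALSE)
  gene_ids <- as.character(tab[[1]])
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup) > 0L)
    stop("duplicate gene id '", dup[1], "' in ", path, call. = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m))
    stop("non-numeric expression values in ", path, call. = FALSE)
  rownames(m) <- gene_ids
  cls <- utils::read.delim(class_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% names(cls)))
    stop("class file needs columns sample_id, class", call. = FALSE)
  missing <- setdiff(colnames(m), cls$sample_id)
  if (length(missing) > 0L)
    stop("sample '", missing[1], "' has no class label in ", class_path,
         call. = FALSE)
  expr_matrix(m, stats::setNames(cls$class, cls$sample_id))
}

#' Write an expression matrix and its sample classes to TSV
#'
#' @param x An [expr_matrix()].
#' @param path Output path for the matrix TSV.
#' @param class_path Output path for the sample-class TSV.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(x, path, class_path) {
  stopifnot(inherits(x, "expr_matrix"))
  tab <- data.frame(gene_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(x$sample_class),
               class = unname(x$sample_class)),
    class_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a probe signal-noise table
#'
#' Columns: `probe_id`, `signal`, `noise`.
#' @param path TSV path.
#' @return Data frame (reader) or invisibly the path (writer).
#' @export
read_probe_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "signal", "noise") %in% names(tab)))
    stop("probe file needs columns probe_id, signal, noise", call. = FALSE)
  tab
}

#' @rdname read_probe_tsv
#' @param probes Probe data frame.
#' @export
write_probe_tsv <- function(probes, path) {
  utils::write.table(probes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write a qPCR Ct table
#'
#' Columns: `sample_id`, `class`, `gene`, `ct_target`, `ct_reference`.
#' @param path TSV path.
#' @export
read_ct_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class", "gene", "ct_target", "ct_reference")
  if (!all(need %in% names(tab)))
    stop("Ct file needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab
}

#' @rdname read_ct_tsv
#' @param ct Ct data frame.
#' @export
write_ct_tsv <- function(ct, path) {
  utils::write.table(ct, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a co-expression network
#'
#' Three dialects: an edge-list TSV (`gene_a`, `gene_b`, `r`, `p`,
#' `sign`) whose leading `#` comment lines record the construction
#' parameters; SIF (`gene_a  pos|neg  gene_b`, isolated nodes on bare
#' lines); and GraphML.
#'
#' @param network A [coexpression_network()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(network, path) {
  stopifnot(inherits(network, "coexpression_network"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# class_label=", network$class_label),
               vapply(names(network$params), function(k)
                 paste0("# ", k, "=", network$params[[k]]),
                 character(1))), con)
  utils::write.table(network$edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  params <- list()
  class_label <- "class"
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) {
      if (kv[1] == "class_label") class_label <- kv[2]
      else params[[kv[1]]] <- utils::type.convert(kv[2], as.is = TRUE)
    }
  }
  tab <- utils::read.delim(textConnection(grep("^#", lines,
                                               invert = TRUE,
                                               value = TRUE)),
                           stringsAsFactors = FALSE)
  coexpression_network(tab, class_label = class_label, params = params)
}

#' @rdname write_edge_list
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "coexpression_network"))
  e <- network$edges
  rel <- ifelse(e$sign == "positive", "pos", "neg")
  lines <- paste(e$gene_a, rel, e$gene_b, sep = "\t")
  isolated <- setdiff(network$nodes, c(e$gene_a, e$gene_b))
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(network, path) {
  igraph::write_graph(as_igraph(network), path, format = "graphml")
  invisible(path)
}

#' Write DEG records or core-gene records to TSV
#'
#' @param x Data frame from [select_degs()] / [two_step_degs()] or
#'   [select_core_genes()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_records_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
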