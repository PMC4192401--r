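#' Expression matrix with sample class labels
#'
#' The central container of the pipeline: a genes x samples numeric matrix
#' (log2 scale after preprocessing) together with a class label for every
#' sample. Classes are free-form strings; the pipeline conventionally uses
#' two patient classes (e.g. `"classA"`, `"classB"`) and a `"control"` arm.
#'
#' @param values Numeric matrix, genes in rows and samples in columns. Row
#'   names are gene identifiers, column names sample identifiers; both are
#'   required and must be unique.
#' @param sample_class Named character vector mapping every sample
#'   (column name of `values`) to its class label.
#' @return An object of class `expr_matrix`: a list with elements `values`
#'   and `sample_class` (reordered to match the columns of `values`).
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' em <- expr_matrix(m, setNames(rep(c("classA", "classB"), 2), colnames(m)))
#' em
#' @export
expr_matrix <- function(values, sample_class) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (nrow(values) > 0L &&
      (is.null(rownames(values)) || anyDuplicated(rownames(values))))
    stop("`values` must have unique row (gene) names", call. = FALSE)
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("`values` must have unique column (sample) names", call. = FALSE)
  if (anyNA(values))
    stop("`values` must not contain missing values", call. = FALSE)
  sample_class <- as.character(sample_class[colnames(values)])
  if (anyNA(sample_class)) {
    missing <- setdiff(colnames(values), names(sample_class))
    stop("no class label for sample(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  names(sample_class) <- colnames(values)
  structure(list(values = values, sample_class = sample_class),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix: ", nrow(x$values), " genes x ", ncol(x$values),
      " samples\n", sep = "")
  tab <- table(x$sample_class)
  cat("classes: ",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

# sample ids belonging to a class; errors if class absent
class_samples <- function(x, label) {
  ids <- names(x$sample_class)[x$sample_class == label]
  if (length(ids) == 0L)
    stop("class '", label, "' not present in expression matrix",
         call. = FALSE)
  ids
}

# subset helper keeping the class structure
subset_expr <- function(x, genes = rownames(x$values),
                        samples = colnames(x$values)) {
  expr_matrix(x$values[genes, samples, drop = FALSE],
              x$sample_class[samples])
}

# run an expression evaluating `code` under a local RNG state seeded by
# `seed`; the caller's .Random.seed is restored afterwards so no generator
# leaks global state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_old) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}
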