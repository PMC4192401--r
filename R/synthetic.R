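#' Configuration for the synthetic expression generator
#'
#' Describes a two-patient-class (plus control) study with planted
#' differential expression and class-specific co-expression modules. The
#' generative model on the log2 scale is
#' \deqn{x_{gs} = \mu + \beta_g 1[s \in A] + \lambda_g f_s 1[s \in
#'   \mathrm{active}] + \varepsilon_{gs},}
#' i.e. baseline + class effect + latent-module term + Gaussian noise.
#' A gene listed in `de_genes` with log2 effect `b` has class-A mean `b`
#' above class B (and control); a gene in a planted module loads on a
#' latent factor shared by all samples of the module's active class only,
#' which creates co-expression in that class's network and none in the
#' other.
#'
#' @param n_genes Number of genes (rows).
#' @param n_per_class Samples per class. Either a single count applied to
#'   `classA`, `classB` and `control`, or a named vector; classes with
#'   count 0 are omitted.
#' @param de_genes Data frame with columns `gene` (1-based index) and
#'   `log2_effect`, or `NULL` for none.
#' @param modules List of [planted_module()] objects.
#' @param noise_sd Standard deviation of the i.i.d. Gaussian noise on the
#'   log2 scale. Must be positive.
#' @param baseline_mean Log2-scale baseline intensity (default 8, a typical
#'   mid-range microarray intensity).
#' @param baseline_gene_sd Standard deviation of per-gene baseline levels
#'   around `baseline_mean` (default 1.5), giving the wide per-gene
#'   dynamic range seen on real arrays; set 0 for a flat baseline.
#' @param seed Integer seed; every generator call is reproducible given the
#'   config.
#' @return A `synthetic_config` object.
#' @seealso [generate_expression()], [generate_probe_table()],
#'   [generate_ct_table()]
#' @export
synthetic_config <- function(n_genes,
                             n_per_class,
                             de_genes = NULL,
                             modules = list(),
                             noise_sd = 0.5,
                             baseline_mean = 8,
                             baseline_gene_sd = 1.5,
                             seed = 1L) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop("invalid `n_genes`: must be a single count >= 1", call. = FALSE)
  n_genes <- as.integer(n_genes)
  if (is.null(names(n_per_class))) {
    if (length(n_per_class) != 1L)
      stop("invalid `n_per_class`: give one count or a named vector",
           call. = FALSE)
    n_per_class <- c(classA = n_per_class, classB = n_per_class,
                     control = n_per_class)
  }
  n_per_class <- vapply(n_per_class, as.integer, integer(1))
  n_per_class <- n_per_class[n_per_class > 0L]
  if (length(n_per_class) == 0L)
    stop("invalid `n_per_class`: at least one class must have samples",
         call. = FALSE)
  if (!is.null(de_genes)) {
    de_genes <- as.data.frame(de_genes)
    if (!all(c("gene", "log2_effect") %in% names(de_genes)))
      stop("invalid `de_genes`: need columns gene, log2_effect",
           call. = FALSE)
    if (any(de_genes$gene < 1 | de_genes$gene > n_genes))
      stop("invalid `de_genes`: gene index out of [1, n_genes]",
           call. = FALSE)
    if (!all(is.finite(de_genes$log2_effect)))
      stop("invalid `de_genes`: effect sizes must be finite", call. = FALSE)
  }
  for (m in modules) {
    if (!inherits(m, "planted_module"))
      stop("invalid `modules`: elements must be planted_module objects",
           call. = FALSE)
    if (any(m$gene_indices < 1 | m$gene_indices > n_genes))
      stop("invalid `modules`: gene index out of [1, n_genes]",
           call. = FALSE)
    if (!m$active_class %in% names(n_per_class))
      stop("invalid `modules`: active_class '", m$active_class,
           "' has no samples", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("invalid `noise_sd`: must be > 0", call. = FALSE)
  structure(list(n_genes = n_genes, n_per_class = n_per_class,
                 de_genes = de_genes, modules = modules,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 baseline_gene_sd = baseline_gene_sd,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' A planted co-expression module
#'
#' A set of genes that share a latent factor in exactly one class, so their
#' pairwise Pearson correlation in that class is
#' \eqn{\rho = \lambda^2 \sigma_f^2 / (\lambda^2 \sigma_f^2 +
#' \sigma_\varepsilon^2)} (for common loading \eqn{\lambda}) and ~0 in the
#' other class. This is the ground truth against which differential-hub
#' recovery is scored.
#'
#' @param gene_indices Integer vector of at least 3 gene indices.
#' @param active_class Class label in which the module is co-expressed.
#' @param latent_loading Per-gene loading on the shared factor; recycled to
#'   the module size. Default 1.
#' @param factor_sd Standard deviation of the latent factor. Default 1.
#' @return A `planted_module` object.
#' @export
planted_module <- function(gene_indices, active_class = "classA",
                           latent_loading = 1, factor_sd = 1) {
  gene_indices <- as.integer(gene_indices)
  if (length(gene_indices) < 3L)
    stop("invalid `gene_indices`: a module needs >= 3 genes", call. = FALSE)
  if (anyDuplicated(gene_indices))
    stop("invalid `gene_indices`: duplicated index", call. = FALSE)
  latent_loading <- rep_len(latent_loading, length(gene_indices))
  if (!all(is.finite(latent_loading)))
    stop("invalid `latent_loading`: must be finite", call. = FALSE)
  structure(list(gene_indices = gene_indices,
                 active_class = as.character(active_class),
                 latent_loading = latent_loading,
                 factor_sd = factor_sd),
            class = "planted_module")
}

#' Generate a synthetic expression matrix
#'
#' Draws a log2-scale genes x samples matrix under the model described in
#' [synthetic_config()]. Deterministic given the config (including its
#' seed).
#'
#' @param config A [synthetic_config()] object.
#' @return An [expr_matrix()] with genes `g1..gN` and samples named
#'   `<class>_<i>`.
#' @examples
#' cfg <- synthetic_config(50, n_per_class = c(classA = 5, classB = 5),
#'                         de_genes = data.frame(gene = 1, log2_effect = 3))
#' em <- generate_expression(cfg)
#' mean(em$values[1, em$sample_class == "classA"]) -
#'   mean(em$values[1, em$sample_class == "classB"])  # ~3
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  classes <- rep(names(config$n_per_class), config$n_per_class)
  n_samples <- length(classes)
  sample_ids <- paste0(classes, "_",
                       unlist(lapply(config$n_per_class, seq_len)))
  gene_ids <- paste0("g", seq_len(config$n_genes))
  with_seed(config$seed, {
    gene_baseline <- stats::rnorm(config$n_genes, config$baseline_mean,
                                  config$baseline_gene_sd)
    x <- gene_baseline +
      matrix(stats::rnorm(config$n_genes * n_samples,
                          sd = config$noise_sd),
             config$n_genes, n_samples,
             dimnames = list(gene_ids, sample_ids))
    if (!is.null(config$de_genes)) {
      a_cols <- classes == "classA"
      for (i in seq_len(nrow(config$de_genes)))
        x[config$de_genes$gene[i], a_cols] <-
          x[config$de_genes$gene[i], a_cols] + config$de_genes$log2_effect[i]
    }
    for (m in config$modules) {
      cols <- classes == m$active_class
      # centred within the class: the module perturbs the covariance
      # structure only, leaving planted class-mean effects calibrated
      f <- stats::rnorm(sum(cols), sd = m$factor_sd)
      f <- f - mean(f)
      x[m$gene_indices, cols] <- x[m$gene_indices, cols] +
        m$latent_loading %o% f
    }
    expr_matrix(x, stats::setNames(classes, sample_ids))
  })
}

#' Generate a raw probe signal/noise table
#'
#' Produces one signal and one noise value per probe such that exactly
#' `floor(snr_fraction_low * n_genes)` probes have signal-to-noise ratio
#' at or below 2 (and so are removed by [snr_filter()] at the default
#' threshold). Low-SNR probes get SNR drawn uniformly in [0.5, 2], the
#' rest in (2, 20].
#'
#' @param config A [synthetic_config()] object (supplies `n_genes` and the
#'   seed).
#' @param snr_fraction_low Proportion of probes in [0, 1] planted below or
#'   at the SNR = 2 boundary.
#' @return Data frame with columns `probe_id`, `signal`, `noise`.
#' @export
generate_probe_table <- function(config, snr_fraction_low = 0) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.numeric(snr_fraction_low) || snr_fraction_low < 0 ||
      snr_fraction_low > 1)
    stop("invalid `snr_fraction_low`: must be in [0, 1]", call. = FALSE)
  n <- config$n_genes
  n_low <- floor(snr_fraction_low * n)
  with_seed(config$seed + 1L, {
    snr <- c(stats::runif(n_low, 0.5, 2),
             stats::runif(n - n_low, 2 + 1e-6, 20))
    noise <- stats::runif(n, 20, 200)
    data.frame(probe_id = paste0("g", seq_len(n)),
               signal = snr * noise, noise = noise,
               stringsAsFactors = FALSE)
  })
}

#' Generate a synthetic qPCR Ct table
#'
#' Emulates a validation cohort measured by real-time RT-PCR: for each
#' sample, a target-gene Ct and a reference-gene Ct. The reference gene
#' behaves like an abundant housekeeping transcript (Ct ~ 18); baseline
#' target delta-Ct is 6 cycles. A `class_shift` of `s` for a gene lowers
#' (if negative) the class-A delta-Ct by `|s|` cycles relative to class B,
#' so the expected A/B relative-expression ratio is `2^(-s)`.
#'
#' @param genes Character vector of target gene names (non-empty).
#' @param n_per_class Samples per class (classA and classB), >= 2.
#' @param class_shift Per-gene delta-Ct shift applied to class A; recycled.
#' @param seed Integer seed.
#' @param ct_sd Technical + biological Ct standard deviation (cycles),
#'   default 0.4.
#' @return Data frame with columns `sample_id`, `class`, `gene`,
#'   `ct_target`, `ct_reference` — the layout [ddct_relative_expression()]
#'   consumes.
#' @export
generate_ct_table <- function(genes, n_per_class, class_shift = 0,
                              seed = 1L, ct_sd = 0.4) {
  if (length(genes) == 0L)
    stop("invalid `genes`: empty gene list", call. = FALSE)
  if (n_per_class < 2L)
    stop("invalid `n_per_class`: need >= 2 samples per class",
         call. = FALSE)
  class_shift <- rep_len(class_shift, length(genes))
  classes <- rep(c("classA", "classB"), each = n_per_class)
  sample_ids <- paste0(classes, "_", rep(seq_len(n_per_class), 2))
  with_seed(seed, {
    rows <- lapply(seq_along(genes), function(i) {
      shift <- ifelse(classes == "classA", class_shift[i], 0)
      ct_ref <- stats::rnorm(length(classes), 18, ct_sd)
      ct_tgt <- ct_ref + 6 + shift + stats::rnorm(length(classes), 0, ct_sd)
      data.frame(sample_id = sample_ids, class = classes, gene = genes[i],
                 ct_target = ct_tgt, ct_reference = ct_ref,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
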