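#' Pipeline configuration
#'
#' Bundles every path, threshold and toggle the end-to-end pipeline uses.
#' When `matrix_path` is `NULL`, the pipeline generates synthetic data
#' from `synthetic` (a [synthetic_config()]) instead of reading files.
#'
#' @param matrix_path,class_path Expression and sample-class TSV paths,
#'   or `NULL` to simulate.
#' @param probe_path Optional probe signal/noise TSV for the SNR filter.
#' @param gmt_path Optional GMT gene-set file; enables the enrichment
#'   stage.
#' @param out_dir Output directory (created if needed).
#' @param synthetic A [synthetic_config()] used when `matrix_path` is
#'   `NULL`.
#' @param fc_threshold,p_threshold DEG thresholds (defaults 2, 0.05).
#' @param snr_threshold Probe SNR threshold (default 2).
#' @param r_threshold,cor_p_threshold Network edge thresholds (defaults
#'   0.8, 0.05).
#' @param degree_min,cc_min Candidate-hub thresholds (defaults 10, 0.2).
#' @param ddeg_min Core-gene degree-difference threshold (default 8).
#' @param n_boot Bootstrap resamples for the panel AUC CI (default 2000).
#' @param ridge Ridge penalty for the panel logistic fit (default 1e-4,
#'   guarding against quasi-separation at small n).
#' @param seed Integer seed for every stochastic stage.
#' @param stages Character vector of enabled stages, a subset of
#'   `c("preprocess", "deg", "network", "core", "panel", "enrich")`.
#' @return A `pipeline_config` (named list).
#' @export
pipeline_config <- function(matrix_path = NULL, class_path = NULL,
                            probe_path = NULL, gmt_path = NULL,
                            out_dir = tempfile("dcoexnet_run_"),
                            synthetic = NULL,
                            fc_threshold = 2, p_threshold = 0.05,
                            snr_threshold = 2,
                            r_threshold = 0.8, cor_p_threshold = 0.05,
                            degree_min = 10, cc_min = 0.2, ddeg_min = 8,
                            n_boot = 2000, ridge = 1e-4, seed = 1L,
                            stages = c("preprocess", "deg", "network",
                                       "core", "panel", "enrich")) {
  stopifnot(fc_threshold >= 1, p_threshold > 0, p_threshold < 1,
            r_threshold > 0, r_threshold <= 1,
            degree_min >= 0, cc_min >= 0, cc_min <= 1, ddeg_min >= 0,
            n_boot >= 100, ridge >= 0)
  bad <- setdiff(stages, c("preprocess", "deg", "network", "core",
                           "panel", "enrich"))
  if (length(bad) > 0L)
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(list(matrix_path = matrix_path, class_path = class_path,
                 probe_path = probe_path, gmt_path = gmt_path,
                 out_dir = out_dir, synthetic = synthetic,
                 fc_threshold = fc_threshold, p_threshold = p_threshold,
                 snr_threshold = snr_threshold,
                 r_threshold = r_threshold,
                 cor_p_threshold = cor_p_threshold,
                 degree_min = degree_min, cc_min = cc_min,
                 ddeg_min = ddeg_min, n_boot = n_boot, ridge = ridge,
                 seed = as.integer(seed), stages = stages),
            class = "pipeline_config")
}

#' Serialize / deserialize a pipeline configuration as YAML
#'
#' Round-trips losslessly (the nested [synthetic_config()] included).
#'
#' @param config A [pipeline_config()].
#' @param path YAML path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- unclass(config)
  x$stages <- as.list(x$stages)
  if (!is.null(x$synthetic)) {
    syn <- unclass(x$synthetic)
    syn$n_per_class <- as.list(syn$n_per_class)  # yaml drops vector names
    syn$modules <- lapply(syn$modules, unclass)
    if (!is.null(syn$de_genes)) syn$de_genes <- as.list(syn$de_genes)
    x$synthetic <- syn
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(x$synthetic)) {
    s <- x$synthetic
    syn <- synthetic_config(
      n_genes = s$n_genes,
      n_per_class = unlist(s$n_per_class),
      de_genes = if (!is.null(s$de_genes)) as.data.frame(s$de_genes),
      modules = lapply(s$modules, function(m)
        planted_module(m$gene_indices, m$active_class, m$latent_loading,
                       m$factor_sd)),
      noise_sd = s$noise_sd, baseline_mean = s$baseline_mean,
      baseline_gene_sd = s$baseline_gene_sd, seed = s$seed)
  }
  x$stages <- unlist(x$stages)
  do.call(pipeline_config,
          c(x[setdiff(names(x), "synthetic")], list(synthetic = syn)))
}

log_stage <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

#' Run the end-to-end pipeline
#'
#' Executes the enabled stages in the study's order — preprocess,
#' two-step differential expression, per-class co-expression networks,
#' core-gene selection, logistic marker panel with ROC, gene-set
#' enrichment — writing each stage's outputs under `config$out_dir` plus
#' a JSON manifest recording versions, thresholds, seed and per-stage
#' counts. Identical config (and seed) reproduces identical outputs.
#'
#' The two patient classes are taken to be `classA` and `classB` with a
#' `control` arm; the panel's positive class is `classB`.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to
#'   `out_dir/manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "dcoexnet",
                   version = as.character(utils::packageVersion("dcoexnet")),
                   seed = config$seed,
                   thresholds = config[c("fc_threshold", "p_threshold",
                                         "snr_threshold", "r_threshold",
                                         "cor_p_threshold", "degree_min",
                                         "cc_min", "ddeg_min")],
                   stages = list())
  fail <- function(stage, msg) stop("stage '", stage, "' failed: ", msg,
                                    call. = FALSE)

  # --- input ---------------------------------------------------------
  probes <- NULL
  if (is.null(config$matrix_path)) {
    syn <- config$synthetic
    if (is.null(syn)) fail("input", "no matrix_path and no synthetic config")
    log_stage("simulate", "generating synthetic data (seed ", syn$seed, ")")
    x <- generate_expression(syn)
    manifest$stages$simulate <- list(n_genes = nrow(x$values),
                                     n_samples = ncol(x$values))
  } else {
    x <- read_expression_tsv(config$matrix_path, config$class_path)
  }
  if (!is.null(config$probe_path)) probes <- read_probe_tsv(config$probe_path)

  # --- preprocess ----------------------------------------------------
  if ("preprocess" %in% config$stages) {
    n0 <- nrow(x$values)
    if (!is.null(probes)) x <- snr_filter(x, probes, config$snr_threshold)
    x <- quantile_normalize(x)
    log_stage("preprocess", n0 - nrow(x$values), " probe(s) removed, ",
              nrow(x$values), " retained")
    write_expression_tsv(x, file.path(config$out_dir, "expression.tsv"),
                         file.path(config$out_dir, "classes.tsv"))
    manifest$stages$preprocess <- list(n_input = n0,
                                       n_retained = nrow(x$values))
  }

  # --- differential expression --------------------------------------
  degs <- NULL
  if ("deg" %in% config$stages) {
    degs <- tryCatch(
      two_step_degs(x, fc_threshold = config$fc_threshold,
                    p_threshold = config$p_threshold),
      error = function(e) fail("deg", conditionMessage(e)))
    log_stage("deg", nrow(degs), " two-step DEGs")
    write_records_tsv(degs, file.path(config$out_dir, "degs.tsv"))
    manifest$stages$deg <- attr(degs, "meta")
  }

  # --- networks ------------------------------------------------------
  net_a <- net_b <- NULL
  if ("network" %in% config$stages) {
    genes <- if (!is.null(degs) && nrow(degs) > 0L) degs$gene_id
             else rownames(x$values)
    build <- function(lab) tryCatch(
      build_network(x, lab, genes, config$r_threshold,
                    config$cor_p_threshold),
      error = function(e) fail("network", conditionMessage(e)))
    net_a <- build("classA"); net_b <- build("classB")
    log_stage("network", "classA: ", nrow(net_a$edges), " edges; classB: ",
              nrow(net_b$edges), " edges over ", length(genes), " genes")
    write_edge_list(net_a, file.path(config$out_dir, "network_classA.tsv"))
    write_edge_list(net_b, file.path(config$out_dir, "network_classB.tsv"))
    write_sif(net_a, file.path(config$out_dir, "network_classA.sif"))
    write_sif(net_b, file.path(config$out_dir, "network_classB.sif"))
    manifest$stages$network <- list(edges_a = nrow(net_a$edges),
                                    edges_b = nrow(net_b$edges),
                                    n_genes = length(genes))
  }

  # --- core genes ----------------------------------------------------
  core <- NULL
  if ("core" %in% config$stages) {
    if (is.null(net_a)) fail("core", "network stage disabled")
    cand <- locate_candidates(net_a, net_b, config$degree_min,
                              config$cc_min)
    core <- select_core_genes(cand, net_a, net_b, config$ddeg_min,
                              de_records = degs)
    log_stage("core", nrow(cand), " candidates, ", nrow(core),
              " core gene(s)")
    write_records_tsv(core, file.path(config$out_dir, "core_genes.tsv"))
    manifest$stages$core <- list(n_candidates = nrow(cand),
                                 n_core = nrow(core),
                                 core_genes = core$gene_id)
  }

  # --- marker panel --------------------------------------------------
  if ("panel" %in% config$stages) {
    if (is.null(core)) fail("panel", "core stage disabled")
    panel_genes <- utils::head(core$gene_id, 3)
    if (length(panel_genes) == 0L) {
      log_stage("panel", "no core genes; skipping panel fit")
      manifest$stages$panel <- list(n_markers = 0L)
    } else {
      ab <- c(class_samples(x, "classA"), class_samples(x, "classB"))
      feats <- t(x$values[panel_genes, ab, drop = FALSE])
      labs <- x$sample_class[ab]
      model <- fit_logistic(feats, labs, positive_class = "classB",
                            penalty = config$ridge)
      prob <- predict_prob(model, feats)
      roc <- roc_auc(prob, labs, positive_class = "classB", ci = TRUE,
                     n_boot = config$n_boot, seed = config$seed)
      log_stage("panel", length(panel_genes), "-gene panel, AUC ",
                round(roc$auc, 3), " (", round(roc$ci_low, 3), "-",
                round(roc$ci_high, 3), ")")
      report <- list(markers = panel_genes,
                     intercept = model$intercept,
                     coefficients = as.list(model$coefficients),
                     converged = model$converged,
                     ridge = config$ridge,
                     auc = roc$auc, ci_low = roc$ci_low,
                     ci_high = roc$ci_high, n_boot = config$n_boot,
                     seed = config$seed)
      jsonlite::write_json(report,
                           file.path(config$out_dir, "panel.json"),
                           auto_unbox = TRUE, digits = NA)
      write_records_tsv(
        data.frame(threshold = roc$thresholds, fpr = roc$fpr,
                   tpr = roc$tpr),
        file.path(config$out_dir, "roc_points.tsv"))
      manifest$stages$panel <- report
    }
  }

  # --- enrichment ----------------------------------------------------
  if ("enrich" %in% config$stages && !is.null(config$gmt_path)) {
    if (is.null(core)) fail("enrich", "core stage disabled")
    coll <- read_gmt(config$gmt_path, background = rownames(x$values))
    glist <- if (!is.null(degs) && nrow(degs) > 0L) degs$gene_id
             else core$gene_id
    enr <- tryCatch(hypergeom_enrich(glist, coll),
                    error = function(e) fail("enrich", conditionMessage(e)))
    log_stage("enrich", nrow(enr), " term(s) tested; top p = ",
              signif(enr$p_value[1], 3))
    write_records_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))
    manifest$stages$enrich <- list(n_terms = nrow(enr),
                                   min_p = min(enr$p_value))
  }

  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
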