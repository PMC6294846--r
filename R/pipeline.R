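#' Pipeline configuration
#'
#' Collects the input locations (or a synthetic-data configuration), the
#' analysis thresholds and the master seed for one end-to-end run. Unknown
#' fields are rejected.
#'
#' @param matrix_path,design_path,annotation_path Input files (TSV matrix,
#'   two-line design, annotations). Ignored when `simulation` is given.
#' @param annotation_format `"two_column"` or `"gaf"`.
#' @param simulation Optional [simulation_config()]; when present the
#'   expression matrix and annotations are generated instead of read.
#' @param p_threshold,lfc_threshold DEG selection cutoffs (strict;
#'   defaults 0.02 and 2).
#' @param subnetwork_weight Strict |SRCC| cutoff for the subnetwork
#'   (default 0.8).
#' @param min_term_genes Strict lower bound on annotated network genes per
#'   retained term (default 20).
#' @param auc_threshold Strict optimal-function AUC cutoff (default 0.7).
#' @param n_folds Cross-validation folds (default 3).
#' @param seed Master seed; the CV fold seed is derived from it.
#' @param out_dir Output directory (created if needed).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_path = NULL, design_path = NULL,
                            annotation_path = NULL,
                            annotation_format = c("two_column", "gaf"),
                            simulation = NULL,
                            p_threshold = 0.02, lfc_threshold = 2,
                            subnetwork_weight = 0.8,
                            min_term_genes = 20L,
                            auc_threshold = 0.7, n_folds = 3L,
                            seed = 1L, out_dir = tempfile("gbanet_run_")) {
  annotation_format <- match.arg(annotation_format)
  if (is.null(simulation)) {
    if (is.null(matrix_path) || is.null(design_path) ||
        is.null(annotation_path))
      stop("provide matrix, design and annotation paths, ",
           "or a `simulation` config")
  } else {
    stopifnot(inherits(simulation, "simulation_config"))
  }
  if (p_threshold <= 0 || p_threshold > 1)
    stop("p_threshold must be in (0, 1]")
  if (lfc_threshold < 0) stop("lfc_threshold must be >= 0")
  if (subnetwork_weight < 0 || subnetwork_weight > 1)
    stop("subnetwork_weight must be in [0, 1]")
  if (auc_threshold < 0 || auc_threshold > 1)
    stop("auc_threshold must be in [0, 1]")
  if (n_folds < 2L) stop("n_folds must be >= 2")
  structure(list(matrix_path = matrix_path, design_path = design_path,
                 annotation_path = annotation_path,
                 annotation_format = annotation_format,
                 simulation = simulation,
                 p_threshold = p_threshold,
                 lfc_threshold = lfc_threshold,
                 subnetwork_weight = subnetwork_weight,
                 min_term_genes = as.integer(min_term_genes),
                 auc_threshold = auc_threshold,
                 n_folds = as.integer(n_folds),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a
#' `simulation:` mapping, if present, is passed to [simulation_config()].
#' Unknown keys in either mapping are rejected.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(pipeline_config)), "simulation")
  unknown <- setdiff(names(raw), c(allowed, "simulation"))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$simulation)) {
    sim_unknown <- setdiff(names(raw$simulation),
                           names(formals(simulation_config)))
    if (length(sim_unknown))
      stop("unknown simulation key(s): ",
           paste(sim_unknown, collapse = ", "))
    raw$simulation <- do.call(simulation_config, raw$simulation)
  }
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes the five stages in order — DEG screening, co-expression
#' network construction, annotation filtering, cross-validated
#' neighbor-voting evaluation, optimal-function selection — writing every
#' stage's table to `config$out_dir` along with a JSON run manifest.
#' Outputs are pure functions of (inputs, config, seed): rerunning with
#' the same configuration reproduces them byte for byte.
#'
#' Stage outputs: `deg_table.tsv`, `edge_list.tsv`, `network.graphml`,
#' `srcc_matrix.tsv`, `top_degree_nodes.tsv`, `subnetwork_edges.tsv`,
#' `subnetwork.graphml`, `term_table.tsv`, `term_performance.tsv`,
#' `mf_scores.tsv`, `auc_histogram.tsv`, `optimal_terms.tsv`,
#' `manifest.json` (plus the simulated inputs in synthetic mode).
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage
#'   (`degs`, `network`, `subnetwork`, `top_nodes`, `annotations`,
#'   `performance`, `optimal`, `manifest`, and `truth` in synthetic mode).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  synthetic <- !is.null(config$simulation)

  # stage 1: inputs
  if (synthetic) {
    sim <- generate_expression(config$simulation)
    em <- sim$expression
    truth <- sim$truth
    ann_full <- generate_annotations(truth, config$simulation)
    truth$coherent_terms <- ann_full$coherent_terms
    write_expression(em, out("expression.tsv"), out("design.tsv"))
    write_annotations(ann_full, out("annotations.tsv"))
    write_ground_truth(truth, out("ground_truth.json"))
  } else {
    em <- read_expression(config$matrix_path, config$design_path)
    truth <- NULL
  }

  # stage 2: differential expression
  records <- moderated_t_test(em)
  records <- select_degs(records, p_threshold = config$p_threshold,
                         lfc_threshold = config$lfc_threshold)
  write_deg_table(records, out("deg_table.tsv"))
  deg_ids <- records$gene_id[records$is_deg]
  if (length(deg_ids) < 2L)
    stop("degs stage: fewer than 2 DEGs selected; ",
         "cannot build a co-expression network ",
         "(DEG table written to ", out("deg_table.tsv"), ")")

  # stage 3: co-expression network over the DEGs
  srcc <- spearman_matrix(em, deg_ids)
  net <- build_network(srcc)
  top_nodes <- node_degrees(net, top_k = 7L)
  sub <- threshold_subnetwork(net, min_weight = config$subnetwork_weight)
  write_srcc_matrix(srcc, out("srcc_matrix.tsv"))
  write_edge_list(net, out("edge_list.tsv"))
  write_graphml(net, out("network.graphml"))
  utils::write.table(top_nodes, out("top_degree_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_edge_list(sub, out("subnetwork_edges.tsv"))
  write_graphml(sub, out("subnetwork.graphml"))

  # stage 4: annotations restricted to the network universe
  if (synthetic) {
    ann <- annotation_set(ann_full$memberships, universe = net$nodes)
    ann$coherent_terms <- ann_full$coherent_terms
  } else {
    ann <- load_annotations(config$annotation_path,
                            format = config$annotation_format,
                            universe = net$nodes)
  }
  ann <- filter_terms(ann, min_genes = config$min_term_genes)
  write_term_table(ann, out("term_table.tsv"))

  # stage 5: neighbor-voting evaluation and optimal-function selection
  ss <- derive_seeds(config$seed)
  cv_seed <- ss[["spare"]]
  perf <- evaluate_terms(net, ann, n_folds = config$n_folds,
                         seed = cv_seed,
                         auc_threshold = config$auc_threshold)
  mf <- multifunctionality_scores(ann)
  optimal <- select_optimal(perf, auc_threshold = config$auc_threshold)
  write_term_performance(perf, out("term_performance.tsv"))
  write_mf_table(mf, out("mf_scores.tsv"))
  utils::write.table(auc_histogram(perf), out("auc_histogram.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_term_performance(optimal, out("optimal_terms.tsv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("gbanet")),
    seed = config$seed,
    cv_seed = unname(cv_seed),
    synthetic = synthetic,
    thresholds = list(p = config$p_threshold,
                      lfc = config$lfc_threshold,
                      subnetwork_weight = config$subnetwork_weight,
                      min_term_genes = config$min_term_genes,
                      auc = config$auc_threshold,
                      n_folds = config$n_folds),
    counts = list(genes = nrow(em$values),
                  samples = ncol(em$values),
                  degs = length(deg_ids),
                  network_edges = nrow(net$edges),
                  subnetwork_nodes = length(sub$nodes),
                  subnetwork_edges = nrow(sub$edges),
                  retained_terms = length(ann$terms),
                  optimal_terms = nrow(optimal)))
  jsonlite::write_json(manifest, out("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(expression = em, truth = truth, degs = records,
                 network = net, subnetwork = sub, top_nodes = top_nodes,
                 annotations = ann, mf = mf, performance = perf,
                 optimal = optimal, manifest = manifest))
}
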