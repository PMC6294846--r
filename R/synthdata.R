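#' Configuration for the synthetic two-group expression study
#'
#' Describes a simulated two-group placenta-style expression study at
#' desk scale: a log2 Gaussian expression matrix with planted
#' differentially expressed (DE) genes, co-expressed gene modules driven by
#' shared latent factors, and annotation terms partially coherent with the
#' modules. Every downstream stage of the pipeline can be exercised against
#' the known ground truth.
#'
#' The module model for a gene g in module m at sample s is
#' `x = mu + noise_sd * (sqrt(module_rho) * f[m,s] + sqrt(1 - module_rho) * eps)`
#' with `f` and `eps` standard normal, so the population correlation of two
#' genes in the same module is exactly `module_rho`. Genes outside modules
#' are independent noise. Planted DE genes additionally receive a constant
#' shift of magnitude `de_lfc_mean` (log2 units) in the case group.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group (two groups).
#' @param n_de_genes Number of planted DE genes.
#' @param de_lfc_mean Planted group-mean difference magnitude, log2 units.
#' @param n_modules,module_size Number and size of co-expressed modules.
#' @param module_rho Target within-module population correlation in [0,1].
#' @param noise_sd Expression noise standard deviation (log2 units).
#' @param n_terms Number of annotation terms to plant.
#' @param term_size Genes per planted term.
#' @param term_coherence Fraction in [0,1] of each term's members drawn
#'   from that term's anchor module; the rest are drawn uniformly from the
#'   remaining genes.
#' @param min_term_size Smallest allowed term size (validated).
#' @param seed Master seed; substreams for expression, DE assignment and
#'   annotations are derived from it deterministically.
#' @param de_covers_modules If `TRUE`, the planted DE set covers all module
#'   genes first and only then draws from the background, modelling a
#'   condition that perturbs whole co-expressed modules. Default `FALSE`:
#'   DE genes are sampled uniformly, independent of module membership.
#' @param de_sign `"random"` (each DE gene goes up or down independently)
#'   or `"by_module"` (each module shifts coherently in one direction,
#'   which is the only construction consistent with a shared within-module
#'   factor; background DE genes still get random signs).
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 500, n_per_group = 8,
                              n_de_genes = 50, de_lfc_mean = 3,
                              n_modules = 10, module_size = 25,
                              module_rho = 0.7, noise_sd = 1,
                              n_terms = 20, term_size = 25,
                              term_coherence = 0.5, min_term_size = 20,
                              seed = 1,
                              de_covers_modules = FALSE,
                              de_sign = c("random", "by_module")) {
  de_sign <- match.arg(de_sign)
  cfg <- list(n_genes = as.integer(n_genes),
              n_per_group = as.integer(n_per_group),
              n_de_genes = as.integer(n_de_genes),
              de_lfc_mean = de_lfc_mean,
              n_modules = as.integer(n_modules),
              module_size = as.integer(module_size),
              module_rho = module_rho, noise_sd = noise_sd,
              n_terms = as.integer(n_terms),
              term_size = as.integer(term_size),
              term_coherence = term_coherence,
              min_term_size = as.integer(min_term_size),
              seed = as.integer(seed),
              de_covers_modules = isTRUE(de_covers_modules),
              de_sign = de_sign)
  with(cfg, {
    if (n_genes < 2L || n_per_group < 2L)
      stop("need n_genes >= 2 and n_per_group >= 2")
    if (n_de_genes < 0L || n_de_genes > n_genes)
      stop("n_de_genes must be in [0, n_genes]")
    if (n_modules * module_size > n_genes)
      stop("n_modules * module_size must not exceed n_genes")
    if (module_rho < 0 || module_rho > 1)
      stop("module_rho must be in [0, 1]")
    if (term_coherence < 0 || term_coherence > 1)
      stop("term_coherence must be in [0, 1]")
    if (noise_sd < 0) stop("noise_sd must be >= 0")
    if (n_terms > 0L && term_size > n_genes)
      stop("term_size exceeds n_genes")
    if (n_terms > 0L && term_size < min_term_size)
      stop("term_size below min_term_size")
  })
  structure(cfg, class = "simulation_config")
}

# Deterministic substream seeds from the master seed (kept < 2^31).
# Order: expression, DE assignment, annotations, spare.
derive_seeds <- function(seed) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  stats::setNames(sample.int(2147483646L, 4L),
                  c("expression", "de", "annotations", "spare"))
}

#' Generate a synthetic expression matrix with known ground truth
#'
#' Draws the two-group log2 expression matrix described by
#' [simulation_config()]: latent-factor modules, independent background
#' genes, and a planted DE shift in the case group.
#'
#' @param config A [simulation_config()].
#' @return A list with `expression` (an [expression_matrix()] with groups
#'   `"control"` and `"case"`) and `truth`, a list of class
#'   `ground_truth` with `de_gene_ids`, `de_signs`, `module_assignments`
#'   (named integer vector, `NA` for background genes) and a
#'   `coherent_terms` slot filled in by [generate_annotations()].
#' @examples
#' sim <- generate_expression(simulation_config(n_genes = 100, seed = 7))
#' sim$expression
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ss <- derive_seeds(config$seed)
  n <- config$n_genes
  ns <- 2L * config$n_per_group
  gene_ids <- sprintf("G%05d", seq_len(n))
  sample_ids <- c(sprintf("ctrl_%02d", seq_len(config$n_per_group)),
                  sprintf("case_%02d", seq_len(config$n_per_group)))
  group <- rep(c("control", "case"), each = config$n_per_group)

  # module membership: a random subset of genes, split into modules
  set.seed(ss[["expression"]])
  module <- rep(NA_integer_, n)
  n_mod_genes <- config$n_modules * config$module_size
  if (n_mod_genes > 0L) {
    mod_genes <- sample.int(n, n_mod_genes)
    module[mod_genes] <- rep(seq_len(config$n_modules),
                             each = config$module_size)
  }
  names(module) <- gene_ids

  rho <- config$module_rho
  eps <- matrix(stats::rnorm(n * ns), n, ns)
  x <- config$noise_sd * sqrt(1 - ifelse(is.na(module), 0, rho)) * eps
  if (config$n_modules > 0L && rho > 0) {
    f <- matrix(stats::rnorm(config$n_modules * ns), config$n_modules, ns)
    in_mod <- !is.na(module)
    x[in_mod, ] <- x[in_mod, ] +
      config$noise_sd * sqrt(rho) * f[module[in_mod], , drop = FALSE]
  }
  x <- x + 8  # baseline log2 abundance

  # planted DE: shift case samples by +/- de_lfc_mean
  set.seed(ss[["de"]])
  de_idx <- integer(0)
  if (config$n_de_genes > 0L) {
    if (config$de_covers_modules && n_mod_genes > 0L) {
      pool <- which(is.na(module))
      de_idx <- which(!is.na(module))
      extra <- config$n_de_genes - length(de_idx)
      if (extra > 0L) de_idx <- c(de_idx, sample(pool, extra))
      else de_idx <- sample(de_idx, config$n_de_genes)
    } else {
      de_idx <- sample.int(n, config$n_de_genes)
    }
  }
  signs <- integer(0)
  if (length(de_idx)) {
    signs <- sample(c(-1L, 1L), length(de_idx), replace = TRUE)
    if (config$de_sign == "by_module") {
      mod_sign <- sample(c(-1L, 1L), max(1L, config$n_modules),
                         replace = TRUE)
      in_mod <- !is.na(module[de_idx])
      signs[in_mod] <- mod_sign[module[de_idx[in_mod]]]
    }
    case_cols <- group == "case"
    x[de_idx, case_cols] <- x[de_idx, case_cols] +
      signs * config$de_lfc_mean
  }

  rownames(x) <- gene_ids
  colnames(x) <- sample_ids
  truth <- structure(
    list(de_gene_ids = gene_ids[de_idx],
         de_signs = stats::setNames(signs, gene_ids[de_idx]),
         module_assignments = module,
         coherent_terms = character(0)),
    class = "ground_truth")
  list(expression = expression_matrix(x, group, case = "case"),
       truth = truth,
       seeds = ss)
}

#' Generate synthetic gene-term annotations coherent with planted modules
#'
#' Each term is anchored to a module (round robin); a fraction
#' `term_coherence` of its members is drawn from the anchor module and the
#' rest uniformly from the remaining genes. With `term_coherence = 0` the
#' terms are independent of the module structure.
#'
#' @param truth The `ground_truth` from [generate_expression()].
#' @param config The same [simulation_config()].
#' @return An [annotation_set()] over all simulated genes, with an extra
#'   element `coherent_terms`: the term ids planted with nonzero module
#'   coherence (empty when `term_coherence == 0` or there are no modules).
#' @export
generate_annotations <- function(truth, config) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(config, "simulation_config"))
  if (config$n_terms > 0L && config$term_size > config$n_genes)
    stop("term_size exceeds the gene universe")
  ss <- derive_seeds(config$seed)
  set.seed(ss[["annotations"]])
  genes <- names(truth$module_assignments)
  terms <- sprintf("GO:%07d", seq_len(config$n_terms))
  n_mod <- max(0L, config$n_modules)
  coherent <- config$term_coherence > 0 && n_mod > 0L
  mem <- vector("list", config$n_terms)
  for (k in seq_len(config$n_terms)) {
    members <- character(0)
    if (coherent) {
      anchor <- ((k - 1L) %% n_mod) + 1L
      mod_genes <- genes[!is.na(truth$module_assignments) &
                           truth$module_assignments == anchor]
      n_coh <- min(round(config$term_coherence * config$term_size),
                   length(mod_genes))
      members <- sample(mod_genes, n_coh)
    }
    rest <- setdiff(genes, members)
    members <- c(members, sample(rest, config$term_size - length(members)))
    mem[[k]] <- data.frame(gene = members, term = terms[k],
                           stringsAsFactors = FALSE)
  }
  memberships <- if (config$n_terms > 0L) do.call(rbind, mem) else
    data.frame(gene = character(0), term = character(0))
  ann <- annotation_set(memberships, universe = genes)
  ann$coherent_terms <- if (coherent) terms else character(0)
  ann
}

#' Serialize synthetic ground truth as JSON
#'
#' @param truth A `ground_truth` list.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  mod <- truth$module_assignments
  jsonlite::write_json(
    list(de_gene_ids = truth$de_gene_ids,
         de_signs = as.list(truth$de_signs),
         module_assignments = as.list(mod[!is.na(mod)]),
         coherent_terms = truth$coherent_terms),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
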