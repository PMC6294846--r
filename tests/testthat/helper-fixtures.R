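# Small fixtures and independent brute-force oracles shared across tests.

# expression_matrix from a plain matrix with an 8-vs-8 style design
toy_expression <- function(values, n_ctrl, n_case) {
  colnames(values) <- c(sprintf("c%02d", seq_len(n_ctrl)),
                        sprintf("d%02d", seq_len(n_case)))
  expression_matrix(values,
                    group = rep(c("control", "case"), c(n_ctrl, n_case)),
                    case = "case")
}

# build a coexpression_network directly from a symmetric weight matrix
toy_network <- function(w) {
  diag(w) <- 1
  build_network(w)
}

# AUC by exhaustive pair counting: the Mann-Whitney oracle
pair_count_auc <- function(scores, positives, negatives) {
  total <- 0
  for (p in positives) for (n in negatives) {
    sp <- scores[[p]]; sn <- scores[[n]]
    total <- total + (sp > sn) + 0.5 * (sp == sn)
  }
  total / (length(positives) * length(negatives))
}

# multifunctionality by an explicit double loop over (gene, term) pairs
brute_force_mf <- function(ann) {
  sz <- term_sizes(ann)
  out <- numeric(length(ann$universe))
  names(out) <- ann$universe
  for (g in ann$universe) {
    for (i in seq_len(nrow(sz))) {
      k <- sz$term[i]
      in_k <- any(ann$memberships$gene == g & ann$memberships$term == k)
      if (in_k && sz$out_count[i] > 0)
        out[g] <- out[g] + 1 / (sz$in_count[i] * sz$out_count[i])
    }
  }
  out
}

# neighbor voting for one gene and one term by explicit summation
brute_force_vote <- function(w_row, members, visible, prior) {
  num <- 0; den <- 0
  for (j in names(w_row)) {
    if (j %in% visible) {
      den <- den + abs(w_row[[j]])
      if (j %in% members) num <- num + abs(w_row[[j]])
    }
  }
  if (den == 0) prior else num / den
}

# the study-condition simulation used for the stochastic checks: a
# module-perturbing condition (all module genes differentially expressed,
# coherent per-module direction) so the functional signal survives the
# DEG screen
study_config <- function(seed, module_rho = 0.7, n_terms = 20,
                         term_coherence = 0.5) {
  simulation_config(n_genes = 500, n_per_group = 8, n_de_genes = 400,
                    de_lfc_mean = 3, n_modules = 10, module_size = 25,
                    module_rho = module_rho, noise_sd = 1,
                    n_terms = n_terms, term_size = 25,
                    term_coherence = term_coherence, min_term_size = 20,
                    seed = seed, de_covers_modules = TRUE,
                    de_sign = "by_module")
}
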