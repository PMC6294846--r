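test_that("multifunctionality follows the in*out reciprocal sum", {
  universe <- sprintf("g%03d", 1:100)
  ann <- annotation_set(
    data.frame(gene = universe[1:10], term = "K"), universe)
  mf <- multifunctionality_scores(ann)
  # single term, 10 in / 90 out: members score 1/900, others 0
  expect_equal(mf$mf_score[mf$gene == "g001"], 1 / 900)
  expect_equal(mf$mf_score[mf$gene == "g050"], 0)
  expect_equal(mf$mf_rank[mf$gene == "g001"], 1)  # tie broken by id

  # a term annotating the whole universe carries no information
  ann2 <- annotation_set(
    rbind(data.frame(gene = universe, term = "ALL"),
          data.frame(gene = universe[1:10], term = "K")), universe)
  expect_warning(mf2 <- multifunctionality_scores(ann2), "whole universe")
  expect_equal(mf2$mf_score, mf$mf_score)
})

test_that("multifunctionality equals the brute-force double loop", {
  for (i in 1:100) {
    set.seed(600 + i)
    universe <- paste0("g", 1:6)
    mem <- data.frame(
      gene = sample(universe, 9, replace = TRUE),
      term = sample(paste0("T", 1:3), 9, replace = TRUE))
    ann <- annotation_set(mem, universe)
    mf <- multifunctionality_scores(ann)
    oracle <- brute_force_mf(ann)
    expect_equal(setNames(mf$mf_score, mf$gene), oracle[mf$gene])
  }
})

test_that("neighbor voting reproduces hand-computed weighted fractions", {
  w <- matrix(0, 4, 4,
              dimnames = list(c("i", "a", "b", "c"), c("i", "a", "b", "c")))
  w["i", c("a", "b", "c")] <- c(0.9, 0.5, 0.1)
  w[c("a", "b", "c"), "i"] <- c(0.9, 0.5, 0.1)
  w["a", "b"] <- w["b", "a"] <- 0.4
  net <- toy_network(w)
  ann <- annotation_set(data.frame(gene = c("a", "c"), term = "K"),
                        universe = c("i", "a", "b", "c"))
  s <- neighbor_voting_scores(net, ann, labels_visible = c("a", "b", "c"))
  expect_equal(s["i", "K"], (0.9 + 0.1) / (0.9 + 0.5 + 0.1))

  # all visible voters annotated -> 1; none annotated -> 0
  ann_all <- annotation_set(data.frame(gene = c("a", "b", "c"), term = "K"),
                            universe = c("i", "a", "b", "c"))
  expect_equal(neighbor_voting_scores(net, ann_all,
                                      c("a", "b", "c"))["i", "K"], 1)
  ann_none <- annotation_set(data.frame(gene = "i", term = "K"),
                             universe = c("i", "a", "b", "c"))
  expect_equal(neighbor_voting_scores(net, ann_none,
                                      c("a", "b", "c"))["i", "K"], 0)
  expect_error(neighbor_voting_scores(net, ann, character(0)),
               "no visible labels")
})

test_that("isolated genes fall back to the term prior", {
  w <- matrix(0, 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  w["a", "b"] <- w["b", "a"] <- 0.8  # c and d are isolated
  net <- toy_network(w)
  ann <- annotation_set(data.frame(gene = c("a", "b"), term = "K"),
                        universe = letters[1:4])
  s <- neighbor_voting_scores(net, ann, labels_visible = c("a", "b", "d"))
  expect_equal(s["c", "K"], 2 / 3)  # prior: 2 of 3 visible genes in K
  expect_true(all(s >= 0 & s <= 1))
})

test_that("hidden labels never influence scores (no leakage)", {
  set.seed(17)
  n <- 12
  w <- matrix(runif(n * n, -1, 1), n, n)
  w <- (w + t(w)) / 2
  dimnames(w) <- list(paste0("g", 1:n), paste0("g", 1:n))
  net <- toy_network(w)
  universe <- paste0("g", 1:n)
  mem <- data.frame(gene = sample(universe, 15, replace = TRUE),
                    term = sample(c("K1", "K2"), 15, replace = TRUE))
  visible <- paste0("g", 1:8)
  s1 <- neighbor_voting_scores(net, annotation_set(mem, universe), visible)
  # rewrite every hidden gene's annotations; visible-fold scores must not move
  mem2 <- mem[mem$gene %in% visible, ]
  mem2 <- rbind(mem2, data.frame(gene = c("g9", "g10", "g11", "g12"),
                                 term = "K1"))
  s2 <- neighbor_voting_scores(net, annotation_set(mem2, universe), visible)
  expect_equal(s1[c("g9", "g10", "g11", "g12"), ],
               s2[c("g9", "g10", "g11", "g12"), ])
})

test_that("cross-validation folds are balanced, disjoint and seeded", {
  f9 <- cv_split(paste0("g", 1:9), 3, seed = 2)
  expect_equal(lengths(f9), c(`1` = 3, `2` = 3, `3` = 3))
  f10 <- cv_split(paste0("g", 1:10), 3, seed = 2)
  expect_equal(sort(lengths(f10), decreasing = TRUE), c(4, 3, 3),
               ignore_attr = TRUE)
  expect_setequal(unlist(f10), paste0("g", 1:10))
  expect_equal(sum(lengths(f10)), 10)
  expect_identical(f10, cv_split(paste0("g", 1:10), 3, seed = 2))
  expect_false(identical(f10, cv_split(paste0("g", 1:10), 3, seed = 3)))
  expect_error(cv_split(paste0("g", 1:2), 3), "configuration error")
})

test_that("roc_auc matches exhaustive pair counting", {
  expect_equal(roc_auc(c(a = 0.9, b = 0.8, c = 0.1, d = 0.2),
                       c("a", "b"), c("c", "d")), 1)
  expect_equal(roc_auc(c(a = 0.5, b = 0.5, c = 0.5), c("a"), c("b", "c")),
               0.5)
  expect_equal(roc_auc(c(p1 = 0.9, p2 = 0.4, n1 = 0.6, n2 = 0.2),
                       c("p1", "p2"), c("n1", "n2")), 3 / 4)
  expect_error(roc_auc(c(a = 1), "a", character(0)), "nonempty")
  expect_error(roc_auc(c(a = 1, b = 2), c("a", "b"), "b"), "disjoint")

  for (i in 1:100) {
    set.seed(700 + i)
    n <- sample(4:50, 1)
    scores <- setNames(sample(seq(0, 1, 0.1), n, replace = TRUE),
                       paste0("g", 1:n))  # coarse grid forces ties
    pos <- sample(names(scores), sample(1:(n - 1), 1))
    neg <- setdiff(names(scores), pos)
    expect_equal(roc_auc(scores, pos, neg),
                 pair_count_auc(scores, pos, neg))
  }
})

test_that("evaluate_terms matches an independent from-scratch pipeline", {
  set.seed(23)
  n <- 20
  w <- matrix(runif(n * n, -1, 1), n, n)
  w <- (w + t(w)) / 2
  genes <- sprintf("g%02d", 1:n)
  dimnames(w) <- list(genes, genes)
  net <- toy_network(w)
  mem <- data.frame(gene = c(sample(genes, 8), sample(genes, 10)),
                    term = rep(c("K1", "K2"), c(8, 10)))
  ann <- annotation_set(mem, genes)
  perf <- evaluate_terms(net, ann, n_folds = 3, seed = 5)

  # oracle: explicit loops over folds, genes and terms
  folds <- cv_split(genes, 3, seed = 5)
  members <- split(ann$memberships$gene, ann$memberships$term)
  W <- abs(w); diag(W) <- 0
  for (k in c("K1", "K2")) {
    fold_aucs <- numeric(3)
    for (f in 1:3) {
      held <- folds[[f]]
      visible <- setdiff(genes, held)
      vis_members <- intersect(members[[k]], visible)
      prior <- length(vis_members) / length(visible)
      scores <- sapply(held, function(i)
        brute_force_vote(W[i, ], vis_members, visible, prior))
      pos <- intersect(held, members[[k]])
      neg <- setdiff(held, members[[k]])
      fold_aucs[f] <- pair_count_auc(scores, pos, neg)
    }
    row <- perf[perf$term == k, ]
    expect_equal(unlist(row[paste0("auc_fold", 1:3)]), fold_aucs,
                 ignore_attr = TRUE)
    expect_equal(row$mean_auc, mean(fold_aucs))
  }
  expect_identical(perf,
                   evaluate_terms(net, ann, n_folds = 3, seed = 5))
})

test_that("optimal-function selection is strict at the AUC threshold", {
  perf <- data.frame(term = c("A", "B", "C"),
                     mean_auc = c(0.9, 0.75, 0.65))
  sel <- select_optimal(perf)
  expect_equal(sel$term, c("A", "B"))
  expect_equal(nrow(select_optimal(data.frame(term = "X",
                                              mean_auc = 0.7))), 0)
  expect_equal(select_optimal(perf, auc_threshold = 0.85)$term, "A")
})

test_that("prediction of coherent terms strengthens with coherence and correlation", {
  mean_coherent_auc <- function(coh, rho, seed) {
    cfg <- study_config(seed, module_rho = rho, n_terms = 10,
                        term_coherence = coh)
    sim <- generate_expression(cfg)
    ann0 <- generate_annotations(sim$truth, cfg)
    rec <- select_degs(moderated_t_test(sim$expression))
    net <- build_network(
      spearman_matrix(sim$expression, rec$gene_id[rec$is_deg]))
    ann <- annotation_set(ann0$memberships, universe = net$nodes)
    perf <- suppressWarnings(evaluate_terms(net, ann, seed = seed))
    mean(perf$mean_auc, na.rm = TRUE)
  }
  seeds <- 1:3
  by_coh <- sapply(c(0.2, 0.5, 0.9), function(coh)
    mean(sapply(seeds, function(s) mean_coherent_auc(coh, 0.9, s))))
  expect_false(is.unsorted(by_coh))
  by_rho <- sapply(c(0.3, 0.6, 0.9), function(rho)
    mean(sapply(seeds, function(s) mean_coherent_auc(0.9, rho, s))))
  expect_false(is.unsorted(by_rho))
})
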