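#' Gene multifunctionality scores
#'
#' For each gene i, `MF_i = sum over terms K containing i of
#' 1 / (Num_in_K * Num_out_K)`, where `Num_in_K` and `Num_out_K` count
#' universe genes inside and outside term K. Genes annotated to many
#' small-but-not-tiny terms score highest; a gene with no annotation
#' scores 0. The score depends only on the annotation structure, never on
#' expression, and its ranking serves as the annotation-bias baseline
#' predictor: a method that merely recapitulates multifunctionality will
#' not beat it.
#'
#' @param ann An [annotation_set()].
#' @return data.frame `gene`, `mf_score`, `mf_rank` (1 = most
#'   multifunctional; ties broken by gene id), one row per universe gene.
#' @export
multifunctionality_scores <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  sz <- term_sizes(ann)
  degenerate <- sz$out_count == 0L
  if (any(degenerate)) {
    warning("term(s) annotating the whole universe excluded from MF: ",
            paste(sz$term[degenerate], collapse = ", "))
    sz <- sz[!degenerate, , drop = FALSE]
  }
  contrib <- stats::setNames(1 / (sz$in_count * sz$out_count), sz$term)
  mem <- ann$memberships[ann$memberships$term %in% sz$term, ,
                         drop = FALSE]
  per_gene <- tapply(contrib[mem$term], mem$gene, sum)
  mf <- stats::setNames(rep(0, length(ann$universe)), ann$universe)
  mf[names(per_gene)] <- per_gene
  ord <- order(-mf, names(mf))
  rank <- integer(length(mf))
  rank[ord] <- seq_along(mf)
  data.frame(gene = names(mf), mf_score = unname(mf), mf_rank = rank,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Dense |SRCC| weight matrix over the network nodes, zero diagonal.
weight_matrix <- function(net, absolute = TRUE) {
  n <- length(net$nodes)
  W <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  ia <- match(net$edges$gene_a, net$nodes)
  ib <- match(net$edges$gene_b, net$nodes)
  w <- if (absolute) net$edges$abs_weight else net$edges$weight
  W[cbind(ia, ib)] <- w
  W[cbind(ib, ia)] <- w
  W
}

#' Weighted neighbor-voting prediction scores
#'
#' For every gene i and term K, all other genes with visible labels vote
#' with their absolute co-expression weight:
#' `score(i, K) = sum_j |w_ij| 1[j in K, j visible] /
#'  sum_j |w_ij| 1[j visible]`, j ranging over all other network genes —
#' in a complete correlation network this pools nearest neighbors and
#' indirect connections alike. If gene i has no weight to any visible
#' gene, the score falls back to the term prior (visible in-count over
#' visible count). Scores lie in [0, 1]. Genes whose labels are hidden
#' never contribute to either sum, which is what makes cross-validation
#' leak-free.
#'
#' @param net A `coexpression_network` covering the annotation universe.
#' @param ann An [annotation_set()] with `universe` a subset of the
#'   network nodes.
#' @param labels_visible Genes whose annotations may be used (the training
#'   folds). Must be a nonempty subset of the universe.
#' @return Numeric matrix, network genes x terms, of voting scores.
#' @export
neighbor_voting_scores <- function(net, ann, labels_visible) {
  stopifnot(inherits(net, "coexpression_network"),
            inherits(ann, "annotation_set"))
  if (!all(ann$universe %in% net$nodes))
    stop("annotation universe must be a subset of the network nodes")
  labels_visible <- intersect(labels_visible, ann$universe)
  if (length(labels_visible) == 0L)
    stop("evaluation error: no visible labels")
  nodes <- net$nodes
  terms <- ann$terms
  L <- matrix(0, length(nodes), length(terms),
              dimnames = list(nodes, terms))
  mem <- ann$memberships
  L[cbind(match(mem$gene, nodes), match(mem$term, terms))] <- 1
  vis <- as.numeric(nodes %in% labels_visible)
  Lv <- L * vis
  W <- weight_matrix(net)
  num <- W %*% Lv
  den <- drop(W %*% vis)
  prior <- colSums(Lv) / sum(vis)
  scores <- num / ifelse(den > 0, den, 1)
  if (any(den == 0))
    scores[den == 0, ] <- matrix(prior, sum(den == 0), length(terms),
                                 byrow = TRUE)
  scores
}

#' Seeded cross-validation folds over genes
#'
#' Shuffles the genes with a seeded permutation and partitions them into
#' `n_folds` nearly equal folds (earlier folds get the remainder), so the
#' same seed always reproduces the same partition.
#'
#' @param genes Ordered gene ids.
#' @param n_folds Number of folds (default 3).
#' @param seed Integer seed for the permutation.
#' @return List of `n_folds` character vectors; disjoint, union = input.
#' @export
cv_split <- function(genes, n_folds = 3L, seed = 1L) {
  n <- length(genes)
  if (n_folds < 2L) stop("configuration error: n_folds must be >= 2")
  if (n_folds > n)
    stop("configuration error: more folds than genes")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  perm <- sample(genes)
  sizes <- rep(n %/% n_folds, n_folds)
  extra <- n %% n_folds
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  split(perm, rep(seq_len(n_folds), times = sizes))
}

#' ROC AUC by the Mann-Whitney rank statistic
#'
#' `AUC = (#{(p, n) pairs with score_p > score_n} + 0.5 * ties) /
#' (|pos| * |neg|)` — the probability that a random positive outranks a
#' random negative, computed via mid-ranks.
#'
#' @param scores Named numeric vector of prediction scores.
#' @param positives,negatives Disjoint, nonempty sets of names present in
#'   `scores`.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, positives, negatives) {
  if (length(positives) == 0L || length(negatives) == 0L)
    stop("positives and negatives must both be nonempty")
  if (length(intersect(positives, negatives)))
    stop("positives and negatives must be disjoint")
  s <- scores[c(positives, negatives)]
  if (anyNA(s)) stop("missing scores for some genes")
  r <- rank(s)  # mid-ranks handle ties as 0.5 per pair
  np <- length(positives); nn <- length(negatives)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' Cross-validated per-term prediction performance
#'
#' Runs `n_folds`-fold cross-validation over the annotation universe: in
#' each fold the held-out genes' annotations are hidden, neighbor-voting
#' scores are computed from the visible folds only, and each term's AUC is
#' taken over the held-out genes (held-out members = positives, held-out
#' non-members = negatives). A fold with no held-out positive or negative
#' for a term yields an undefined AUC, excluded from that term's mean with
#' a flag. Terms with fewer positives than folds are skipped. Each term's
#' AUC under the (non-cross-validated) multifunctionality ranking is
#' reported alongside as the annotation-bias baseline.
#'
#' @param net A `coexpression_network`.
#' @param ann A filtered [annotation_set()] whose universe is a subset of
#'   the network nodes.
#' @param n_folds Number of folds (default 3).
#' @param seed Seed for the fold permutation.
#' @param auc_threshold Strict cutoff defining optimal functions
#'   (default 0.7).
#' @return data.frame with one row per evaluated term: `term`,
#'   `in_count`, `auc_fold1..k`, `mean_auc`, `mf_auc`,
#'   `n_defined_folds`, `all_folds_defined`, `is_optimal`
#'   (`mean_auc > auc_threshold`, strict).
#' @export
evaluate_terms <- function(net, ann, n_folds = 3L, seed = 1L,
                           auc_threshold = 0.7) {
  stopifnot(inherits(net, "coexpression_network"),
            inherits(ann, "annotation_set"))
  genes <- ann$universe
  folds <- cv_split(genes, n_folds = n_folds, seed = seed)
  sz <- term_sizes(ann)
  skip <- sz$in_count < n_folds
  if (any(skip))
    warning("term(s) with fewer than ", n_folds,
            " annotated genes skipped: ",
            paste(sz$term[skip], collapse = ", "))
  terms <- sz$term[!skip]
  if (length(terms) == 0L) stop("no evaluable terms")
  members <- split(ann$memberships$gene, ann$memberships$term)

  fold_auc <- matrix(NA_real_, length(terms), n_folds,
                     dimnames = list(terms, NULL))
  for (f in seq_len(n_folds)) {
    held_out <- folds[[f]]
    visible <- setdiff(genes, held_out)
    scores <- neighbor_voting_scores(net, ann, visible)
    for (k in terms) {
      pos <- intersect(held_out, members[[k]])
      neg <- setdiff(held_out, members[[k]])
      if (length(pos) && length(neg))
        fold_auc[k, f] <- roc_auc(scores[, k], pos, neg)
    }
  }

  # multifunctionality baseline: one label-derived ranking for all terms
  mf <- multifunctionality_scores(ann)
  mf_scores <- stats::setNames(mf$mf_score, mf$gene)
  mf_auc <- vapply(terms, function(k) {
    pos <- members[[k]]
    neg <- setdiff(genes, pos)
    if (length(neg) == 0L) return(NA_real_)
    roc_auc(mf_scores, pos, neg)
  }, numeric(1))

  n_def <- rowSums(!is.na(fold_auc))
  mean_auc <- rowMeans(fold_auc, na.rm = TRUE)
  if (any(n_def == 0L))
    warning("term(s) with no defined fold AUC: ",
            paste(terms[n_def == 0L], collapse = ", "))
  mean_auc[n_def == 0L] <- NA_real_
  out <- data.frame(term = terms,
                    in_count = sz$in_count[!skip],
                    stringsAsFactors = FALSE)
  for (f in seq_len(n_folds))
    out[[paste0("auc_fold", f)]] <- fold_auc[, f]
  out$mean_auc <- unname(mean_auc)
  out$mf_auc <- unname(mf_auc)
  out$n_defined_folds <- unname(n_def)
  out$all_folds_defined <- out$n_defined_folds == n_folds
  out$is_optimal <- !is.na(out$mean_auc) & out$mean_auc > auc_threshold
  rownames(out) <- NULL
  out
}

#' Select optimal functions by cross-validated AUC
#'
#' Returns the terms whose mean cross-validated AUC strictly exceeds the
#' threshold (default 0.7), sorted by descending AUC — the "optimal
#' function" screening rule.
#'
#' @param perf Output of [evaluate_terms()].
#' @param auc_threshold Strict cutoff (default 0.7).
#' @return Subset of `perf`, possibly empty, sorted by `mean_auc`
#'   descending.
#' @export
select_optimal <- function(perf, auc_threshold = 0.7) {
  stopifnot(is.data.frame(perf), "mean_auc" %in% colnames(perf))
  sel <- perf[!is.na(perf$mean_auc) & perf$mean_auc > auc_threshold, ,
              drop = FALSE]
  sel <- sel[order(-sel$mean_auc, sel$term), , drop = FALSE]
  sel$is_optimal <- rep(TRUE, nrow(sel))
  rownames(sel) <- NULL
  sel
}

#' Histogram bins of per-term mean AUC
#'
#' @param perf Output of [evaluate_terms()].
#' @param bin_width Bin width on [0, 1] (default 0.05).
#' @return data.frame `bin_lo`, `bin_hi`, `count`.
#' @export
auc_histogram <- function(perf, bin_width = 0.05) {
  breaks <- seq(0, 1, by = bin_width)
  h <- graphics::hist(perf$mean_auc[!is.na(perf$mean_auc)],
                      breaks = breaks, plot = FALSE)
  data.frame(bin_lo = utils::head(h$breaks, -1L),
             bin_hi = utils::tail(h$breaks, -1L),
             count = h$counts)
}

#' Write tables from the prediction stage
#'
#' @param perf Output of [evaluate_terms()].
#' @param mf Output of [multifunctionality_scores()].
#' @param path Output path.
#' @name gba-export
NULL

#' @rdname gba-export
#' @export
write_term_performance <- function(perf, path) {
  utils::write.table(perf, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname gba-export
#' @export
write_mf_table <- function(mf, path) {
  utils::write.table(mf, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
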