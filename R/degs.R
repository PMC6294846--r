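#' Moderated two-sample t-test for differential expression
#'
#' Fits the two-group linear model gene by gene and shrinks the gene-wise
#' residual variances towards a common prior before forming the t
#' statistic, in the empirical-Bayes style standard for small microarray
#' cohorts. The gene-wise pooled variances s^2 (d residual df each) are
#' modelled as scaled inverse chi-square draws around a prior variance s0^2
#' with d0 prior df, so that marginally `s^2 / s0^2 ~ F(d, d0)`; `(d0,
#' s0^2)` are estimated by method of moments on that marginal. The
#' moderated variance is `s~^2 = (d0 s0^2 + d s^2) / (d0 + d)` and
#' `t = lfc / (s~ sqrt(1/n1 + 1/n2))` is referred to a t distribution on
#' `d + d0` degrees of freedom.
#'
#' With `moderate = FALSE` (d0 = 0) this is exactly the ordinary
#' pooled-variance two-sample t-test.
#'
#' @param em An [expression_matrix()]; log2-scale values, each group with
#'   at least two samples.
#' @param moderate Apply empirical-Bayes variance moderation (default
#'   `TRUE`).
#' @return A data.frame with one row per gene: `gene_id`,
#'   `log2_fold_change` (case minus control), `t_stat`, `p_value`,
#'   `neg_log10_p`, plus the fitted `d0` and `s0_sq` as attributes
#'   `"prior_df"` and `"prior_var"`.
#' @seealso [select_degs()] for applying the DEG thresholds.
#' @export
moderated_t_test <- function(em, moderate = TRUE) {
  stopifnot(inherits(em, "expression_matrix"))
  case <- em$values[, em$group == em$case, drop = FALSE]
  ctrl <- em$values[, em$group == em$control, drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2L || n2 < 2L)
    stop("design error: each group needs at least 2 samples")
  lfc <- rowMeans(case) - rowMeans(ctrl)
  v1 <- apply(case, 1L, stats::var)
  v2 <- apply(ctrl, 1L, stats::var)
  d <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d
  if (all(s2 == 0))
    stop("estimation error: zero residual variance in every gene")

  if (moderate) {
    prior <- fit_variance_prior(s2, d)
    d0 <- prior$d0; s0_sq <- prior$s0_sq
    s2_mod <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
      (d0 * s0_sq + d * s2) / (d0 + d)
    df_total <- d + d0
  } else {
    d0 <- 0; s0_sq <- NA_real_
    s2_mod <- s2
    df_total <- d
  }

  se <- sqrt(s2_mod * (1 / n1 + 1 / n2))
  t_stat <- ifelse(se > 0, lfc / se,
                   ifelse(lfc == 0, 0, sign(lfc) * Inf))
  p <- ifelse(is.finite(t_stat),
              2 * stats::pt(-abs(t_stat), df = df_total),
              ifelse(t_stat == 0 | is.nan(t_stat), 1, 0))
  # zero moderated variance with zero lfc: no evidence at all
  p[se == 0 & lfc == 0] <- 1

  out <- data.frame(gene_id = rownames(em$values),
                    log2_fold_change = unname(lfc),
                    t_stat = unname(t_stat),
                    p_value = unname(p),
                    neg_log10_p = unname(-log10(p)),
                    stringsAsFactors = FALSE)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s0_sq
  attr(out, "residual_df") <- d
  out
}

# Method-of-moments fit of the scaled-inverse-chi-square prior for the
# gene-wise variances: s2/s0^2 ~ F(d, d0), so CV^2(s2) = 2(d+d0-2)/(d(d0-4)).
# Solving for d0 from the sample CV^2 gives d0 in (4, Inf]; cv^2*d <= 2
# means no excess dispersion beyond chi-square sampling, i.e. d0 = Inf.
fit_variance_prior <- function(s2, d) {
  m <- mean(s2)
  v <- stats::var(s2)
  if (m <= 0) stop("estimation error: non-positive mean variance")
  cv2 <- v / m^2
  if (!is.finite(cv2) || cv2 * d <= 2) {
    return(list(d0 = Inf, s0_sq = m))
  }
  d0 <- (2 * d - 4 + 4 * cv2 * d) / (cv2 * d - 2)
  list(d0 = d0, s0_sq = m * (d0 - 2) / d0)
}

#' Select differentially expressed genes at fixed thresholds
#'
#' Flags genes passing both criteria strictly: `p_value < p_threshold` and
#' `|log2_fold_change| > lfc_threshold`. Both comparisons are strict, so a
#' gene sitting exactly on either boundary is not selected.
#'
#' @param records Output of [moderated_t_test()].
#' @param p_threshold Raw p-value cutoff (default 0.02). No multiplicity
#'   correction is applied by default; set `adjust = "BH"` to filter on
#'   Benjamini-Hochberg adjusted p-values instead.
#' @param lfc_threshold Absolute log2 fold-change cutoff (default 2).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return The input records with an `is_deg` logical column (and
#'   `p_adjusted` when `adjust != "none"`), sorted by ascending p-value.
#' @export
select_degs <- function(records, p_threshold = 0.02, lfc_threshold = 2,
                        adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(is.data.frame(records),
            all(c("gene_id", "log2_fold_change", "p_value") %in%
                  colnames(records)))
  p <- records$p_value
  if (adjust == "BH") {
    records$p_adjusted <- stats::p.adjust(p, method = "BH")
    p <- records$p_adjusted
  }
  records$is_deg <- (p < p_threshold) &
    (abs(records$log2_fold_change) > lfc_threshold)
  records <- records[order(records$p_value, records$gene_id), ,
                     drop = FALSE]
  rownames(records) <- NULL
  if (!any(records$is_deg))
    warning("no gene passes the DEG thresholds; ",
            "downstream network construction will fail")
  records
}

#' Write a DEG table as TSV
#' @param records Output of [select_degs()].
#' @param path Output path.
#' @export
write_deg_table <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
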