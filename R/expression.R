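#' Two-group expression matrix
#'
#' Container for a log2-scale gene x sample expression matrix with a
#' two-group design. This is the entry point of the pipeline: rows are
#' genes, columns are samples, and every sample carries one of exactly two
#' group labels (e.g. case placentas vs gestational-age-matched controls).
#'
#' @param values Numeric matrix, genes in rows and samples in columns, with
#'   unique non-empty rownames (gene ids) and colnames (sample ids). Values
#'   are log2-scale expression and must be finite.
#' @param group Character or factor of length `ncol(values)` giving each
#'   sample's group label; exactly two distinct labels, each with at least
#'   two samples.
#' @param case Which of the two labels is the case (disease) group. Fold
#'   changes downstream are case minus control. Defaults to the second
#'   distinct label in column order.
#'
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `group` (character), `case` and `control`.
#' @export
expression_matrix <- function(values, group, case = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids in `values`")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in `values`")
  if (!all(is.finite(values)))
    stop("expression values must be finite (no NA/NaN/Inf)")
  group <- as.character(group)
  if (length(group) != ncol(values))
    stop("`group` must have one label per sample column")
  labs <- unique(group)
  if (length(labs) != 2L)
    stop("exactly two distinct group labels are required, got ",
         length(labs))
  if (any(table(group) < 2L))
    stop("each group needs at least 2 samples")
  if (is.null(case)) case <- labs[2L]
  if (!case %in% labs)
    stop("`case` label '", case, "' not found among group labels")
  structure(
    list(values = values, group = group, case = case,
         control = setdiff(labs, case)),
    class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf(
    "expression_matrix: %d genes x %d samples (%s: %d, %s: %d)\n",
    nrow(x$values), ncol(x$values),
    x$case, sum(x$group == x$case),
    x$control, sum(x$group == x$control)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Write / read an expression matrix as TSV plus a design file
#'
#' The matrix file is tab-separated with a `gene_id` first column and one
#' column per sample. The design file has two lines, each
#' `<group_label>TAB<sample_id>TAB...`; the case group is the first line,
#' which fixes the fold-change orientation (case minus control) when the
#' files are read back.
#'
#' @param em An [expression_matrix()].
#' @param matrix_path,design_path Output (or input) file paths.
#' @return `write_expression` returns its paths invisibly;
#'   `read_expression` returns an [expression_matrix()].
#' @export
write_expression <- function(em, matrix_path, design_path) {
  stopifnot(inherits(em, "expression_matrix"))
  df <- data.frame(gene_id = rownames(em$values), em$values,
                   check.names = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  case_samples <- colnames(em$values)[em$group == em$case]
  ctrl_samples <- colnames(em$values)[em$group == em$control]
  lines <- c(paste(c(em$case, case_samples), collapse = "\t"),
             paste(c(em$control, ctrl_samples), collapse = "\t"))
  writeLines(lines, design_path)
  invisible(c(matrix = matrix_path, design = design_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(matrix_path, design_path) {
  df <- utils::read.table(matrix_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (colnames(df)[1L] != "gene_id")
    stop("matrix file must start with a 'gene_id' column")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  rownames(vals) <- df$gene_id
  dl <- readLines(design_path)
  dl <- dl[nzchar(dl)]
  if (length(dl) != 2L)
    stop("design file must have exactly two non-empty lines")
  parts <- strsplit(dl, "\t", fixed = TRUE)
  case_lab <- parts[[1L]][1L]
  ctrl_lab <- parts[[2L]][1L]
  sample_group <- c(
    stats::setNames(rep(case_lab, length(parts[[1L]]) - 1L), parts[[1L]][-1L]),
    stats::setNames(rep(ctrl_lab, length(parts[[2L]]) - 1L), parts[[2L]][-1L]))
  missing <- setdiff(colnames(vals), names(sample_group))
  if (length(missing))
    stop("samples missing from design file: ",
         paste(missing, collapse = ", "))
  expression_matrix(vals, group = unname(sample_group[colnames(vals)]),
                    case = case_lab)
}
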