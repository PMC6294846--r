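#' Gene-term annotation set
#'
#' Bipartite gene/term membership restricted to a gene universe. The
#' universe is the gene set against which "outside" counts are taken; for
#' the network analysis it is the DEG set forming the network, so that
#' `in_count(K) + out_count(K) = |universe|` for every term K.
#'
#' @param memberships data.frame with columns `gene` and `term` (extra
#'   columns such as `name` or `namespace` are carried along on the term
#'   table). Pairs whose gene is outside the universe are dropped;
#'   duplicate pairs are collapsed.
#' @param universe Character vector of gene ids.
#' @param term_names Optional named character vector of term display names.
#' @return An object of class `annotation_set`: list with `memberships`
#'   (deduplicated data.frame), `universe`, `terms` (term ids) and
#'   `term_names`.
#' @export
annotation_set <- function(memberships, universe, term_names = NULL) {
  stopifnot(is.data.frame(memberships),
            all(c("gene", "term") %in% colnames(memberships)))
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty gene universe")
  mem <- data.frame(gene = as.character(memberships$gene),
                    term = as.character(memberships$term),
                    stringsAsFactors = FALSE)
  mem <- mem[mem$gene %in% universe, , drop = FALSE]
  mem <- unique(mem)
  mem <- mem[order(mem$term, mem$gene), , drop = FALSE]
  rownames(mem) <- NULL
  structure(list(memberships = mem,
                 universe = universe,
                 terms = sort(unique(mem$term)),
                 term_names = term_names),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf(
    "annotation_set: %d terms, %d gene-term pairs, universe of %d genes\n",
    length(x$terms), nrow(x$memberships), length(x$universe)))
  invisible(x)
}

#' Per-term in/out gene counts
#'
#' @param ann An [annotation_set()].
#' @return data.frame `term`, `in_count`, `out_count` with
#'   `in_count + out_count == length(ann$universe)` for every term.
#' @export
term_sizes <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  tab <- table(factor(ann$memberships$term, levels = ann$terms))
  data.frame(term = names(tab),
             in_count = as.integer(tab),
             out_count = length(ann$universe) - as.integer(tab),
             stringsAsFactors = FALSE)
}

#' Load gene-term annotations from GAF or two-column TSV
#'
#' GAF 2.x: comment lines starting with `!` are skipped, the gene symbol
#' (column 3) and GO id (column 5) are used, and rows whose qualifier
#' (column 4) contains `NOT` are dropped per GAF semantics. Two-column
#' format: `gene<TAB>term`, no header. Memberships are restricted to the
#' given universe and deduplicated.
#'
#' @param path Annotation file.
#' @param format `"two_column"` or `"gaf"`.
#' @param universe Gene ids to restrict to.
#' @return An [annotation_set()].
#' @export
load_annotations <- function(path, format = c("two_column", "gaf"),
                             universe) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  if (format == "gaf") {
    keep <- !startsWith(lines, "!") & nzchar(lines)
    rows <- strsplit(lines[keep], "\t", fixed = TRUE)
    lineno <- which(keep)
    bad <- which(vapply(rows, length, 1L) < 15L)
    if (length(bad))
      stop("malformed GAF line ", lineno[bad[1L]],
           ": fewer than 15 columns")
    gene <- vapply(rows, `[[`, "", 3L)
    qual <- vapply(rows, `[[`, "", 4L)
    term <- vapply(rows, `[[`, "", 5L)
    not <- vapply(strsplit(qual, "|", fixed = TRUE),
                  function(q) any(q == "NOT"), TRUE)
    mem <- data.frame(gene = gene[!not], term = term[!not],
                      stringsAsFactors = FALSE)
  } else {
    keep <- nzchar(lines)
    rows <- strsplit(lines[keep], "\t", fixed = TRUE)
    lineno <- which(keep)
    bad <- which(vapply(rows, length, 1L) != 2L)
    if (length(bad))
      stop("malformed line ", lineno[bad[1L]],
           ": expected gene<TAB>term")
    mem <- data.frame(gene = vapply(rows, `[[`, "", 1L),
                      term = vapply(rows, `[[`, "", 2L),
                      stringsAsFactors = FALSE)
  }
  ann <- annotation_set(mem, universe)
  if (nrow(ann$memberships) == 0L)
    stop("data error: no annotation overlaps the gene universe")
  ann
}

#' Filter annotation terms by the number of annotated universe genes
#'
#' Keeps terms annotating strictly more than `min_genes` universe genes
#' ("more than 20" by default), dropping sparser terms whose
#' cross-validated evaluation would be unstable. The universe is
#' unchanged; the operation is idempotent.
#'
#' @param ann An [annotation_set()].
#' @param min_genes Strict lower bound on the in-count (default 20).
#' @param comparator Comparison function (default `` `>` ``; supply
#'   `` `>=` `` for an inclusive filter).
#' @return A filtered [annotation_set()].
#' @export
filter_terms <- function(ann, min_genes = 20L, comparator = `>`) {
  stopifnot(inherits(ann, "annotation_set"))
  sz <- term_sizes(ann)
  keep <- sz$term[comparator(sz$in_count, min_genes)]
  if (length(keep) == 0L)
    stop("data error: no term has more than ", min_genes,
         " annotated genes; consider a smaller min_genes")
  out <- annotation_set(
    ann$memberships[ann$memberships$term %in% keep, , drop = FALSE],
    ann$universe, term_names = ann$term_names)
  out$coherent_terms <- intersect(ann$coherent_terms, out$terms)
  out
}

#' Write annotations as two-column TSV or GAF 2.2
#'
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @param format `"two_column"` (gene<TAB>term) or `"gaf"` (a minimal
#'   synthetic GAF 2.2 with IEA evidence).
#' @export
write_annotations <- function(ann, path,
                              format = c("two_column", "gaf")) {
  format <- match.arg(format)
  stopifnot(inherits(ann, "annotation_set"))
  mem <- ann$memberships
  if (format == "two_column") {
    utils::write.table(mem[, c("gene", "term")], path, sep = "\t",
                       quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  } else {
    fields <- cbind("SYNTH", mem$gene, mem$gene, "", mem$term,
                    "SYNTH_REF:0000001", "IEA", "", "P", "", "",
                    "gene", "taxon:9606", "20180101", "SYNTH", "", "")
    lines <- c("!gaf-version: 2.2",
               apply(fields, 1L, paste, collapse = "\t"))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Write the retained-term table as TSV
#' @param ann An [annotation_set()].
#' @param path Output path.
#' @export
write_term_table <- function(ann, path) {
  sz <- term_sizes(ann)
  if (!is.null(ann$term_names))
    sz$name <- unname(ann$term_names[sz$term])
  utils::write.table(sz, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
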