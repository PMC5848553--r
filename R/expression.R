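#' Construct an expression matrix container
#'
#' Holds linear-scale RPKM expression values as a samples-by-genes matrix plus
#' per-sample metadata (cohort code, tumor/normal flag, free clinical fields).
#'
#' @param values Numeric matrix, samples in rows, genes in columns, with
#'   dimnames. Values must be non-negative and finite.
#' @param sample_meta Optional data frame with a \code{sample} column matching
#'   the row names of \code{values}; a \code{cohort} code and logical
#'   \code{tumor} flag are filled with defaults (\code{"COHORT"},
#'   \code{TRUE}) when absent.
#' @return An object of class \code{rpt_expression}: a list with elements
#'   \code{values}, \code{sample_ids}, \code{gene_ids}, \code{sample_meta}.
#' @export
expression_matrix <- function(values, sample_meta = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_ribotype("expression values need sample row names and gene column names")
  if (anyDuplicated(colnames(values)))
    stop_ribotype("duplicate gene ids: ",
                  paste(unique(colnames(values)[duplicated(colnames(values))]),
                        collapse = ", "))
  if (anyNA(values)) stop_ribotype("expression matrix contains missing values")
  if (any(values < 0)) stop_ribotype("expression matrix contains negative values")
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample = rownames(values), stringsAsFactors = FALSE)
  }
  if (!"sample" %in% names(sample_meta))
    stop_ribotype("sample_meta needs a 'sample' column")
  sample_meta <- sample_meta[match(rownames(values), sample_meta$sample), ,
                             drop = FALSE]
  if (anyNA(sample_meta$sample))
    stop_ribotype("sample_meta does not cover all samples")
  rownames(sample_meta) <- NULL
  if (!"cohort" %in% names(sample_meta)) sample_meta$cohort <- "COHORT"
  if (!"tumor" %in% names(sample_meta)) sample_meta$tumor <- TRUE
  structure(list(values = values,
                 sample_ids = rownames(values),
                 gene_ids = colnames(values),
                 sample_meta = sample_meta),
            class = "rpt_expression")
}

#' @export
print.rpt_expression <- function(x, ...) {
  cat("Expression matrix:", length(x$sample_ids), "samples x",
      length(x$gene_ids), "genes;",
      length(unique(x$sample_meta$cohort)), "cohort(s)\n")
  invisible(x)
}

#' Read an expression table from TSV
#'
#' Reads a tab-separated expression table in the UCSC-Xena convention (gene
#' rows, sample columns, first column gene symbol) or its transpose, and
#' converts values to the linear RPKM scale. The storage dialect is an
#' explicit argument, never guessed: Xena stores \code{log2(RPKM + 1)}
#' (\code{"log2_plus1"}), some exports store plain \code{log2(RPKM)}
#' (\code{"log2"}), and \code{"linear"} passes values through.
#'
#' @param path Path to the TSV file.
#' @param dialect One of \code{"log2_plus1"} (default; applies
#'   \code{2^v - 1}), \code{"log2"} (applies \code{2^v}) or \code{"linear"}.
#' @param orientation \code{"genes_in_rows"} (Xena) or \code{"samples_in_rows"}.
#' @param sample_meta Optional per-sample metadata data frame (see
#'   \code{\link{expression_matrix}}).
#' @return An \code{\link{expression_matrix}} on the linear scale.
#' @details Missing cells are an error, as are duplicate gene symbols.
#'   Negative linear values arising from round-off (magnitude at most 1e-9)
#'   are clamped to zero with a warning; larger negatives are an error.
#' @export
load_expression_table <- function(path,
                                  dialect = c("log2_plus1", "log2", "linear"),
                                  orientation = c("genes_in_rows",
                                                  "samples_in_rows"),
                                  sample_meta = NULL) {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop_ribotype("cannot read expression table '", path, "'")
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop_ribotype("expression table '", path, "' has no sample columns")
  ids <- trimws(as.character(tab[[1L]]))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (orientation == "genes_in_rows") m <- t(m)
  if (anyDuplicated(colnames(m)))
    stop_ribotype("duplicate gene ids in '", path, "': ",
                  paste(unique(colnames(m)[duplicated(colnames(m))]),
                        collapse = ", "))
  if (anyNA(m)) stop_ribotype("missing cells in expression table '", path, "'")
  m <- switch(dialect,
              log2_plus1 = 2^m - 1,
              log2 = 2^m,
              linear = m)
  if (any(m < 0)) {
    worst <- min(m)
    if (worst < -1e-9)
      stop_ribotype("negative linear expression after '", dialect,
                    "' transform (min ", format(worst), ")")
    warning("clamping ", sum(m < 0), " slightly negative value(s) to 0",
            call. = FALSE)
    m[m < 0] <- 0
  }
  expression_matrix(m, sample_meta = sample_meta)
}

#' Write an expression table as TSV
#'
#' Inverse of \code{\link{load_expression_table}}: writes the Xena-style
#' gene-rows TSV in the requested storage dialect.
#'
#' @param x An \code{rpt_expression} object.
#' @param path Output path.
#' @param dialect Storage dialect (see \code{\link{load_expression_table}}).
#' @param orientation Table orientation on disk.
#' @return \code{path}, invisibly.
#' @export
write_expression_table <- function(x, path,
                                   dialect = c("log2_plus1", "log2", "linear"),
                                   orientation = c("genes_in_rows",
                                                   "samples_in_rows")) {
  dialect <- match.arg(dialect)
  orientation <- match.arg(orientation)
  m <- x$values
  m <- switch(dialect,
              log2_plus1 = log2(m + 1),
              log2 = log2(m),
              linear = m)
  if (orientation == "genes_in_rows") {
    out <- data.frame(gene = colnames(x$values), t(m), check.names = FALSE)
  } else {
    out <- data.frame(sample = rownames(x$values), m, check.names = FALSE)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict an expression matrix to the RP gene registry
#'
#' Keeps only registry genes, in registry order. Genes absent from the table
#' are reported via the \code{missing_genes} attribute (and a message); if the
#' fraction found falls below \code{min_found} the extraction fails.
#'
#' @param x An \code{rpt_expression} object.
#' @param registry An \code{\link{rp_registry}} (default: packaged 80 genes).
#' @param min_found Minimum fraction of registry genes that must be present
#'   (default 0.95).
#' @return An \code{rpt_expression} restricted to the registry genes, with
#'   attribute \code{missing_genes}.
#' @export
extract_rp_expression <- function(x, registry = rp_registry(),
                                  min_found = 0.95) {
  stopifnot(inherits(x, "rpt_expression"))
  genes <- registry$gene
  if (length(genes) == 0L) stop_ribotype("empty registry")
  found <- genes[genes %in% x$gene_ids]
  missing <- setdiff(genes, found)
  if (length(found) == 0L)
    stop_ribotype("no registry genes found in the expression table")
  coverage <- length(found) / length(genes)
  if (coverage < min_found)
    stop_ribotype("only ", length(found), "/", length(genes),
                  " registry genes found (", round(coverage, 3),
                  " < min_found ", min_found, ")")
  if (length(missing) > 0L)
    message("registry genes absent from table: ",
            paste(missing, collapse = ", "))
  out <- expression_matrix(x$values[, found, drop = FALSE],
                           sample_meta = x$sample_meta)
  attr(out, "missing_genes") <- missing
  out
}

#' Relative (compositional) RPT expression
#'
#' The package's core statistic: each sample's RPKM for every RP gene divided
#' by that sample's summed RPKM over all RP genes, so each sample becomes a
#' composition on the simplex (fractions summing to 1). Relative expression is
#' invariant to per-sample scale (library size).
#'
#' @param x An \code{rpt_expression} object (linear scale).
#' @return An object of class \code{rpt_relexpr}: list with \code{fractions}
#'   (samples x genes, rows summing to 1), \code{sample_ids}, \code{gene_ids},
#'   \code{sample_meta}.
#' @examples
#' m <- matrix(c(2, 3, 5), 1, dimnames = list("s1", c("g1", "g2", "g3")))
#' relative_expression(expression_matrix(m))$fractions  # 0.2 0.3 0.5
#' @export
relative_expression <- function(x) {
  stopifnot(inherits(x, "rpt_expression"))
  totals <- rowSums(x$values)
  zero <- totals <= 0
  if (any(zero))
    stop_ribotype("sample(s) with all-zero RP expression: ",
                  paste(x$sample_ids[zero], collapse = ", "))
  fr <- x$values / totals
  structure(list(fractions = fr,
                 sample_ids = x$sample_ids,
                 gene_ids = x$gene_ids,
                 sample_meta = x$sample_meta),
            class = "rpt_relexpr")
}

#' @export
print.rpt_relexpr <- function(x, ...) {
  cat("Relative RPT expression:", length(x$sample_ids), "samples x",
      length(x$gene_ids), "genes (rows sum to 1)\n")
  invisible(x)
}
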