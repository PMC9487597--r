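#' Construct a gene-by-cell count matrix
#'
#' The raw container for one dataset: non-negative read or UMI counts with
#' unique gene and cell identifiers and a platform/batch tag (for example
#' `"SS2"` or `"10X"`).
#'
#' @param values numeric matrix or `Matrix::sparseMatrix`, genes in rows,
#'   cells in columns, non-negative entries.
#' @param gene_ids character vector of unique gene identifiers, one per row.
#' @param cell_ids character vector of unique cell identifiers, one per
#'   column.
#' @param platform single string tagging the platform or batch of origin.
#' @return an object of class `count_matrix`.
#' @examples
#' cm <- count_matrix(matrix(c(0, 1, 2, 0, 5, 5), nrow = 3, byrow = TRUE),
#'                    gene_ids = c("g1", "g2", "g3"),
#'                    cell_ids = c("c1", "c2"), platform = "SS2")
#' dim(cm$values)
#' @export
count_matrix <- function(values, gene_ids, cell_ids, platform = "batch") {
  .stop_if(length(gene_ids) != nrow(values),
           "gene_ids length does not match the number of rows")
  .stop_if(length(cell_ids) != ncol(values),
           "cell_ids length does not match the number of columns")
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  .stop_if(length(dup_g) > 0, "duplicate gene ids: ",
           paste(utils::head(dup_g, 10), collapse = ", "))
  dup_c <- unique(cell_ids[duplicated(cell_ids)])
  .stop_if(length(dup_c) > 0, "duplicate cell ids: ",
           paste(utils::head(dup_c, 10), collapse = ", "))
  .stop_if(min(values) < 0, "negative entries are not valid counts")
  dimnames(values) <- list(gene_ids, cell_ids)
  structure(list(values = values,
                 gene_ids = as.character(gene_ids),
                 cell_ids = as.character(cell_ids),
                 platform = as.character(platform)[1]),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d cells [%s], %s storage\n",
              nrow(x$values), ncol(x$values), x$platform,
              if (methods::is(x$values, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' Read a count matrix from disk
#'
#' Supports the 10x-style Matrix Market triplet (`matrix.mtx` with
#' co-located `genes.tsv` and `barcodes.tsv`) and dense CSV/TSV with a
#' header row of cell ids and the gene id in the first column.
#'
#' @param path path to the `.mtx` file (or its directory) or to the
#'   CSV/TSV file.
#' @param format one of `"mtx"`, `"csv"`, `"tsv"`; guessed from the file
#'   extension when missing.
#' @param platform platform/batch tag attached to the result.
#' @return a [count_matrix].
#' @export
read_counts <- function(path, format = c("guess", "mtx", "csv", "tsv"),
                        platform = "batch") {
  format <- match.arg(format)
  if (format == "guess") {
    format <- if (dir.exists(path)) "mtx" else
      switch(tolower(tools::file_ext(path)),
             mtx = "mtx", csv = "csv", tsv = "tsv", txt = "tsv",
             stop("cannot guess format from '", path, "'; pass format="))
  }
  .stop_if(!file.exists(path), "path does not exist: ", path)
  if (format == "mtx") {
    dirn <- if (dir.exists(path)) path else dirname(path)
    mtx <- if (dir.exists(path)) file.path(path, "matrix.mtx") else path
    genes_f <- file.path(dirn, "genes.tsv")
    barcodes_f <- file.path(dirn, "barcodes.tsv")
    .stop_if(!file.exists(genes_f), "missing gene sidecar: ", genes_f)
    .stop_if(!file.exists(barcodes_f), "missing barcode sidecar: ", barcodes_f)
    values <- tryCatch(methods::as(Matrix::readMM(mtx), "CsparseMatrix"),
                       error = function(e)
                         stop("malformed Matrix Market file '", mtx, "': ",
                              conditionMessage(e), call. = FALSE))
    genes <- utils::read.delim(genes_f, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    barcodes <- utils::read.delim(barcodes_f, header = FALSE,
                                  stringsAsFactors = FALSE)[[1]]
    return(count_matrix(values, genes, barcodes, platform))
  }
  sep <- if (format == "csv") "," else "\t"
  tab <- tryCatch(utils::read.table(path, header = TRUE, sep = sep,
                                    row.names = NULL, check.names = FALSE,
                                    stringsAsFactors = FALSE),
                  error = function(e)
                    stop("malformed ", format, " file '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  gene_ids <- as.character(tab[[1]])
  values <- as.matrix(tab[, -1, drop = FALSE])
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  .stop_if(nrow(bad) > 0,
           sprintf("invalid count at data line %d (gene '%s')",
                   bad[1, 1], gene_ids[bad[1, 1]]))
  count_matrix(values, gene_ids, colnames(values), platform)
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts()]: `mtx` writes the Matrix Market triplet into a
#' directory, `csv`/`tsv` a dense table with gene ids in the first column.
#'
#' @param cm a [count_matrix].
#' @param path output directory (mtx) or file (csv/tsv).
#' @param format one of `"mtx"`, `"csv"`, `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(cm, path, format = c("mtx", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(methods::as(cm$values, "dMatrix"),
                                "CsparseMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(cm$gene_ids, file.path(path, "genes.tsv"))
    writeLines(cm$cell_ids, file.path(path, "barcodes.tsv"))
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  tab <- data.frame(gene = cm$gene_ids, .dense(cm$values),
                    check.names = FALSE)
  colnames(tab) <- c("gene", cm$cell_ids)
  utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
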