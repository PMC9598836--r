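#' Read a genes-by-samples expression matrix from delimited text
#'
#' Expression files are plain text with the first row holding sample IDs,
#' the first column holding gene IDs, and one row per gene.  Empty cells
#' are read as missing (`NA`), never as zero: downstream filtering decides
#' what happens to genes with missing entries.
#'
#' @param path Path to an existing TSV/CSV file.
#' @param delimiter Field separator, `"\t"` (default) or `","`.
#' @return A numeric matrix (genes x samples) with `rownames` = gene IDs
#'   and `colnames` = sample IDs.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 3, 2, dimnames = list(c("G1", "G2", "G3"), c("S1", "S2")))
#' write_expression_matrix(m, tf)
#' read_expression_matrix(tf)
#' @seealso [write_expression_matrix()], [filter_genes()], [log_normalize()]
#' @export
read_expression_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("expression file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("expression file is empty: ", path)
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1L]]
  sample_ids <- header[-1L]
  n_col <- length(header)
  body <- fields[-1L]
  gene_ids <- character(length(body))
  values <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids))
  for (i in seq_along(body)) {
    row <- body[[i]]
    # a trailing empty cell is dropped by strsplit; restore it
    if (length(row) == n_col - 1L &&
        substring(lines[[i + 1L]], nchar(lines[[i + 1L]])) == delimiter) {
      row <- c(row, "")
    }
    if (length(row) != n_col) {
      stop("ragged row in ", path, " at line ", i + 1L, ": expected ",
           n_col, " fields, found ", length(row))
    }
    gene_ids[i] <- row[1L]
    cells <- row[-1L]
    cells[cells == ""] <- NA_character_
    values[i, ] <- suppressWarnings(as.numeric(cells))
    bad <- which(!is.na(cells) & is.na(values[i, ]))
    if (length(bad)) {
      stop("non-numeric cell in ", path, " at line ", i + 1L,
           ", column ", bad[1L] + 1L, ": '", cells[bad[1L]], "'")
    }
  }
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup)) stop("duplicate gene ID(s): ", paste(dup, collapse = ", "))
  dup <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup)) stop("duplicate sample ID(s): ", paste(dup, collapse = ", "))
  dimnames(values) <- list(gene_ids, sample_ids)
  values
}

#' Write an expression matrix as delimited text
#'
#' Inverse of [read_expression_matrix()]: full double precision, `NA`
#' written as an empty cell.
#'
#' @param m Numeric matrix with gene-ID rownames and sample-ID colnames.
#' @param path Output file path.
#' @param delimiter Field separator.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, delimiter = "\t") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  fmt <- function(x) {
    out <- formatC(x, digits = 17, format = "g")
    out[is.na(x)] <- ""
    out
  }
  header <- paste(c("gene_id", colnames(m)), collapse = delimiter)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], fmt(m[i, ])), collapse = delimiter)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Filter genes by missingness and zero-majority
#'
#' Applies the two raw-scale gene filters used before log normalization:
#' a gene is dropped if it has any missing value, or if its number of
#' zero entries strictly exceeds half of the training samples.  Ties
#' (zero count exactly n/2) are kept.  Gene order is preserved.
#'
#' @param m Raw-scale expression matrix (genes x samples).
#' @param n_train Number of training samples the zero rule is evaluated
#'   against; defaults to `ncol(m)`.
#' @return The matrix restricted to surviving genes.
#' @export
filter_genes <- function(m, n_train = ncol(m)) {
  stopifnot(is.matrix(m), n_train >= 1)
  has_missing <- apply(m, 1L, anyNA)
  zero_count <- rowSums(m == 0, na.rm = TRUE)
  keep <- !has_missing & (zero_count <= n_train / 2)
  if (!any(keep)) stop("all ", nrow(m), " genes removed by filtering")
  m[keep, , drop = FALSE]
}

#' Log-normalize an expression matrix
#'
#' Replaces every entry x by `log(x + 1)` in the chosen base; `log2` is
#' the default (the usual RNA-seq pseudo-count convention, under which
#' 0 -> 0, 1 -> 1, 7 -> 3).
#'
#' @param m Non-negative matrix with no missing values (run
#'   [filter_genes()] first).
#' @param base `"log2"`, `"ln"` or `"log10"`.
#' @return Matrix of the same shape and dimnames.
#' @export
log_normalize <- function(m, base = c("log2", "ln", "log10")) {
  base <- match.arg(base)
  if (anyNA(m)) stop("missing values present; filter genes before log normalization")
  if (any(m < 0)) stop("negative expression value at raw scale")
  switch(base,
    log2  = log2(m + 1),
    ln    = log1p(m),
    log10 = log10(m + 1)
  )
}
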