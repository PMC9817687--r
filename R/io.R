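#' Read an expression matrix from TSV
#'
#' Rectangular TSV: first column feature ids, header of sample ids. The
#' string `NA` marks missing cells and is accepted on protein layers only;
#' an `NA` in a counts/tpm layer is a contract violation and errors.
#'
#' @param path TSV path.
#' @param layer layer tag (see [expression_matrix()]).
#' @return `ExpressionMatrix`.
#' @export
read_expression_tsv <- function(path, layer) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                   na.strings = "NA")
  abort_if(ncol(df) < 2L, "expected feature id column plus >= 1 sample")
  ids <- as.character(df[[1]])
  dup <- unique(ids[duplicated(ids)])
  abort_if(length(dup) > 0L, "duplicate feature id(s): ",
           paste(head(dup, 5), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  abort_if(!is.numeric(m), "non-numeric cells in ", path)
  rownames(m) <- ids
  expression_matrix(m, layer)
}

#' Write an expression matrix to TSV
#'
#' Missing cells are written as `NA`; [read_expression_tsv()] round-trips
#' values and mask exactly (full double precision).
#'
#' @param mat `ExpressionMatrix`.
#' @param path output path.
#' @export
write_expression_tsv <- function(mat, path) {
  v <- em_values(mat)
  df <- data.frame(feature_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write the sample design table
#'
#' @param path TSV path with the [validate_design()] columns.
#' @return validated design data.frame.
#' @export
read_design_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  validate_design(d)
  d
}

#' @rdname read_design_tsv
#' @param design design data.frame.
#' @export
write_design_tsv <- function(design, path) {
  write.table(design, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CETSA dose-response CSV
#'
#' Expected columns: `agonist_dose`, `antagonist_conc`, `replicate`,
#' `signal`. Concentrations are interpreted in the given unit and
#' converted to molar.
#'
#' @param path CSV path.
#' @param unit concentration unit of the dose columns: `"M"`, `"mM"`,
#'   `"uM"` or `"nM"`.
#' @return `CetsaDataset` data.frame in molar units.
#' @export
read_cetsa_csv <- function(path, unit = c("M", "mM", "uM", "nM")) {
  unit <- match.arg(unit)
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)[[unit]]
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("agonist_dose", "antagonist_conc", "replicate", "signal")
  abort_if(!all(need %in% names(df)), "CETSA CSV needs columns ",
           paste(need, collapse = ", "))
  df$agonist_dose <- df$agonist_dose * scale
  df$antagonist_conc <- df$antagonist_conc * scale
  structure(df, class = c("CetsaDataset", "data.frame"))
}

#' @rdname read_cetsa_csv
#' @param data `CetsaDataset` in molar units (written as-is).
#' @export
write_cetsa_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read/write gene lengths
#'
#' Two-column TSV: `feature_id`, `length` (bases).
#'
#' @param path TSV path.
#' @return named numeric vector.
#' @export
read_gene_lengths_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  abort_if(!all(c("feature_id", "length") %in% names(df)),
           "gene-length TSV needs feature_id and length columns")
  abort_if(any(df$length <= 0), "gene lengths must be > 0")
  setNames(df$length, df$feature_id)
}

#' @rdname read_gene_lengths_tsv
#' @param lengths named numeric vector of lengths.
#' @export
write_gene_lengths_tsv <- function(lengths, path) {
  write.table(data.frame(feature_id = names(lengths),
                         length = as.vector(lengths)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_tsv_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
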