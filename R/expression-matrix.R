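#' Expression matrix for one assay layer
#'
#' A light container for a features x samples numeric matrix together with a
#' `layer` tag that records what the values are. RNA layers (`"counts"`,
#' `"tpm"`) must be complete and non-negative; protein layers
#' (`"intensity"`, `"log2_intensity"`, `"ibaq"`) may carry `NA` cells, which
#' represent non-detection (missing not at random) rather than zero.
#'
#' @param values numeric matrix with feature row names and sample column
#'   names.
#' @param layer one of `"counts"`, `"tpm"`, `"intensity"`,
#'   `"log2_intensity"`, `"ibaq"`.
#' @return an `ExpressionMatrix`: the matrix with a `layer` attribute and
#'   class `"ExpressionMatrix"`.
#' @examples
#' m <- matrix(rpois(6, 50), 3, 2,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:2)))
#' em <- expression_matrix(m, "counts")
#' em_layer(em)
#' @export
expression_matrix <- function(values, layer) {
  layer <- match.arg(layer, c("counts", "tpm", "intensity",
                              "log2_intensity", "ibaq"))
  abort_if(!is.matrix(values) || !is.numeric(values),
           "`values` must be a numeric matrix")
  abort_if(is.null(rownames(values)) || is.null(colnames(values)),
           "`values` must have feature row names and sample column names")
  abort_if(anyDuplicated(rownames(values)) > 0L,
           "duplicated feature ids: ",
           paste(unique(rownames(values)[duplicated(rownames(values))]),
                 collapse = ", "))
  abort_if(anyDuplicated(colnames(values)) > 0L, "duplicated sample ids")
  if (!is_protein_layer(layer)) {
    abort_if(anyNA(values),
             "missing values are only allowed on protein layers, not ",
             layer)
    abort_if(any(values < 0), layer, " values must be non-negative")
    if (layer == "counts") {
      abort_if(any(values != floor(values)), "counts must be integers")
    }
  }
  structure(values, layer = layer, class = c("ExpressionMatrix", "matrix"))
}

is_protein_layer <- function(layer) {
  layer %in% c("intensity", "log2_intensity", "ibaq")
}

#' @rdname expression_matrix
#' @param x an `ExpressionMatrix`.
#' @export
em_layer <- function(x) {
  abort_if(!inherits(x, "ExpressionMatrix"), "not an ExpressionMatrix")
  attr(x, "layer")
}

#' @rdname expression_matrix
#' @export
em_values <- function(x) {
  abort_if(!inherits(x, "ExpressionMatrix"), "not an ExpressionMatrix")
  y <- unclass(x)
  attr(y, "layer") <- NULL
  y
}

#' @export
`[.ExpressionMatrix` <- function(x, i, j, ..., drop = FALSE) {
  expression_matrix(em_values(x)[i, j, ..., drop = FALSE], em_layer(x))
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  v <- em_values(x)
  cat(sprintf("ExpressionMatrix [%s]: %d features x %d samples, %d missing\n",
              em_layer(x), nrow(v), ncol(v), sum(is.na(v))))
  print(v[seq_len(min(5L, nrow(v))), seq_len(min(5L, ncol(v))), drop = FALSE])
  invisible(x)
}

# Internal constructor bypassing re-validation for hot paths where the
# values are already known valid (same layer, same dimnames discipline).
new_em <- function(values, layer) {
  structure(values, layer = layer, class = c("ExpressionMatrix", "matrix"))
}

#' Validate a sample design table
#'
#' The design maps each sample to its treatment condition, timepoint,
#' replicate and assay. Conditions follow the three-arm perturbation design:
#' vehicle control, agonist, and agonist plus antagonist.
#'
#' @param design data.frame with columns `sample_id`, `condition`
#'   (`vehicle`/`agonist`/`agonist_antagonist`), `timepoint`
#'   (`early`/`late`), `replicate`, `assay` (`rna`/`protein`).
#' @return the validated design, invisibly unchanged.
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "condition", "timepoint", "replicate", "assay")
  abort_if(!is.data.frame(design) || !all(need %in% names(design)),
           "design must have columns ", paste(need, collapse = ", "))
  abort_if(anyDuplicated(design$sample_id) > 0L, "duplicated sample ids")
  abort_if(!all(design$condition %in% c("vehicle", "agonist",
                                        "agonist_antagonist")),
           "unknown condition in design")
  abort_if(!all(design$timepoint %in% c("early", "late")),
           "unknown timepoint in design")
  abort_if(!all(design$assay %in% c("rna", "protein")),
           "unknown assay in design")
  cells <- table(design$condition, design$timepoint, design$assay)
  abort_if(any(cells[cells > 0] < 2L),
           "every occupied (condition, timepoint, assay) cell needs >= 2 replicates")
  invisible(design)
}
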