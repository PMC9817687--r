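#' Read a GMT gene-set file
#'
#' One set per line: name, description, then member ids, tab-separated.
#' Duplicate members within a set are removed with a warning.
#'
#' @param path GMT file path.
#' @return `GeneSetCollection`: named list of member vectors with a
#'   `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    abort_if(length(f) < 3L, "GMT line ", i, " has fewer than 3 fields")
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set ", f[1], " deduplicated",
              call. = FALSE)
      members <- unique(members)
    }
    sets[[f[1]]] <- members
    desc[f[1]] <- f[2]
  }
  structure(sets, description = desc, class = "GeneSetCollection")
}

#' Write a GMT gene-set file
#'
#' @param sets `GeneSetCollection` (or plain named list).
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes from a
#' universe of `N` containing `K` set members. Computed by exact summation
#' of the point probabilities on the log scale.
#'
#' @param k observed overlap.
#' @param K set size within the universe.
#' @param n query size.
#' @param N universe size.
#' @return upper-tail p-value in `(0, 1]`.
#' @export
hypergeom_tail <- function(k, K, n, N) {
  ok <- k >= 0 && K >= 0 && n >= 0 && N >= 0 &&
    k <= min(K, n) && K <= N && n <= N
  abort_if(!ok, "inconsistent hypergeometric counts")
  if (k == 0) return(1)
  i <- k:min(K, n)
  logp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  min(1, sum(exp(logp)))
}

#' Select two-fold-regulated features
#'
#' @param diff a `DiffTable`.
#' @param lfc_threshold log2 fold-change cutoff (default 1, i.e. two-fold).
#' @param direction `"up"` (`log2fc >= threshold`) or `"down"`
#'   (`log2fc <= -threshold`); thresholds inclusive.
#' @return character vector of feature ids.
#' @export
select_regulated <- function(diff, lfc_threshold = 1,
                             direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (nrow(diff) == 0L) return(character())
  keep <- if (direction == "up") diff$log2fc >= lfc_threshold
          else diff$log2fc <= -lfc_threshold
  diff$feature_id[keep]
}

#' Over-representation test of a query list against gene sets
#'
#' One hypergeometric upper-tail test per set, with set membership
#' restricted to the universe, followed by BH adjustment across sets. Sets
#' with no member in the universe are skipped with a warning.
#'
#' @param query feature ids of interest (must be within the universe).
#' @param universe background feature ids (typically all features entering
#'   the concordance fit).
#' @param sets `GeneSetCollection`.
#' @param fdr_threshold significance flag cutoff (default 0.25).
#' @return `EnrichmentTable` data.frame: per set `k`, `K`, `n`, `N`, `p`,
#'   `fdr`, `significant`.
#' @export
enrich <- function(query, universe, sets, fdr_threshold = 0.25) {
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  abort_if(length(outside) > 0L, "query ids outside the universe: ",
           paste(head(outside, 5), collapse = ", "))
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    if (length(members) == 0L) {
      warning("set ", nm, " disjoint from universe, skipped",
              call. = FALSE)
      return(NULL)
    }
    K <- length(members)
    k <- length(intersect(members, query))
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               p = hypergeom_tail(k, K, n, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      fdr = numeric(), significant = logical())
    return(out)
  }
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr_threshold
  out[order(out$p), ]
}
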