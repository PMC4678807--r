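#' Expression profile of one sample
#'
#' Bundles one sample's mapped-read counts per gene with its identifier and
#' arbitrary metadata (e.g. drug concentration in mM, exposure history).
#' This is the unit object every diversity computation consumes.
#'
#' @param counts Nonnegative integer vector of read counts, one per gene.
#'   At least one count must be positive.
#' @param sample_id Character scalar naming the sample.
#' @param gene_ids Character vector of unique gene identifiers, same length
#'   as `counts`. Defaults to `names(counts)`.
#' @param metadata Named list of sample-level annotations (e.g.
#'   `concentration_mM`, `history_id`).
#'
#' @return An object of class `expression_profile`.
#' @export
#' @examples
#' expression_profile(c(geneA = 1, geneB = 10, geneC = 100), "case1")
expression_profile <- function(counts, sample_id = "sample",
                               gene_ids = names(counts),
                               metadata = list()) {
  if (is.null(gene_ids)) {
    gene_ids <- sprintf("gene%0*d", nchar(length(counts)), seq_along(counts))
  }
  gene_ids <- as.character(gene_ids)
  counts <- as.numeric(counts)
  if (length(gene_ids) != length(counts)) {
    stop("`gene_ids` and `counts` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicated gene ids: ", paste(utils::head(dup, 5L), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("counts must be finite and nonnegative", call. = FALSE)
  }
  if (!any(counts > 0)) {
    stop("all counts are zero: profile carries no reads", call. = FALSE)
  }
  structure(
    list(sample_id = as.character(sample_id)[1L],
         gene_ids = gene_ids,
         counts = counts,
         metadata = as.list(metadata)),
    class = "expression_profile"
  )
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile> %s: %d genes (%d nonzero), %s reads\n",
              x$sample_id, length(x$counts), sum(x$counts > 0),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

# Coerce bare numeric vectors so the statistics can be called directly on
# counts in examples and interactive use.
as_profile <- function(x, sample_id = "sample") {
  if (inherits(x, "expression_profile")) return(x)
  if (is.numeric(x)) return(expression_profile(x, sample_id = sample_id))
  stop("expected an expression_profile or a numeric count vector", call. = FALSE)
}
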