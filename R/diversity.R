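#' Relative frequencies of a transcriptome
#'
#' Converts a sample's gene counts into the relative-frequency distribution
#' p_i = count_i / total reads. Zero counts map to p = 0 (they are retained
#' so gene order and universe are preserved).
#'
#' @param profile An [expression_profile()] or a numeric count vector.
#' @return A data.frame with columns `gene_id` and `p`; `sum(p)` is 1.
#' @export
#' @examples
#' relative_frequencies(c(1, 10, 100))$p  # 1/111, 10/111, 100/111
relative_frequencies <- function(profile) {
  profile <- as_profile(profile)
  data.frame(gene_id = profile$gene_ids,
             p = profile$counts / sum(profile$counts),
             stringsAsFactors = FALSE)
}

#' Transcriptome diversity: Shannon entropy of a sample's expression profile
#'
#' Computes H = -sum over expressed genes of p_i * log2(p_i), in bits, where
#' p_i is the relative frequency of gene i. Genes with zero counts contribute
#' exactly 0 (the 0*log 0 := 0 convention). H summarizes in one number how
#' evenly the transcriptome is spread across genes: a uniform profile over g
#' genes attains the maximum log2(g); a profile with a single expressed gene
#' has H = 0 (not an error).
#'
#' The sign convention is fixed at nonnegative H. (Formulations that report
#' the raw sum of p*log2(p) yield the same magnitude with a negative sign.)
#'
#' @param profile An [expression_profile()] or a numeric count vector.
#' @return An object of class `diversity_result`: a list with `sample_id`,
#'   `H` (bits), `g_nonzero` (number of expressed genes), `total_count`,
#'   and the profile's `metadata`.
#' @export
#' @examples
#' shannon_diversity(c(1, 10, 100))$H   # 0.51 at 2 d.p.
#' shannon_diversity(c(1, 10, 1000))$H  # 0.09 at 2 d.p.
shannon_diversity <- function(profile) {
  profile <- as_profile(profile)
  p <- profile$counts / sum(profile$counts)
  nz <- p > 0
  H <- -sum(p[nz] * log2(p[nz]))
  structure(
    list(sample_id = profile$sample_id,
         H = H,
         g_nonzero = sum(nz),
         total_count = sum(profile$counts),
         metadata = profile$metadata),
    class = "diversity_result"
  )
}

#' @export
print.diversity_result <- function(x, ...) {
  cat(sprintf("<diversity_result> %s: H = %.4f bits over %d expressed genes (%s reads)\n",
              x$sample_id, x$H, x$g_nonzero,
              format(x$total_count, big.mark = ",")))
  invisible(x)
}

#' Per-sample diversity table for a count matrix
#'
#' Applies [shannon_diversity()] to every column of a gene-by-sample count
#' matrix and joins per-sample metadata by `sample_id`.
#'
#' @param counts Numeric matrix, genes as rows, samples as columns; both
#'   dimnames set. Every column must contain at least one positive count.
#' @param metadata Optional data.frame with a `sample_id` column; every
#'   sample in `counts` must appear in it. Additional columns are joined
#'   onto the result.
#' @return A data.frame, one row per sample in column order, with columns
#'   `sample_id`, `H`, `g_nonzero`, `total_count` and any metadata columns.
#' @export
diversity_table <- function(counts, metadata = NULL) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) {
    stop("count matrix must have sample ids as column names", call. = FALSE)
  }
  if (is.null(rownames(counts))) {
    stop("count matrix must have gene ids as row names", call. = FALSE)
  }
  res <- lapply(colnames(counts), function(s) {
    d <- shannon_diversity(expression_profile(counts[, s], sample_id = s,
                                              gene_ids = rownames(counts)))
    data.frame(sample_id = s, H = d$H, g_nonzero = d$g_nonzero,
               total_count = d$total_count, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"sample_id" %in% names(metadata)) {
      stop("metadata must contain a `sample_id` column", call. = FALSE)
    }
    missing <- setdiff(out$sample_id, metadata$sample_id)
    if (length(missing)) {
      stop("samples missing from metadata: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    out <- merge(out, metadata, by = "sample_id", sort = FALSE)
    out <- out[match(colnames(counts), out$sample_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# Indices of the k most-expressed genes; ties among equal counts broken by
# ascending gene_id so the selection is deterministic.
top_gene_idx <- function(profile, k) {
  ord <- order(-profile$counts, profile$gene_ids)
  ord[seq_len(k)]
}

#' Diversity after removing the top-k most-expressed genes
#'
#' For each k, deletes the k genes with the largest counts (ties broken by
#' ascending gene id), renormalizes the relative frequencies over the
#' remaining genes, and recomputes the Shannon diversity. Tracks how much
#' of the diversity difference between samples is carried by their most
#' highly expressed genes: dominated and diffuse transcriptomes converge
#' as k grows. k = 0 (no removal) is always evaluated and reproduces
#' [shannon_diversity()] exactly.
#'
#' @param profile An [expression_profile()] or numeric count vector.
#' @param ks Nonnegative integers, each strictly less than the number of
#'   expressed genes. Default mirrors the standard ladder 10..500.
#' @return A data.frame with columns `sample_id`, `k`, `H` (bits, after
#'   renormalization) and `residual_mass` (raw fraction of reads left after
#'   removal, before renormalization).
#' @export
removal_curve <- function(profile, ks = c(10, 20, 30, 50, 100, 200, 300, 500)) {
  profile <- as_profile(profile)
  ks <- sort(unique(c(0L, as.integer(ks))))
  if (any(ks < 0)) stop("k must be nonnegative", call. = FALSE)
  g_nz <- sum(profile$counts > 0)
  if (max(ks) >= g_nz) {
    stop("k must be smaller than the number of expressed genes (",
         g_nz, ")", call. = FALSE)
  }
  p <- profile$counts / sum(profile$counts)
  ord <- order(-profile$counts, profile$gene_ids)
  rows <- lapply(ks, function(k) {
    keep <- if (k == 0L) seq_along(p) else setdiff(seq_along(p), ord[seq_len(k)])
    mass <- sum(p[keep])
    q <- p[keep] / mass
    q <- q[q > 0]
    data.frame(sample_id = profile$sample_id, k = k,
               H = -sum(q * log2(q)), residual_mass = mass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Sorted log2 relative-frequency profile
#'
#' Returns log2(p) for every expressed gene, sorted in decreasing order of
#' p (rank 1 = most-expressed gene). These rank-abundance profiles separate
#' dominated transcriptomes (a steep head followed by a depressed tail)
#' from diffuse ones.
#'
#' @param profile An [expression_profile()] or numeric count vector.
#' @return A data.frame with columns `sample_id`, `rank` (1-based) and
#'   `log2p` (non-increasing, all values <= 0).
#' @export
sorted_log_profile <- function(profile) {
  profile <- as_profile(profile)
  p <- profile$counts / sum(profile$counts)
  p <- p[p > 0]
  p <- sort(p, decreasing = TRUE)
  data.frame(sample_id = profile$sample_id,
             rank = seq_along(p),
             log2p = log2(p),
             stringsAsFactors = FALSE)
}

#' Occupancy fraction of a gene set
#'
#' Fraction of a sample's total reads held by a set of genes (its
#' "occupation rate"), either the `top_n` most-expressed genes (ties among
#' equal counts broken by ascending gene id) or an explicit set of gene ids.
#' In a dominated transcriptome a small set, e.g. storage-protein genes,
#' can hold more than a third of all reads.
#'
#' @param profile An [expression_profile()] or numeric count vector.
#' @param top_n Number of most-expressed genes to select. Exactly one of
#'   `top_n` and `genes` must be given.
#' @param genes Character vector of gene ids to select.
#' @return A single number in \[0, 1\].
#' @export
#' @examples
#' occupancy_fraction(c(a = 1, b = 10, c = 100), top_n = 1)  # 100/111
occupancy_fraction <- function(profile, top_n = NULL, genes = NULL) {
  profile <- as_profile(profile)
  if (is.null(top_n) == is.null(genes)) {
    stop("supply exactly one of `top_n` or `genes`", call. = FALSE)
  }
  p <- profile$counts / sum(profile$counts)
  if (!is.null(top_n)) {
    top_n <- as.integer(top_n)
    if (top_n < 1L || top_n > length(p)) {
      stop("`top_n` must be between 1 and the number of genes", call. = FALSE)
    }
    idx <- top_gene_idx(profile, top_n)
  } else {
    genes <- as.character(genes)
    if (!length(genes)) stop("`genes` must be nonempty", call. = FALSE)
    unknown <- setdiff(genes, profile$gene_ids)
    if (length(unknown)) {
      stop("unknown gene ids: ", paste(unknown, collapse = ", "), call. = FALSE)
    }
    idx <- match(genes, profile$gene_ids)
  }
  sum(p[idx])
}
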