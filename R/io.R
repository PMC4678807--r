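#' Read a gene-by-sample count matrix from tab-separated text
#'
#' Expects a header row `gene_id<TAB>sample1<TAB>...` followed by one row
#' per gene of nonnegative integer cells. Validation failures report the
#' offending line number: ragged rows, duplicated gene ids, negative or
#' non-integer cells are all rejected.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, genes as rows and samples as columns, with
#'   dimnames set.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  if (!length(lines) || !nzchar(lines[1L])) {
    stop("parse error: ", path, " is empty", call. = FALSE)
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 2L) {
    stop("parse error at line 1: header must be gene_id followed by sample ids",
         call. = FALSE)
  }
  samples <- header[-1L]
  if (anyDuplicated(samples)) {
    stop("parse error at line 1: duplicated sample ids", call. = FALSE)
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  if (!length(body)) stop("parse error: no gene rows in ", path, call. = FALSE)
  fields <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(fields)
  bad <- which(widths != length(header))
  if (length(bad)) {
    stop("parse error at line ", bad[1L] + 1L, ": expected ",
         length(header), " fields, found ", widths[bad[1L]], call. = FALSE)
  }
  gene_ids <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids)) {
    line <- which(duplicated(gene_ids))[1L] + 1L
    stop("parse error at line ", line, ": duplicated gene id ",
         gene_ids[duplicated(gene_ids)][1L], call. = FALSE)
  }
  cells <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-1L]), numeric(length(samples)))
  )
  cells <- matrix(cells, nrow = length(samples))  # guards the 1-sample case
  bad_num <- which(apply(cells, 2L, function(col) anyNA(col) || any(col < 0) ||
                           any(col != floor(col))))
  if (length(bad_num)) {
    stop("parse error at line ", bad_num[1L] + 1L,
         ": cells must be nonnegative integers", call. = FALSE)
  }
  counts <- t(cells)
  dimnames(counts) <- list(gene_ids, samples)
  counts
}

#' Write a count matrix as tab-separated text
#'
#' Inverse of [read_count_matrix()]: a `gene_id` first column, sample ids
#' in the header, integer cells. Reading the written file reproduces the
#' matrix exactly.
#'
#' @param counts Matrix with gene and sample dimnames.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Tab-separated with a mandatory `sample_id` column; `concentration_mM`
#' and `history_id` are validated when `require_columns` asks for them.
#'
#' @param path Path to the TSV file.
#' @param require_columns Columns that must be present (default
#'   `sample_id`).
#' @return A data.frame.
#' @export
read_sample_metadata <- function(path,
                                 require_columns = "sample_id") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  md <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(require_columns, names(md))
  if (length(missing)) {
    stop("metadata is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(md$sample_id)) {
    stop("metadata has duplicated sample ids", call. = FALSE)
  }
  md
}

#' Write a metadata or results table as tab-separated text
#'
#' @param df A data.frame.
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Published phenobarbital diversity values
#'
#' The 21 transcriptome diversities (bits) of cultured silkworm fat-body
#' tissue reported for the phenobarbital study: the five-dose ladder
#' (0, 0.25, 1.0, 2.5, 12.5 mM; three replicates each) and the two
#' hysteresis arms cultured at 0 or 0.25 mM after a 10 h exposure to
#' 1.0 mM (three replicates each). Two values are corrected printer's
#' errors in the source table: "10,26" is read as 10.26 and the
#' concentration omitted for the second hysteresis arm is taken as
#' 0.25 mM (the arm the study design defines).
#'
#' @return A data.frame with `sample_id`, `concentration_mM`, `history_id`
#'   ("naive" or "after_1.0mM") and `H` (bits).
#' @export
phenobarbital_diversities <- function() {
  path <- system.file("extdata", "phenobarbital_diversity.tsv",
                      package = "txdiversity", mustWork = TRUE)
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  md
}

#' The three-gene worked-example count matrix
#'
#' Cases 1-3 of the toy demonstration that diversity ignores gene order
#' but responds to dominance: counts (1, 10, 100), (10, 100, 1) and
#' (1, 10, 1000) over genes A-C give H = 0.51, 0.51 and 0.09 bits.
#'
#' @return A 3 x 3 integer matrix (genes x cases).
#' @export
worked_example_counts <- function() {
  m <- cbind(case1 = c(1, 10, 100),
             case2 = c(10, 100, 1),
             case3 = c(1, 10, 1000))
  rownames(m) <- c("geneA", "geneB", "geneC")
  m
}
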