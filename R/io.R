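# Readers and writers for the tab-delimited counts format and genotype
# matrices.

#' Read a paired genotype counts table
#'
#' Tab-delimited text, one SNP per line, with a header. Required columns:
#' `snp_id` and the nine counts `n00 ... n22`; `chrom` and `pos` are
#' carried through when present. Counts must be non-negative integers;
#' malformed cells are reported with their line number.
#'
#' @param path Path to the TSV file.
#' @return Tibble with one row per SNP.
#' @export
read_counts_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  missing <- setdiff(c("snp_id", COUNT_COLS), names(df))
  if (length(missing) > 0) {
    stop("counts table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (cc in COUNT_COLS) {
    v <- df[[cc]]
    bad <- which(!is.finite(v) | v < 0 | v != round(v))
    if (length(bad) > 0) {
      stop(sprintf("invalid count in column %s, line %d (+header): %s",
                   cc, bad[1] + 1L, as.character(v[bad[1]])), call. = FALSE)
    }
  }
  tibble::as_tibble(df)
}

#' Write a paired genotype counts table
#'
#' @param data Counts tibble.
#' @param path Output path.
#' @return `data`, invisibly.
#' @export
write_counts_table <- function(data, path) {
  stopifnot(all(COUNT_COLS %in% names(data)))
  readr::write_tsv(data, path, progress = FALSE)
  invisible(data)
}

#' Cross-tabulate paired genotype matrices into per-SNP counts
#'
#' Builds the 9-cell table per SNP from matched genotype matrices
#' (samples x SNPs, dosages in `{0, 1, 2}` or `NA`). Samples missing
#' either genotype at a SNP are excluded from that SNP's table and counted
#' in the `n_missing` column.
#'
#' @param normal,tumor Integer matrices of identical dimension; column
#'   names are used as SNP identifiers when present.
#' @return Tibble with `snp_id`, the nine count columns, `n_missing`, and
#'   a logical `missing` flag (any missing genotype at the SNP).
#' @export
tabulate_counts <- function(normal, tumor) {
  normal <- as.matrix(normal); tumor <- as.matrix(tumor)
  if (!identical(dim(normal), dim(tumor))) {
    stop("normal and tumor matrices must have identical dimensions",
         call. = FALSE)
  }
  ok_vals <- function(x) all(is.na(x) | x %in% 0:2)
  stopifnot(ok_vals(normal), ok_vals(tumor))
  ids <- colnames(normal)
  if (is.null(ids)) ids <- paste0("snp", seq_len(ncol(normal)))
  rows <- lapply(seq_len(ncol(normal)), function(s) {
    g_n <- normal[, s]; g_t <- tumor[, s]
    use <- !is.na(g_n) & !is.na(g_t)
    cts <- numeric(9)
    if (any(use)) {
      tab <- table(factor(g_n[use], levels = 0:2),
                   factor(g_t[use], levels = 0:2))
      cts <- as.numeric(t(tab))
    }
    out <- tibble::as_tibble(as.list(stats::setNames(as.integer(cts),
                                                     COUNT_COLS)))
    out$snp_id <- ids[s]
    out$n_missing <- sum(!use)
    out$missing <- any(!use)
    out
  })
  dplyr::bind_rows(rows) |>
    dplyr::select("snp_id", dplyr::all_of(COUNT_COLS), "n_missing", "missing")
}
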