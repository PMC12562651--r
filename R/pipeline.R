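# Genome-scale plumbing: quality control, SNP-to-gene mapping with flanks,
# even segmentation of long genes, and gene-level score aggregation.

#' Hardy-Weinberg equilibrium goodness-of-fit test
#'
#' One-degree-of-freedom chi-square test of the normal-tissue genotype
#' counts `(c0, c1, c2)` against Hardy-Weinberg proportions at the sample
#' allele frequency. Vectorized over SNPs.
#'
#' @param c0,c1,c2 Genotype counts (reference homozygote, heterozygote,
#'   alternate homozygote).
#' @return Numeric vector of p-values; monomorphic SNPs return 1.
#' @export
#' @examples
#' hwe_test(64, 32, 4)   # exact HWE proportions: p = 1
#' hwe_test(50, 0, 50)   # extreme departure
hwe_test <- function(c0, c1, c2) {
  n <- c0 + c1 + c2
  stopifnot(all(n > 0))
  p <- (c1 + 2 * c2) / (2 * n)
  e0 <- n * (1 - p)^2; e1 <- n * 2 * p * (1 - p); e2 <- n * p^2
  mono <- p == 0 | p == 1
  chisq <- ifelse(mono, 0,
                  (c0 - e0)^2 / pmax(e0, 1e-300) +
                  (c1 - e1)^2 / pmax(e1, 1e-300) +
                  (c2 - e2)^2 / pmax(e2, 1e-300))
  ifelse(mono, 1, stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Quality-control filter for a SNP panel
#'
#' Removes SNPs failing the Hardy-Weinberg test on normal-tissue genotypes
#' (`p < hwe_alpha`), with allele frequency below `maf_min`, or flagged as
#' carrying missing genotypes (logical `missing` column, if present).
#'
#' @param data Counts tibble, one row per SNP.
#' @param hwe_alpha Hardy-Weinberg p-value cutoff.
#' @param maf_min Minimum allele frequency.
#' @param drop_missing Drop SNPs whose `missing` column is `TRUE`.
#' @param reorient_maf If `TRUE`, frequencies above 0.5 are folded to
#'   `1 - freq` for the MAF filter only (the counts are not flipped).
#' @return The filtered tibble, with a `qc_report` attribute (a tibble of
#'   removal counts per rule; overlaps mean the per-rule counts can exceed
#'   the total removed).
#' @export
qc_filter <- function(data, hwe_alpha = 0.05, maf_min = 0.05,
                      drop_missing = TRUE, reorient_maf = FALSE) {
  stopifnot(is.data.frame(data))
  if (nrow(data) == 0) {
    return(structure(tibble::as_tibble(data),
                     qc_report = tibble::tibble(rule = character(),
                                                removed = integer())))
  }
  stopifnot(all(COUNT_COLS %in% names(data)))
  c0 <- rowSums(data[c("n00", "n01", "n02")])
  c1 <- rowSums(data[c("n10", "n11", "n12")])
  c2 <- rowSums(data[c("n20", "n21", "n22")])
  af <- (c1 + 2 * c2) / (2 * (c0 + c1 + c2))
  maf <- if (reorient_maf) pmin(af, 1 - af) else af
  fail_hwe <- hwe_test(c0, c1, c2) < hwe_alpha
  fail_maf <- maf < maf_min
  fail_missing <- if (drop_missing && "missing" %in% names(data)) {
    isTRUE_vec(data$missing)
  } else {
    rep(FALSE, nrow(data))
  }
  keep <- !(fail_hwe | fail_maf | fail_missing)
  report <- tibble::tibble(
    rule = c("hwe", "maf", "missing", "total_removed", "retained"),
    removed = c(sum(fail_hwe), sum(fail_maf), sum(fail_missing),
                sum(!keep), sum(keep))
  )
  structure(tibble::as_tibble(data)[keep, , drop = FALSE], qc_report = report)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' QC report of a filtered panel
#' @param data Output of [qc_filter()].
#' @return Tibble of per-rule removal counts.
#' @export
qc_report <- function(data) attr(data, "qc_report")

#' Read a refFlat gene annotation
#'
#' Standard 11-column refFlat format (gene name, transcript name, chrom,
#' strand, txStart, txEnd, cdsStart, cdsEnd, exonCount, exonStarts,
#' exonEnds); coordinates are 0-based, end-exclusive. Transcripts of the
#' same gene are collapsed to the union of their transcription spans.
#'
#' @param path Path to a refFlat file (no header).
#' @return Tibble with `gene_name`, `chrom`, `strand`, `tx_start`,
#'   `tx_end` (refFlat convention preserved).
#' @export
read_refflat <- function(path) {
  cols <- c("gene_name", "tx_name", "chrom", "strand", "tx_start", "tx_end",
            "cds_start", "cds_end", "exon_count", "exon_starts", "exon_ends")
  df <- readr::read_tsv(path, col_names = cols,
                        col_types = "ccccddddicc", progress = FALSE)
  df |>
    dplyr::group_by(.data$gene_name, .data$chrom, .data$strand) |>
    dplyr::summarise(tx_start = min(.data$tx_start),
                     tx_end = max(.data$tx_end), .groups = "drop")
}

# refFlat 0-based half-open [tx_start, tx_end) with a symmetric flank maps
# to the 1-based inclusive interval [tx_start - flank + 1, tx_end + flank].
# All coordinate conversion happens here.
flanked_region_1based <- function(tx_start, tx_end, flank) {
  list(start = tx_start - flank + 1, end = tx_end + flank)
}

#' Map SNPs to genes with flanking regions
#'
#' A SNP maps to a gene when its (1-based) position falls within the gene's
#' transcription span extended by `flank` base pairs on both sides. A SNP
#' may map to several overlapping genes; it then contributes to each.
#'
#' @param snps Tibble with `snp_id`, `chrom`, `pos` (1-based).
#' @param genes Gene annotation as from [read_refflat()].
#' @param flank Flank size in base pairs.
#' @return Tibble of (`snp_id`, `gene_name`, `chrom`, `pos`) pairs, one
#'   row per mapping. SNPs on chromosomes absent from the annotation are
#'   dropped with a warning.
#' @export
map_snps_to_genes <- function(snps, genes, flank = 1000) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(snps)),
            all(c("gene_name", "chrom", "tx_start", "tx_end") %in% names(genes)))
  unknown <- setdiff(unique(snps$chrom), unique(genes$chrom))
  if (length(unknown) > 0) {
    warning("SNPs on chromosomes without annotation left unmapped: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  reg <- flanked_region_1based(genes$tx_start, genes$tx_end, flank)
  g <- dplyr::mutate(genes, .start = reg$start, .end = reg$end)
  dplyr::inner_join(
    dplyr::select(snps, "snp_id", "chrom", "pos"),
    dplyr::select(g, "gene_name", "chrom", ".start", ".end"),
    by = "chrom", relationship = "many-to-many"
  ) |>
    dplyr::filter(.data$pos >= .data$.start, .data$pos <= .data$.end) |>
    dplyr::select("snp_id", "gene_name", "chrom", "pos")
}

#' Split flanked gene regions into balanced segments
#'
#' The flanked region of each gene is tiled by `k = ceiling(L / max_len)`
#' contiguous, non-overlapping segments whose lengths differ by at most one
#' base pair; genes whose flanked length is at most `max_len` yield a
#' single segment.
#'
#' @param genes Gene annotation as from [read_refflat()].
#' @param flank Flank size in base pairs (applied before segmentation).
#' @param max_len Maximum segment length in base pairs.
#' @return Tibble with `gene_name`, `chrom`, `segment_id`,
#'   `segment_index`, `start`, `end` (1-based inclusive).
#' @export
#' @examples
#' genes <- tibble::tibble(gene_name = "g", chrom = "chr1", strand = "+",
#'                         tx_start = 1000, tx_end = 63001)
#' segment_genes(genes, flank = 1000)  # flanked length 64001 -> 3 segments
segment_genes <- function(genes, flank = 1000, max_len = 32000) {
  reg <- flanked_region_1based(genes$tx_start, genes$tx_end, flank)
  purrr::pmap(list(genes$gene_name, genes$chrom, reg$start, reg$end),
              function(gene, chrom, s, e) {
    L <- e - s + 1
    k <- ceiling(L / max_len)
    base <- L %/% k
    extra <- L %% k  # first `extra` segments get one extra bp
    len <- rep(base, k) + c(rep(1, extra), rep(0, k - extra))
    stops <- s - 1 + cumsum(len)
    starts <- c(s, utils::head(stops, -1) + 1)
    tibble::tibble(gene_name = gene, chrom = chrom,
                   segment_index = seq_len(k),
                   segment_id = paste0(gene, ".seg", seq_len(k)),
                   start = starts, end = stops)
  }) |> dplyr::bind_rows()
}

#' Assign mapped SNPs to gene segments
#'
#' @param mapping SNP-to-gene mapping from [map_snps_to_genes()].
#' @param segments Segment table from [segment_genes()].
#' @return The mapping with `segment_id` and `segment_index` columns.
#' @export
assign_segments <- function(mapping, segments) {
  dplyr::inner_join(mapping, segments,
                    by = c("gene_name", "chrom"),
                    relationship = "many-to-many") |>
    dplyr::filter(.data$pos >= .data$start, .data$pos <= .data$end) |>
    dplyr::select("snp_id", "gene_name", "chrom", "pos", "segment_id",
                  "segment_index")
}

#' Aggregate per-SNP or per-segment posterior scores to genes
#'
#' Single-marker mode: each segment is scored by the mean of its SNPs'
#' posterior association probabilities, and the gene takes the maximum
#' segment score. Multi-marker mode: the gene takes the maximum of its
#' segments' set-level posterior summaries. `"largest"` is read as the
#' largest-scoring segment; `rule = "longest"` instead picks the
#' physically longest segment's score (single mode only).
#'
#' @param scores Single mode: tibble with `gene_name`, `segment_id` and a
#'   per-SNP `score` column (one row per SNP). Multi mode: tibble with
#'   `gene_name`, `segment_id` and one `score` per segment.
#' @param mode `"single"` or `"multi"`.
#' @param rule `"max_score"` (default) or `"longest"`; `"longest"`
#'   requires a `segment_length` column.
#' @return Tibble with `gene_name` and `gene_score`, ranked by score.
#' @export
aggregate_gene_scores <- function(scores, mode = c("single", "multi"),
                                  rule = c("max_score", "longest")) {
  mode <- match.arg(mode)
  rule <- match.arg(rule)
  stopifnot(all(c("gene_name", "segment_id", "score") %in% names(scores)))
  seg <- if (mode == "single") {
    scores |>
      dplyr::group_by(.data$gene_name, .data$segment_id) |>
      dplyr::summarise(seg_score = mean(.data$score),
                       segment_length = if ("segment_length" %in% names(scores))
                         .data$segment_length[1] else NA_real_,
                       .groups = "drop")
  } else {
    dplyr::mutate(scores, seg_score = .data$score,
                  segment_length = if ("segment_length" %in% names(scores))
                    .data$segment_length else NA_real_)
  }
  picked <- if (rule == "max_score") {
    seg |>
      dplyr::group_by(.data$gene_name) |>
      dplyr::summarise(gene_score = max(.data$seg_score), .groups = "drop")
  } else {
    seg |>
      dplyr::group_by(.data$gene_name) |>
      dplyr::slice_max(.data$segment_length, n = 1, with_ties = FALSE) |>
      dplyr::summarise(gene_score = .data$seg_score[1], .groups = "drop")
  }
  dplyr::arrange(picked, dplyr::desc(.data$gene_score))
}

#' Run the gene-level analysis pipeline on a SNP panel
#'
#' QC filter, map to flanked genes, segment long genes, fit the requested
#' model per segment, and aggregate to gene scores.
#'
#' @param snps Tibble with `snp_id`, `chrom`, `pos` and the nine count
#'   columns.
#' @param genes Gene annotation as from [read_refflat()].
#' @param mode `"single"` (per-SNP Bayesian model, segment mean, gene max)
#'   or `"multi"` (per-segment SNP-set model, gene max).
#' @param flank,max_len,hwe_alpha,maf_min Pipeline parameters.
#' @inheritParams fit_bayes
#' @return List with `genes` (ranked gene scores), `segments`,
#'   `snp_scores`, and `qc` (the QC report).
#' @export
run_pipeline <- function(snps, genes, mode = c("single", "multi"),
                         flank = 1000, max_len = 32000, hwe_alpha = 0.05,
                         maf_min = 0.05, priors = prior_config(),
                         mcmc = mcmc_config()) {
  mode <- match.arg(mode)
  kept <- qc_filter(snps, hwe_alpha = hwe_alpha, maf_min = maf_min)
  mapping <- map_snps_to_genes(kept, genes, flank = flank)
  segments <- segment_genes(genes, flank = flank, max_len = max_len)
  assigned <- assign_segments(mapping, segments)
  panel <- dplyr::inner_join(assigned, kept, by = c("snp_id", "chrom", "pos"))
  if (mode == "single") {
    # fit each distinct SNP once (a SNP mapping to several genes is scored
    # once and contributes to each)
    uniq <- dplyr::distinct(panel, .data$snp_id, .keep_all = TRUE)
    fit <- fit_bayes_sets(uniq, set = "snp_id", priors = priors, mcmc = mcmc)
    per_snp <- dplyr::distinct(tibble::tibble(snp_id = fit$snp$snp_id,
                                              score = fit$snp$H_mean))
    snp_scores <- panel |>
      dplyr::select("snp_id", "gene_name", "segment_id") |>
      dplyr::left_join(per_snp, by = "snp_id")
    gene_scores <- aggregate_gene_scores(snp_scores, mode = "single")
  } else {
    fit <- fit_bayes_sets(panel, set = "segment_id", priors = priors,
                          mcmc = mcmc)
    seg_scores <- dplyr::left_join(
      dplyr::distinct(panel, .data$gene_name, .data$segment_id),
      dplyr::select(fit$set, "segment_id", score = "G_median"),
      by = "segment_id"
    )
    snp_scores <- fit$snp
    gene_scores <- aggregate_gene_scores(seg_scores, mode = "multi")
  }
  list(genes = gene_scores, segments = segments, snp_scores = snp_scores,
       qc = qc_report(kept))
}
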