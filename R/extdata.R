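#' Bundled reference tables
#'
#' Small reference tables shipped with the package: the major QTL regions
#' (logBF > 12) reported for six maternal performance traits of beef cattle
#' (calving difficulty score CS, pelvic opening PO, maternal calving score
#' CSm, milk yield MY, udder swelling score US, maternal weaning weight WWm),
#' the common regions identified across those traits, and the candidate gene
#' intervals proposed within them (UMD 3.1 coordinates). They serve as worked
#' examples for the interval operations and as ground truth for the
#' cross-trait comparison utilities.
#'
#' @param trait Optional trait label(s) to filter on.
#' @return `qtl_reference_regions()`: region tibble (`trait`, `chrom`,
#'   `start_bp`, `end_bp`, `peak_bp`, `peak_logbf`, `evidence_class`)
#'   compatible with [common_regions()]. `common_reference_regions()`: tibble
#'   of reported common regions. `candidate_gene_intervals()`: gene tibble
#'   compatible with [annotate_genes()].
#' @export
qtl_reference_regions <- function(trait = NULL) {
  path <- system.file("extdata", "published_major_qtl.tsv", package = "bayescqtl")
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::mutate(
      chrom = as.character(.data$chrom),
      start_bp = round(.data$start_mb * 1e6),
      end_bp = round(.data$end_mb * 1e6),
      peak_bp = round(.data$peak_mb * 1e6),
      evidence_class = classify_evidence(.data$peak_logbf)
    )
  if (!is.null(trait)) tab <- tab[tab$trait %in% trait, , drop = FALSE]
  tab
}

#' @rdname qtl_reference_regions
#' @export
common_reference_regions <- function() {
  path <- system.file("extdata", "published_common_qtl.tsv", package = "bayescqtl")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::mutate(
      chrom = as.character(.data$chrom),
      start_bp = round(.data$common_start_mb * 1e6),
      end_bp = round(.data$common_end_mb * 1e6),
      peak_bp_1 = round(.data$peak_mb_trait_1 * 1e6),
      peak_bp_2 = round(.data$peak_mb_trait_2 * 1e6)
    )
}

#' @rdname qtl_reference_regions
#' @export
candidate_gene_intervals <- function() {
  path <- system.file("extdata", "published_candidate_genes.tsv", package = "bayescqtl")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::mutate(
      chrom = as.character(.data$chrom),
      start_bp = round(.data$start_mb * 1e6),
      end_bp = round(.data$end_mb * 1e6)
    ) |>
    dplyr::select("gene_symbol", "gene_name", "chrom", "start_bp", "end_bp", "strand") |>
    dplyr::arrange(.data$chrom, .data$start_bp)
  }
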