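evidence_at_least <- function(regions, min_class) {
  lev <- match(regions$evidence_class, evidence_levels)
  regions[lev >= match(min_class, evidence_levels), , drop = FALSE]
}

regions_to_granges <- function(regions, seqlevels = NULL) {
  GenomicRanges::GRanges(
    seqnames = factor(regions$chrom, levels = seqlevels %||% unique(regions$chrom)),
    ranges = IRanges::IRanges(
      start = round(regions$start_bp), end = round(regions$end_bp)
    )
  )
}

#' Common QTL regions between two traits
#'
#' For every pair of same-chromosome regions (at evidence `min_class` or
#' better in both traits) with a non-empty overlap, returns the interval
#' intersection `[max(starts), min(ends)]` together with both peak positions.
#' Regions are closed intervals at SNP positions, so a single shared position
#' counts as overlap. A region overlapping two regions of the other trait
#' yields two rows.
#'
#' @param regions_a,regions_b Region tibbles from [call_regions()].
#' @param trait_a,trait_b Trait labels for the output.
#' @param min_class Minimum evidence class (`"putative"`, `"qtl"`, `"major"`).
#' @return Tibble `trait_a`, `trait_b`, `chrom`, `start_bp`, `end_bp`,
#'   `peak_bp_a`, `peak_bp_b`, one row per overlapping pair.
#' @export
common_regions <- function(regions_a, regions_b, trait_a = "trait_a",
                           trait_b = "trait_b", min_class = "qtl") {
  a <- evidence_at_least(tibble::as_tibble(regions_a), min_class)
  b <- evidence_at_least(tibble::as_tibble(regions_b), min_class)
  empty <- tibble::tibble(
    trait_a = character(), trait_b = character(), chrom = character(),
    start_bp = numeric(), end_bp = numeric(),
    peak_bp_a = numeric(), peak_bp_b = numeric()
  )
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  lev <- union(a$chrom, b$chrom)
  ga <- regions_to_granges(a, lev)
  gb <- regions_to_granges(b, lev)
  hits <- GenomicRanges::findOverlaps(ga, gb)
  if (!length(hits)) return(empty)
  ia <- S4Vectors::queryHits(hits)
  ib <- S4Vectors::subjectHits(hits)
  inter <- GenomicRanges::pintersect(ga[ia], gb[ib])
  tibble::tibble(
    trait_a = trait_a, trait_b = trait_b,
    chrom = as.character(a$chrom[ia]),
    start_bp = as.numeric(GenomicRanges::start(inter)),
    end_bp = as.numeric(GenomicRanges::end(inter)),
    peak_bp_a = a$peak_bp[ia],
    peak_bp_b = b$peak_bp[ib]
  ) |>
    dplyr::arrange(.data$chrom, .data$start_bp)
}

#' Venn cell counts of QTL sharing across three traits
#'
#' Reference-trait oriented: counts how many regions of the reference trait
#' overlap neither, exactly one (each), or both of the two other traits'
#' region sets. Overlap is a non-empty closed-interval intersection on the
#' same chromosome.
#'
#' @param regions_by_trait Named list of exactly three region tibbles.
#' @param reference Name of the reference trait (default: first element).
#' @param min_class Minimum evidence class applied to every trait.
#' @return Tibble `cell`, `count` with four rows (`<ref> only`,
#'   `<ref> & <b>`, `<ref> & <c>`, `all three`); counts sum to the reference
#'   trait's region count.
#' @export
venn_counts <- function(regions_by_trait, reference = NULL, min_class = "qtl") {
  if (length(regions_by_trait) != 3 || is.null(names(regions_by_trait))) {
    stop("`regions_by_trait` must be a named list of three region tables", call. = FALSE)
  }
  reference <- reference %||% names(regions_by_trait)[1]
  others <- setdiff(names(regions_by_trait), reference)
  filt <- purrr::map(regions_by_trait, ~ evidence_at_least(tibble::as_tibble(.x), min_class))
  ref <- filt[[reference]]
  overlaps_any <- function(other) {
    if (nrow(ref) == 0 || nrow(other) == 0) return(rep(FALSE, nrow(ref)))
    lev <- union(ref$chrom, other$chrom)
    GenomicRanges::countOverlaps(
      regions_to_granges(ref, lev), regions_to_granges(other, lev)
    ) > 0
  }
  o1 <- overlaps_any(filt[[others[1]]])
  o2 <- overlaps_any(filt[[others[2]]])
  tibble::tibble(
    cell = c(
      paste(reference, "only"),
      paste(reference, "&", others[1]),
      paste(reference, "&", others[2]),
      "all three"
    ),
    count = c(sum(!o1 & !o2), sum(o1 & !o2), sum(!o1 & o2), sum(o1 & o2))
  )
}

#' Annotate QTL regions with gene intervals
#'
#' Reports every gene overlapping each region; for regions with no
#' overlapping gene, the nearest same-chromosome gene is reported with its
#' gap distance in Mb (3 decimal places).
#'
#' @param regions Region tibble ([call_regions()] or [common_regions()]
#'   output; needs `chrom`, `start_bp`, `end_bp`).
#' @param genes Gene tibble `gene_symbol`, `chrom`, `start_bp`, `end_bp`
#'   (and optionally `strand`), e.g. from [read_gene_intervals()].
#' @return Tibble `region_index`, `chrom`, `start_bp`, `end_bp`,
#'   `gene_symbol`, `relation` (`"overlap"`/`"nearest"`), `distance_mb`.
#' @export
annotate_genes <- function(regions, genes) {
  regions <- tibble::as_tibble(regions)
  genes <- dplyr::arrange(tibble::as_tibble(genes), .data$chrom, .data$start_bp)
  empty <- tibble::tibble(
    region_index = integer(), chrom = character(),
    start_bp = numeric(), end_bp = numeric(),
    gene_symbol = character(), relation = character(), distance_mb = numeric()
  )
  if (nrow(regions) == 0 || nrow(genes) == 0) return(empty)
  lev <- union(regions$chrom, genes$chrom)
  gr <- regions_to_granges(regions, lev)
  gg <- GenomicRanges::GRanges(
    seqnames = factor(genes$chrom, levels = lev),
    ranges = IRanges::IRanges(round(genes$start_bp), round(genes$end_bp))
  )
  hits <- GenomicRanges::findOverlaps(gr, gg)
  ov <- tibble::tibble(
    region_index = S4Vectors::queryHits(hits),
    gene_symbol = genes$gene_symbol[S4Vectors::subjectHits(hits)],
    relation = "overlap", distance_mb = 0
  )
  no_hit <- setdiff(seq_len(nrow(regions)), unique(S4Vectors::queryHits(hits)))
  near <- empty[0, c("region_index", "gene_symbol", "relation", "distance_mb")]
  if (length(no_hit)) {
    nh <- GenomicRanges::distanceToNearest(gr[no_hit], gg)
    if (length(nh)) {
      near <- tibble::tibble(
        region_index = no_hit[S4Vectors::queryHits(nh)],
        gene_symbol = genes$gene_symbol[S4Vectors::subjectHits(nh)],
        relation = "nearest",
        distance_mb = round(S4Vectors::mcols(nh)$distance / 1e6, 3)
      )
    }
  }
  dplyr::bind_rows(ov, near) |>
    dplyr::mutate(
      chrom = regions$chrom[.data$region_index],
      start_bp = regions$start_bp[.data$region_index],
      end_bp = regions$end_bp[.data$region_index],
      .after = "region_index"
    ) |>
    dplyr::arrange(.data$region_index, .data$relation, .data$gene_symbol)
}

#' Distance between two QTL peaks
#'
#' @param peak_a_bp,peak_b_bp Peak positions in bp, on the same chromosome.
#' @param chrom_a,chrom_b Optional chromosome labels; differing labels are an
#'   error.
#' @return `|a - b|` in Mb.
#' @export
peak_distance <- function(peak_a_bp, peak_b_bp, chrom_a = NULL, chrom_b = NULL) {
  if (!is.null(chrom_a) && !is.null(chrom_b) && any(chrom_a != chrom_b)) {
    stop("peaks lie on different chromosomes", call. = FALSE)
  }
  abs(peak_a_bp - peak_b_bp) / 1e6
}

#' Read gene intervals from BED or GFF3
#'
#' BED files are converted from 0-based half-open to 1-based closed
#' coordinates; for GFF3 only `gene` features are kept and the gene symbol is
#' taken from the `Name` (falling back to `ID`) attribute.
#'
#' @param path File path ending in `.bed`, `.gff`, `.gff3` (optionally `.gz`).
#' @return Tibble `gene_symbol`, `chrom`, `start_bp`, `end_bp`, `strand`.
#' @export
read_gene_intervals <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading gene-interval files requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  if (any(c("type") %in% names(S4Vectors::mcols(gr)))) {
    gr <- gr[S4Vectors::mcols(gr)$type == "gene"]
  }
  mc <- S4Vectors::mcols(gr)
  sym <- if ("Name" %in% names(mc)) {
    as.character(mc$Name)
  } else if ("name" %in% names(mc)) {
    as.character(mc$name)
  } else if ("ID" %in% names(mc)) {
    as.character(mc$ID)
  } else {
    sprintf("gene_%d", seq_along(gr))
  }
  tibble::tibble(
    gene_symbol = sym,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start_bp = as.numeric(GenomicRanges::start(gr)),
    end_bp = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr))
  ) |>
    dplyr::arrange(.data$chrom, .data$start_bp)
}

#' Write common regions as TSV (region-table layout) or BED
#'
#' @param common Tibble from [common_regions()].
#' @param path Output path.
#' @export
write_common_regions_tsv <- function(common, path) {
  out <- tibble::tibble(
    traits = paste(common$trait_a, "-", common$trait_b),
    chrom = common$chrom,
    common_start_mb = sprintf("%.6f", common$start_bp / 1e6),
    common_end_mb = sprintf("%.6f", common$end_bp / 1e6),
    peak_mb_trait_1 = sprintf("%.6f", common$peak_bp_a / 1e6),
    peak_mb_trait_2 = sprintf("%.6f", common$peak_bp_b / 1e6)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}

#' @rdname write_common_regions_tsv
#' @export
write_common_regions_bed <- function(common, path) {
  out <- tibble::tibble(
    chrom = common$chrom,
    start = as.integer(round(common$start_bp)) - 1L,
    end = as.integer(round(common$end_bp)),
    name = paste0(common$trait_a, "-", common$trait_b)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(out)
}
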