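test_that("common regions reproduce the reported chr6 suckling intersection", {
  # the udder-score and milk-yield major regions on chromosome 6 overlap;
  # their intersection is the reported common interval ending at 88.959 Mb
  us <- qtl_reference_regions("US")
  my <- qtl_reference_regions("MY")
  common <- common_regions(us, my, trait_a = "US", trait_b = "MY")
  chr6 <- common[common$chrom == "6", ]
  expect_equal(nrow(chr6), 1L)
  expect_equal(chr6$start_bp / 1e6, 88.485)
  expect_equal(chr6$end_bp / 1e6, 88.959)
  expect_equal(chr6$peak_bp_a / 1e6, 88.922396)
  expect_equal(chr6$peak_bp_b / 1e6, 88.919352)
  # matches the bundled common-region reference row
  ref <- common_reference_regions()
  ref6 <- ref[ref$trait_1 == "US" & ref$trait_2 == "MY" & ref$chrom == "6", ]
  expect_equal(chr6$start_bp, ref6$start_bp)
  expect_equal(chr6$end_bp, ref6$end_bp)
})

test_that("interval intersection is symmetric, idempotent and size-reducing", {
  a <- tibble::tibble(
    chrom = c("1", "1", "2"), start_bp = c(1e6, 8e6, 3e6),
    end_bp = c(3e6, 9e6, 5e6), peak_bp = c(2e6, 8.5e6, 4e6),
    peak_logbf = c(9, 13, 10), evidence_class = c("qtl", "major", "qtl")
  )
  b <- tibble::tibble(
    chrom = c("1", "2"), start_bp = c(2e6, 6e6), end_bp = c(4e6, 7e6),
    peak_bp = c(2.5e6, 6.5e6), peak_logbf = c(10, 9),
    evidence_class = c("qtl", "qtl")
  )
  ab <- common_regions(a, b)
  ba <- common_regions(b, a)
  expect_equal(nrow(ab), 1L) # disjoint chr2 intervals drop out
  expect_equal(ab$start_bp, 2e6)
  expect_equal(ab$end_bp, 3e6)
  expect_equal(ab[c("chrom", "start_bp", "end_bp")], ba[c("chrom", "start_bp", "end_bp")])
  # width never exceeds either input
  expect_true(all(ab$end_bp - ab$start_bp <=
    min(a$end_bp - a$start_bp, b$end_bp - b$start_bp)))

  # self-intersection returns each region unchanged
  aa <- common_regions(a, a)
  self <- aa[aa$peak_bp_a == aa$peak_bp_b, ]
  expect_equal(nrow(self), 3L)
  expect_equal(self$start_bp, a$start_bp)
  expect_equal(self$end_bp, a$end_bp)

  # touching at a single shared position counts as overlap
  t1 <- a[1, ]
  t2 <- t1
  t2$start_bp <- t1$end_bp
  t2$end_bp <- t1$end_bp + 1e6
  touch <- common_regions(t1, t2)
  expect_equal(nrow(touch), 1L)
  expect_equal(touch$start_bp, touch$end_bp)

  # evidence filtering: putative regions excluded at the default min_class
  put <- a
  put$evidence_class <- "putative"
  expect_equal(nrow(common_regions(put, b)), 0L)
  expect_equal(nrow(common_regions(put, b, min_class = "putative")), 1L)
})

test_that("Venn counts are reference-oriented and sum to the reference total", {
  mk <- function(start, end, chrom = "1") {
    tibble::tibble(
      chrom = chrom, start_bp = start * 1e6, end_bp = end * 1e6,
      peak_bp = (start + end) / 2 * 1e6, peak_logbf = 9,
      evidence_class = "qtl"
    )
  }
  empty <- mk(numeric(0), numeric(0))
  all0 <- venn_counts(list(A = empty, B = empty, C = empty))
  expect_equal(all0$count, rep(0L, 4))

  a <- mk(1, 2)
  b <- mk(1.5, 3)
  v <- venn_counts(list(A = a, B = b, C = empty), reference = "A")
  expect_equal(v$count[v$cell == "A & B"], 1L)
  expect_equal(v$count[v$cell == "all three"], 0L)

  same <- mk(5, 6)
  v3 <- venn_counts(list(A = same, B = same, C = same))
  expect_equal(v3$count[v3$cell == "all three"], 1L)
  expect_equal(sum(v3$count), 1L)

  ref <- dplyr::bind_rows(mk(1, 2), mk(10, 11), mk(20, 21))
  v4 <- venn_counts(list(A = ref, B = b, C = mk(10.5, 10.6)))
  expect_equal(sum(v4$count), nrow(ref))
  expect_error(venn_counts(list(A = a, B = b)), "three")
})

test_that("gene annotation reports overlaps and nearest genes with Mb distances", {
  genes <- candidate_gene_intervals()
  us6 <- qtl_reference_regions("US")[qtl_reference_regions("US")$chrom == "6", ]
  ann <- annotate_genes(us6, genes)
  # the vitamin D binding protein gene lies inside the chr6 region
  expect_true(any(ann$gene_symbol == "GC" & ann$relation == "overlap"))

  # nearest-gene fallback: gap of 0.2 Mb to the downstream gene
  region <- tibble::tibble(chrom = "9", start_bp = 10.0e6, end_bp = 11.0e6)
  g2 <- tibble::tibble(
    gene_symbol = c("up", "down"), chrom = "9",
    start_bp = c(8.0e6, 11.2e6), end_bp = c(9.5e6, 12.0e6)
  )
  near <- annotate_genes(region, g2)
  expect_equal(nrow(near), 1L)
  expect_identical(near$gene_symbol, "down")
  expect_identical(near$relation, "nearest")
  expect_equal(near$distance_mb, 0.200)

  # no same-chromosome genes -> no annotation rows for that region
  lonely <- tibble::tibble(chrom = "12", start_bp = 1e6, end_bp = 2e6)
  expect_equal(nrow(annotate_genes(lonely, g2)), 0L)
  expect_equal(nrow(annotate_genes(us6, g2[0, ])), 0L)
})

test_that("peak distances are symmetric Mb gaps on a shared chromosome", {
  expect_equal(peak_distance(88.922e6, 88.745e6), 0.177)
  expect_equal(peak_distance(5e6, 5e6), 0)
  expect_equal(peak_distance(1e6, 4e6), peak_distance(4e6, 1e6))
  expect_error(peak_distance(1e6, 2e6, chrom_a = "1", chrom_b = "2"), "chromosome")
})

test_that("gene intervals read from BED and GFF3 with coordinate conventions", {
  genes <- candidate_gene_intervals()[1:4, ]
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(sprintf(
    "%s\t%d\t%d\t%s\t0\t%s",
    genes$chrom, genes$start_bp - 1, genes$end_bp, genes$gene_symbol,
    ifelse(genes$strand == ".", "+", genes$strand)
  ), bed)
  from_bed <- read_gene_intervals(bed)
  # both are sorted by (chrom, start); BED start is 0-based half-open
  expect_equal(from_bed$start_bp, genes$start_bp)
  expect_equal(from_bed$end_bp, genes$end_bp)
  expect_identical(from_bed$gene_symbol, genes$gene_symbol)

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    sprintf(
      "%s\ttest\tgene\t%d\t%d\t.\t+\t.\tID=gene:%s;Name=%s",
      genes$chrom, genes$start_bp, genes$end_bp, genes$gene_symbol, genes$gene_symbol
    ),
    sprintf(
      "%s\ttest\texon\t%d\t%d\t.\t+\t.\tID=exon:%s",
      genes$chrom, genes$start_bp, genes$start_bp + 10, genes$gene_symbol
    )
  ), gff)
  from_gff <- read_gene_intervals(gff)
  expect_equal(nrow(from_gff), 4L) # exon features dropped
  expect_setequal(from_gff$gene_symbol, genes$gene_symbol)
  expect_equal(sort(from_gff$start_bp), sort(genes$start_bp))
})

test_that("common regions export mirrors the reported table layout", {
  us <- qtl_reference_regions("US")
  my <- qtl_reference_regions("MY")
  common <- common_regions(us, my, trait_a = "US", trait_b = "MY")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  out <- write_common_regions_tsv(common, tsv)
  expect_true("US - MY" %in% out$traits)
  row6 <- out[out$chrom == "6", ]
  expect_identical(row6$common_end_mb, "88.959000")
  bed <- withr::local_tempfile(fileext = ".bed")
  bed_out <- write_common_regions_bed(common, bed)
  expect_equal(bed_out$end - bed_out$start, as.integer(common$end_bp - common$start_bp) + 1L)
})
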