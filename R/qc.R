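#' Per-marker allele frequencies
#'
#' Frequency of allele 1 at each marker, computed on non-missing calls only:
#' `p = (2 n_hom1 + n_het) / (2 n_nonmissing)`. In the `{-1, 0, 1}` coding
#' this is `(mean(z) + 1) / 2`.
#'
#' @param G A [geno_matrix()]; every marker needs at least one non-missing call.
#' @return Tibble `marker_id`, `p`.
#' @export
allele_frequencies <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  nonmiss <- colSums(!is.na(G$geno))
  if (any(nonmiss == 0)) stop("some markers are fully missing", call. = FALSE)
  tibble::tibble(
    marker_id = G$map$marker_id,
    p = unname((colMeans(G$geno, na.rm = TRUE) + 1) / 2)
  )
}

#' Call-rate marker filter
#'
#' Retains markers whose fraction of non-missing calls is strictly greater
#' than `threshold` (a marker observed in exactly 90% of animals is removed
#' at the default).
#'
#' @param G A [geno_matrix()].
#' @param threshold Call-rate threshold in (0, 1].
#' @return Filtered `geno_matrix`, marker map order preserved.
#' @export
call_rate_filter <- function(G, threshold = 0.90) {
  stopifnot(inherits(G, "geno_matrix"), threshold > 0, threshold <= 1)
  if (n_markers(G) == 0 || n_animals(G) == 0) stop("empty genotype matrix", call. = FALSE)
  rate <- colMeans(!is.na(G$geno))
  subset_markers(G, rate > threshold)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom goodness-of-fit test of observed genotype counts
#' against Hardy-Weinberg expectations at the sample allele frequency,
#' using the closed form
#' `chi2 = n (4 n_AA n_aa - n_Aa^2)^2 / (n_A n_a)^2` with allele counts
#' `n_A = 2 n_AA + n_Aa`, `n_a = 2 n_aa + n_Aa`. Monomorphic markers return
#' `p = 1`. Vectorized over count triples.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (hom allele 1, het, hom allele 2).
#' @return Upper-tail chi-square p-value(s).
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative", call. = FALSE)
  n <- n_AA + n_Aa + n_aa
  if (any(n == 0)) stop("at least one genotype call is required", call. = FALSE)
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  chi2 <- ifelse(nA == 0 | na == 0, 0,
    n * (4 * n_AA * n_aa - n_Aa^2)^2 / (nA * na)^2
  )
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

#' Hardy-Weinberg marker filter
#'
#' Retains markers whose HWE test p-value (on non-missing calls) is strictly
#' greater than `p_threshold`.
#'
#' @param G A [geno_matrix()].
#' @param p_threshold Significance cut-off (default `1e-4`).
#' @return Filtered `geno_matrix`.
#' @export
hwe_filter <- function(G, p_threshold = 1e-4) {
  stopifnot(inherits(G, "geno_matrix"), p_threshold > 0)
  p <- marker_hwe_p(G)
  subset_markers(G, p > p_threshold)
}

marker_hwe_p <- function(G) {
  z <- G$geno
  hwe_test(
    colSums(z == 1, na.rm = TRUE),
    colSums(z == 0, na.rm = TRUE),
    colSums(z == -1, na.rm = TRUE)
  )
}

#' Run the genotype editing filters
#'
#' Applies the call-rate filter then the HWE filter, and reports per-marker
#' QC metrics. Both filters are idempotent.
#'
#' @param G A [geno_matrix()].
#' @param call_rate_threshold Call-rate cut-off (kept if strictly above).
#' @param hwe_p_threshold HWE p-value cut-off (kept if strictly above).
#' @return List with `genotypes` (filtered `geno_matrix`) and `report`
#'   (tibble `marker_id`, `call_rate`, `hwe_p`, `kept`). The HWE p-value in
#'   the report is computed after the call-rate filter for retained markers.
#' @export
run_qc <- function(G, call_rate_threshold = 0.90, hwe_p_threshold = 1e-4) {
  rate <- colMeans(!is.na(G$geno))
  g1 <- call_rate_filter(G, call_rate_threshold)
  hwe_p_all <- rep(NA_real_, n_markers(G))
  names(hwe_p_all) <- G$map$marker_id
  hwe_p_all[g1$map$marker_id] <- marker_hwe_p(g1)
  g2 <- hwe_filter(g1, hwe_p_threshold)
  report <- tibble::tibble(
    marker_id = G$map$marker_id,
    call_rate = unname(rate),
    hwe_p = unname(hwe_p_all),
    kept = G$map$marker_id %in% g2$map$marker_id
  )
  list(genotypes = g2, report = report)
}

#' Write a QC report TSV
#' @param report Report tibble from [run_qc()].
#' @param path Output path.
#' @export
write_qc_report <- function(report, path) {
  readr::write_tsv(report, path, progress = FALSE)
  invisible(report)
}
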