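#' Simulation configuration
#'
#' Collects the parameters of the synthetic half-sib population used to
#' exercise the pipeline: genotypes with block linkage disequilibrium,
#' a trait with a small number of medium/large-effect QTL on a polygenic
#' background, and DEBV-style pseudo-phenotypes with per-animal reliabilities.
#'
#' Defaults describe a desk-scale progeny-test population: 1,000 animals in
#' 78 paternal half-sib families, 10,000 SNP on 10 chromosomes of 100 Mb,
#' minor-allele frequencies in \[0.05, 0.5\], LD blocks of 20 markers, 10 QTL
#' jointly carrying 60% of a heritability-0.4 genetic variance, and DEBV
#' reliabilities in \[0.05, 0.33\].
#'
#' @param n_animals,n_snps,n_chromosomes,n_sires Population counts.
#' @param chrom_length_mb Chromosome length in Mb.
#' @param maf_min,maf_max Allele-frequency bounds, in (0, 0.5].
#' @param ld_block_len Markers per LD block (1 = linkage equilibrium).
#' @param n_qtl Number of planted QTL.
#' @param h2 Narrow-sense heritability in \[0, 1).
#' @param qtl_var_fraction Fraction of genetic variance on planted QTL.
#' @param reliability_min,reliability_max DEBV reliability range, in (0, 1).
#' @param missing_rate Fraction of genotype calls masked as missing.
#' @param seed RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_animals = 1000, n_snps = 10000, n_chromosomes = 10,
                       chrom_length_mb = 100, maf_min = 0.05, maf_max = 0.5,
                       ld_block_len = 20, n_sires = 78, n_qtl = 10, h2 = 0.4,
                       qtl_var_fraction = 0.6, reliability_min = 0.05,
                       reliability_max = 0.33, missing_rate = 0.02, seed = 1L) {
  cfg <- list(
    n_animals = n_animals, n_snps = n_snps, n_chromosomes = n_chromosomes,
    chrom_length_mb = chrom_length_mb, maf_min = maf_min, maf_max = maf_max,
    ld_block_len = ld_block_len, n_sires = n_sires, n_qtl = n_qtl, h2 = h2,
    qtl_var_fraction = qtl_var_fraction, reliability_min = reliability_min,
    reliability_max = reliability_max, missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  counts <- c("n_animals", "n_snps", "n_chromosomes", "ld_block_len", "n_sires")
  for (f in counts) {
    if (cfg[[f]] < 1) stop(sprintf("`%s` must be a positive count", f), call. = FALSE)
  }
  if (cfg$maf_min <= 0 || cfg$maf_max > 0.5 || cfg$maf_min > cfg$maf_max) {
    stop("allele-frequency bounds must satisfy 0 < maf_min <= maf_max <= 0.5", call. = FALSE)
  }
  if (cfg$h2 < 0 || cfg$h2 > 1) stop("`h2` must lie in [0, 1]", call. = FALSE)
  if (cfg$n_qtl > cfg$n_snps) stop("`n_qtl` cannot exceed `n_snps`", call. = FALSE)
  if (cfg$qtl_var_fraction < 0 || cfg$qtl_var_fraction > 1) {
    stop("`qtl_var_fraction` must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$reliability_min <= 0 || cfg$reliability_max >= 1 ||
    cfg$reliability_min > cfg$reliability_max) {
    stop("reliabilities must lie in (0, 1)", call. = FALSE)
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    stop("`missing_rate` must lie in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

# Split n items as evenly as possible over k groups.
split_counts <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + (seq_len(k) <= extra)
}

# Draw n_h haplotypes for one chromosome: per LD block each haplotype copies
# one of `n_founders` founder haplotypes, then mutates each site (resampling
# from Bernoulli(p_j), which preserves the per-site marginal frequency).
draw_haplotypes <- function(n_h, founders, blk, p, mut_rate) {
  k <- nrow(founders)
  m <- ncol(founders)
  choice <- matrix(sample.int(k, n_h * max(blk), replace = TRUE), n_h, max(blk))
  ce <- choice[, blk, drop = FALSE] # n_h x m founder index per site
  site <- rep(seq_len(m), each = n_h)
  H <- matrix(founders[cbind(as.vector(ce), site)], n_h, m)
  mask <- matrix(stats::runif(n_h * m) < mut_rate, n_h, m)
  if (any(mask)) {
    H[mask] <- stats::rbinom(sum(mask), 1L, rep(p, each = n_h)[mask])
  }
  H
}

#' Simulate genotypes for a half-sib population with block LD
#'
#' Haplotypes are generated by a copy-with-mutation scheme: each LD block has
#' a small pool of founder haplotype segments; a population haplotype copies
#' one founder per block (block boundaries act as recombination points) and
#' mutates each site with a small probability by resampling from the site's
#' allele frequency. Each animal receives one paternal haplotype assembled
#' from the two haplotypes of its sire (one of the 78-style half-sib sires)
#' and one maternal haplotype drawn fresh from the population.
#'
#' @param cfg A [sim_config()].
#' @return A [geno_matrix()] with `n_animals` x `n_snps` entries in
#'   `{-1, 0, 1}` plus `NA` at `missing_rate`, and attribute `sire` giving the
#'   sire index of each animal.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_animals
  n_founders <- 10L
  mut_rate <- 0.03
  m_per_chrom <- split_counts(cfg$n_snps, cfg$n_chromosomes)
  sire <- rep_len(seq_len(cfg$n_sires), n)

  geno <- matrix(NA_real_, n, cfg$n_snps)
  maps <- vector("list", cfg$n_chromosomes)
  col0 <- 0L
  for (cc in seq_len(cfg$n_chromosomes)) {
    m <- m_per_chrom[cc]
    if (m == 0L) next
    pos <- sort(sample.int(cfg$chrom_length_mb * 1e6, m))
    p <- stats::runif(m, cfg$maf_min, cfg$maf_max)
    blk <- ceiling(seq_len(m) / cfg$ld_block_len)
    # founder pool: per site, floor/ceil(k*p) founders carry allele 1
    # (stochastic rounding keeps the expected pool frequency at p)
    k1 <- floor(n_founders * p) +
      (stats::runif(m) < (n_founders * p - floor(n_founders * p)))
    founders <- matrix(0L, n_founders, m)
    for (j in seq_len(m)) {
      if (k1[j] > 0) founders[sample.int(n_founders, k1[j]), j] <- 1L
    }
    sire_haps <- draw_haplotypes(2L * cfg$n_sires, founders, blk, p, mut_rate)
    dam_haps <- draw_haplotypes(n, founders, blk, p, mut_rate)
    # paternal haplotype: per block pick one of the sire's two haplotypes
    pick <- matrix(sample.int(2L, n * max(blk), replace = TRUE), n, max(blk))
    hap_row <- 2L * (sire - 1L) + pick[, blk, drop = FALSE] # n x m
    site <- rep(seq_len(m), each = n)
    pat <- matrix(sire_haps[cbind(as.vector(hap_row), site)], n, m)
    geno[, col0 + seq_len(m)] <- pat + dam_haps - 1
    maps[[cc]] <- tibble::tibble(
      marker_id = sprintf("snp_%d_%d", cc, seq_len(m)),
      chrom = as.character(cc), pos_bp = pos
    )
    col0 <- col0 + m
  }
  map <- dplyr::bind_rows(maps)
  if (cfg$missing_rate > 0) {
    miss <- stats::runif(length(geno)) < cfg$missing_rate
    geno[miss] <- NA_real_
  }
  rownames(geno) <- sprintf("animal_%d", seq_len(n))
  colnames(geno) <- map$marker_id
  G <- geno_matrix(geno, map)
  attr(G, "sire") <- sire
  G
}

#' Simulate a quantitative trait with planted QTL
#'
#' Builds `y = mu + Z_qtl a + u_polygenic + e` on the coded genotypes. The QTL
#' term, the polygenic term (small effects on every non-QTL marker) and the
#' residual are each rescaled to their exact target sample variances so the
#' realized heritability tracks `cfg$h2` and the planted QTL jointly explain
#' `cfg$qtl_var_fraction` of the genetic variance.
#'
#' @param G A complete (or mean-imputed) [geno_matrix()].
#' @param cfg A [sim_config()]; `h2 = 1` is rejected (a positive residual
#'   variance is required).
#' @param qtl_indices,qtl_effects Optional planted QTL marker indices and raw
#'   effect sizes (before variance scaling), e.g. to share QTL across traits.
#' @param mu Trait mean.
#' @param trait Trait label stored in the phenotype table.
#' @return A list with `phen` (tibble `animal_id`, `value`, `weight` = 1,
#'   `trait`) and `truth` (list of class `sim_truth`: `qtl_indices`,
#'   `qtl_effects` on the final scale, `sigma2_u_true`, `sigma2_e_true`,
#'   `true_breeding_values`).
#' @export
simulate_traits <- function(G, cfg, qtl_indices = NULL, qtl_effects = NULL,
                            mu = 0, trait = "trait") {
  stopifnot(inherits(G, "geno_matrix"), inherits(cfg, "sim_config"))
  if (anyNA(G$geno)) {
    stop("genotypes contain missing calls; run mean_impute() first", call. = FALSE)
  }
  if (cfg$h2 >= 1) stop("`h2` = 1 is not allowed: residual variance must be positive", call. = FALSE)
  set.seed(cfg$seed + 1L)
  n <- n_animals(G)
  m <- n_markers(G)
  Z <- G$geno
  polymorphic <- which(matrixStats_colVars(Z) > 0)
  if (is.null(qtl_indices)) {
    if (length(polymorphic) < cfg$n_qtl) stop("not enough polymorphic markers for the requested QTL", call. = FALSE)
    qtl_indices <- sort(sample(polymorphic, cfg$n_qtl))
  }
  if (is.null(qtl_effects)) qtl_effects <- stats::rnorm(length(qtl_indices))
  stopifnot(length(qtl_indices) == length(qtl_effects))

  scale_to_var <- function(x, v) {
    s <- stats::sd(x)
    if (v <= 0 || s == 0) return(list(x = x * 0, f = 0))
    f <- sqrt(v) / s
    list(x = x * f, f = f)
  }
  var_qtl <- cfg$h2 * cfg$qtl_var_fraction
  var_poly <- cfg$h2 * (1 - cfg$qtl_var_fraction)
  g_qtl <- as.vector(Z[, qtl_indices, drop = FALSE] %*% qtl_effects)
  sq <- scale_to_var(g_qtl, var_qtl)
  u_poly <- 0
  if (var_poly > 0) {
    bg <- setdiff(seq_len(m), qtl_indices)
    b <- stats::rnorm(length(bg))
    u_poly <- scale_to_var(as.vector(Z[, bg, drop = FALSE] %*% b), var_poly)$x
  }
  tbv <- sq$x + u_poly
  names(tbv) <- rownames(Z)
  e <- scale_to_var(stats::rnorm(n), 1 - cfg$h2)$x
  y <- mu + tbv + e
  truth <- structure(list(
    qtl_indices = qtl_indices,
    qtl_marker_id = G$map$marker_id[qtl_indices],
    qtl_effects = qtl_effects * sq$f,
    sigma2_u_true = stats::var(tbv),
    sigma2_e_true = stats::var(e),
    true_breeding_values = tbv
  ), class = "sim_truth")
  phen <- tibble::tibble(
    animal_id = rownames(Z), value = unname(y), weight = 1, trait = trait
  )
  list(phen = phen, truth = truth)
}

# colVars without a matrixStats dependency
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(0, ncol(X)))
  mu <- colMeans(X)
  (colSums(X^2) - n * mu^2) / (n - 1)
}

#' Simulate DEBV pseudo-phenotypes with reliability weights
#'
#' Deregressed EBV are emulated as the true breeding value plus noise whose
#' variance follows the reliability `r` of the underlying evaluation:
#' `Var(noise) = sigma2_u (1 - r) / r`, so that `r` is the squared correlation
#' between pseudo-phenotype and breeding value in expectation. The residual
#' weight is the standard reliability mapping `w = r / (1 - r)`.
#'
#' @param truth A `sim_truth` from [simulate_traits()].
#' @param cfg A [sim_config()]; reliabilities are drawn uniformly in
#'   `[reliability_min, reliability_max]`.
#' @param reliability Optional explicit per-animal reliabilities in (0, 1).
#' @param trait Trait label.
#' @return Tibble `animal_id`, `value`, `weight`, `reliability`, `trait`.
#' @export
simulate_debv <- function(truth, cfg, reliability = NULL, trait = "trait_debv") {
  stopifnot(inherits(truth, "sim_truth"))
  tbv <- truth$true_breeding_values
  n <- length(tbv)
  set.seed(cfg$seed + 2L)
  if (is.null(reliability)) {
    reliability <- stats::runif(n, cfg$reliability_min, cfg$reliability_max)
  }
  if (any(reliability <= 0) || any(reliability >= 1)) {
    stop("reliabilities must lie strictly in (0, 1)", call. = FALSE)
  }
  noise_sd <- sqrt(truth$sigma2_u_true * (1 - reliability) / reliability)
  tibble::tibble(
    animal_id = names(tbv) %||% sprintf("animal_%d", seq_len(n)),
    value = tbv + stats::rnorm(n, 0, noise_sd),
    weight = reliability / (1 - reliability),
    reliability = reliability,
    trait = trait
  )
}

#' Milk-yield weighted average of day-60 and day-120 measurements
#'
#' Combines the weigh-suckle-weigh milk measurements taken at the 60th and
#' 120th day after calving with weights one-third and two-thirds.
#'
#' @param m60,m120 Non-negative milk measurements (kg), vectorized.
#' @return `(1/3) m60 + (2/3) m120` in kg.
#' @export
my_combine <- function(m60, m120) {
  if (any(m60 < 0, na.rm = TRUE) || any(m120 < 0, na.rm = TRUE)) {
    stop("milk measurements must be non-negative", call. = FALSE)
  }
  m60 / 3 + 2 * m120 / 3
}

#' Write simulation truth as TSV
#'
#' @param truth A `sim_truth`.
#' @param path Output path.
#' @export
write_sim_truth <- function(truth, path) {
  readr::write_tsv(tibble::tibble(
    marker_index = truth$qtl_indices,
    marker_id = truth$qtl_marker_id,
    effect = truth$qtl_effects,
    sigma2_u_true = truth$sigma2_u_true,
    sigma2_e_true = truth$sigma2_e_true
  ), path, progress = FALSE)
  invisible(truth)
}
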