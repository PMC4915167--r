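small_cfg <- function(...) {
  args <- utils::modifyList(
    list(
      n_animals = 200, n_snps = 600, n_chromosomes = 2, n_sires = 20,
      n_qtl = 5, missing_rate = 0, seed = 11
    ),
    list(...)
  )
  do.call(sim_config, args)
}

test_that("simulated genotypes respect coding, missingness and map ordering", {
  cfg <- small_cfg(missing_rate = 0.05)
  G <- simulate_genotypes(cfg)
  expect_s3_class(G, "geno_matrix")
  expect_equal(dim(G$geno), c(200, 600))
  expect_true(all(G$geno[!is.na(G$geno)] %in% c(-1, 0, 1)))
  expect_gt(mean(is.na(G$geno)), 0.04)
  expect_lt(mean(is.na(G$geno)), 0.06)
  by_chrom <- split(G$map$pos_bp, G$map$chrom)
  expect_true(all(vapply(by_chrom, function(p) !is.unsorted(p, strictly = TRUE), TRUE)))

  expect_false(anyNA(simulate_genotypes(small_cfg())$geno))
})

test_that("missing fraction tracks missing_rate within 0.01 at >= 1e5 calls", {
  cfg <- sim_config(
    n_animals = 250, n_snps = 500, n_chromosomes = 2, n_sires = 20,
    missing_rate = 0.1, seed = 4
  )
  G <- simulate_genotypes(cfg)
  expect_lt(abs(mean(is.na(G$geno)) - 0.1), 0.01)
})

test_that("genotype simulation is deterministic under a fixed seed", {
  cfg <- small_cfg(missing_rate = 0.03)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$geno, g2$geno)
  expect_identical(g1$map, g2$map)
})

test_that("LD blocks create adjacent-marker r2 well above distant pairs", {
  cfg <- sim_config(
    n_animals = 400, n_snps = 1000, n_chromosomes = 1, n_sires = 40,
    ld_block_len = 20, missing_rate = 0, seed = 21
  )
  G <- simulate_genotypes(cfg)
  blk <- ceiling(seq_len(1000) / 20)
  r2_pair <- function(j, k) suppressWarnings(stats::cor(G$geno[, j], G$geno[, k]))^2
  set.seed(1)
  adj <- which(blk[-1000] == blk[-1]) # same-block adjacent pairs
  adj <- sample(adj, 500)
  r2_adj <- vapply(adj, function(j) r2_pair(j, j + 1), 1.0)
  far <- replicate(500, sample.int(1000, 2))
  r2_far <- apply(far, 2, function(jk) r2_pair(jk[1], jk[2]))
  expect_gt(mean(r2_adj, na.rm = TRUE), mean(r2_far, na.rm = TRUE) + 0.05)
})

test_that("ld_block_len = 1 leaves adjacent pairs at background r2", {
  cfg <- sim_config(
    n_animals = 500, n_snps = 1000, n_chromosomes = 1, n_sires = 50,
    ld_block_len = 1, missing_rate = 0, seed = 22
  )
  G <- simulate_genotypes(cfg)
  r2_pair <- function(j, k) suppressWarnings(stats::cor(G$geno[, j], G$geno[, k]))^2
  set.seed(2)
  r2_adj <- vapply(sample(999, 1000, replace = TRUE), function(j) r2_pair(j, j + 1), 1.0)
  far <- replicate(1000, sample.int(1000, 2))
  r2_far <- apply(far, 2, function(jk) r2_pair(jk[1], jk[2]))
  expect_lt(abs(mean(r2_adj, na.rm = TRUE) - mean(r2_far, na.rm = TRUE)), 0.05)
})

test_that("sample allele frequencies roughly respect the configured bounds", {
  cfg <- sim_config(
    n_animals = 500, n_snps = 800, n_chromosomes = 2, n_sires = 30,
    maf_min = 0.1, maf_max = 0.5, missing_rate = 0, seed = 5
  )
  G <- simulate_genotypes(cfg)
  p <- allele_frequencies(G)$p
  expect_gt(mean(p >= 0.05 & p <= 0.55), 0.9)
})

test_that("simulated traits hit the target heritability decomposition", {
  cfg <- sim_config(
    n_animals = 2000, n_snps = 2000, n_chromosomes = 2, n_sires = 78,
    n_qtl = 10, h2 = 0.4, missing_rate = 0, seed = 31
  )
  G <- simulate_genotypes(cfg)
  sim <- simulate_traits(G, cfg)
  h2_real <- stats::var(sim$truth$true_breeding_values) / stats::var(sim$phen$value)
  expect_lt(abs(h2_real - 0.4), 0.05)
  expect_equal(length(sim$truth$qtl_indices), length(sim$truth$qtl_effects))
  expect_true(all(sim$phen$weight == 1))

  # h2 ~ 1: regression of y on TBV has slope ~ 1
  cfg99 <- sim_config(
    n_animals = 2000, n_snps = 2000, n_chromosomes = 2, n_sires = 78,
    n_qtl = 10, h2 = 0.99, missing_rate = 0, seed = 32
  )
  sim99 <- simulate_traits(G, cfg99)
  slope <- stats::coef(stats::lm(sim99$phen$value ~ sim99$truth$true_breeding_values))[2]
  expect_lt(abs(slope - 1), 0.1)

  # h2 = 0: no genetic signal in the phenotype
  cfg0 <- sim_config(
    n_animals = 2000, n_snps = 2000, n_chromosomes = 2, n_sires = 78,
    n_qtl = 10, h2 = 0, missing_rate = 0, seed = 33
  )
  sim0 <- simulate_traits(G, cfg0)
  expect_equal(stats::var(sim0$truth$true_breeding_values), 0)

  expect_error(
    simulate_traits(G, sim_config(h2 = 1, n_snps = 2000, n_animals = 2000)),
    "residual variance"
  )
})

test_that("a single QTL with full genetic variance explains h2 of the trait", {
  cfg <- sim_config(
    n_animals = 1500, n_snps = 500, n_chromosomes = 1, n_sires = 50,
    n_qtl = 1, h2 = 0.3, qtl_var_fraction = 1, missing_rate = 0, seed = 41
  )
  G <- simulate_genotypes(cfg)
  sim <- simulate_traits(G, cfg)
  z <- G$geno[, sim$truth$qtl_indices]
  ratio <- stats::var(z * sim$truth$qtl_effects) / stats::var(sim$phen$value)
  expect_lt(abs(ratio - 0.3), 0.05)
})

test_that("DEBV pseudo-phenotypes follow the reliability contract", {
  cfg <- small_cfg()
  G <- simulate_genotypes(cfg)
  sim <- simulate_traits(G, cfg)

  # w = r / (1 - r): hand value at r = 0.5, and strictly increasing in r
  d_half <- simulate_debv(sim$truth, cfg, reliability = rep(0.5, 200))
  expect_equal(d_half$weight, rep(1.0, 200))
  set.seed(9)
  r_sorted <- sort(stats::runif(200, 0.05, 0.95))
  d_sorted <- simulate_debv(sim$truth, cfg, reliability = r_sorted)
  expect_true(all(diff(d_sorted$weight) > 0))

  # r -> 1: pseudo-phenotypes collapse onto the breeding values
  d_hi <- simulate_debv(sim$truth, cfg, reliability = rep(0.9999, 200))
  expect_lt(max(abs(d_hi$value - sim$truth$true_breeding_values)), 0.2)

  expect_error(simulate_debv(sim$truth, cfg, reliability = rep(1, 200)), "0, 1")
})

test_that("higher-reliability strata correlate better with the truth", {
  cfg <- sim_config(
    n_animals = 2000, n_snps = 400, n_chromosomes = 1, n_sires = 40,
    h2 = 0.4, missing_rate = 0, seed = 51
  )
  G <- simulate_genotypes(cfg)
  sim <- simulate_traits(G, cfg)
  rel <- rep(c(0.1, 0.9), each = 1000)
  d <- simulate_debv(sim$truth, cfg, reliability = rel)
  tbv <- sim$truth$true_breeding_values
  cor_lo <- stats::cor(d$value[rel == 0.1], tbv[rel == 0.1])
  cor_hi <- stats::cor(d$value[rel == 0.9], tbv[rel == 0.9])
  expect_gt(cor_hi, cor_lo)
})

test_that("milk-yield combination weights day 60 and day 120 as 1/3 and 2/3", {
  expect_equal(my_combine(3, 6), 5)
  expect_equal(my_combine(4.2, 4.2), 4.2)
  expect_equal(my_combine(0, 0), 0)
  expect_equal(my_combine(c(3, 0), c(6, 9)), c(5, 6))
  expect_error(my_combine(-1, 5), "non-negative")
})

test_that("genotype and phenotype TSV round-trips preserve the data", {
  cfg <- small_cfg(missing_rate = 0.05)
  G <- simulate_genotypes(cfg)
  gp <- withr::local_tempfile(fileext = ".tsv")
  mp <- withr::local_tempfile(fileext = ".map")
  write_genotypes(G, gp, mp)
  G2 <- read_genotypes(gp, mp)
  expect_equal(G2$geno, G$geno)
  expect_equal(G2$map, G$map)

  raw <- withr::local_tempfile(fileext = ".raw")
  write_plink_raw(G, raw)
  hdr <- strsplit(readLines(raw, n = 1), " ")[[1]]
  expect_identical(hdr[1:6], c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"))

  sim <- simulate_traits(mean_impute(G), cfg)
  pp <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(sim$phen, pp)
  expect_equal(read_phenotypes(pp), sim$phen)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(sim_config(n_animals = 0), "positive count")
  expect_error(sim_config(maf_min = 0), "maf")
  expect_error(sim_config(maf_max = 0.6), "maf")
  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(sim_config(n_qtl = 50, n_snps = 10), "n_qtl")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
})
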