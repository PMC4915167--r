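#' BayesC model configuration
#'
#' Settings for the Gibbs sampler. The defaults reproduce a full production
#' run: prior inclusion fraction `pi = 0.00025` (0.025% of markers carry an
#' effect at each iteration), 100,000 iterations with a burn-in of 20,000 and
#' no thinning. Shorter chains are appropriate for small instances and tests.
#'
#' Variance priors are scaled-inverse-chi-square. When the scales are left
#' `NULL` they are derived from preliminary variance estimates
#' (`sigma2_u_prior`, `sigma2_e_prior`): the residual scale targets
#' `sigma2_e_prior` and the marker-effect scale targets
#' `sigma2_u_prior / (pi * 2 sum p(1-p))`, i.e. the per-effect variance needed
#' for the included markers to carry the genetic variance. When no preliminary
#' estimates are supplied, half the phenotypic variance is used for each.
#'
#' @param pi Prior inclusion fraction in (0, 1]; `pi = 1` keeps every marker
#'   in the model (the ridge / SNP-BLUP limit).
#' @param n_iter,burn_in,thin Chain length, discarded iterations, keep-every.
#' @param seed RNG seed for the chain.
#' @param prior_df_a,prior_df_e Prior degrees of freedom for the marker-effect
#'   and residual variances.
#' @param prior_scale_a,prior_scale_e Prior scales; `NULL` = derive as above.
#' @param sigma2_u_prior,sigma2_e_prior Preliminary genetic and residual
#'   variance estimates (e.g. from a pedigree BLUP evaluation or the
#'   simulator's truth) used to set prior scales and starting values.
#' @param fix_sigma2_a,fix_sigma2_e Optional fixed values; when given the
#'   corresponding variance is not sampled.
#' @return A list of class `model_config`.
#' @export
model_config <- function(pi = 0.00025, n_iter = 100000, burn_in = 20000,
                         thin = 1, seed = 1L,
                         prior_df_a = 4, prior_scale_a = NULL,
                         prior_df_e = 4, prior_scale_e = NULL,
                         sigma2_u_prior = NULL, sigma2_e_prior = NULL,
                         fix_sigma2_a = NULL, fix_sigma2_e = NULL) {
  if (pi <= 0 || pi > 1) stop("`pi` must lie in (0, 1]", call. = FALSE)
  if (burn_in >= n_iter) stop("`burn_in` must be smaller than `n_iter`", call. = FALSE)
  if (thin < 1) stop("`thin` must be >= 1", call. = FALSE)
  structure(list(
    pi = pi, n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
    thin = as.integer(thin), seed = as.integer(seed),
    prior_df_a = prior_df_a, prior_scale_a = prior_scale_a,
    prior_df_e = prior_df_e, prior_scale_e = prior_scale_e,
    sigma2_u_prior = sigma2_u_prior, sigma2_e_prior = sigma2_e_prior,
    fix_sigma2_a = fix_sigma2_a, fix_sigma2_e = fix_sigma2_e
  ), class = "model_config")
}

#' Mean-impute missing genotype calls
#'
#' Replaces missing entries by the marker's mean coded genotype (a continuous
#' dosage), leaving observed calls untouched; column means are preserved
#' exactly. Model fitting requires a complete matrix.
#'
#' @param G A [geno_matrix()]; each marker needs at least one observed call.
#' @return A complete `geno_matrix`.
#' @export
mean_impute <- function(G) {
  stopifnot(inherits(G, "geno_matrix"))
  z <- G$geno
  if (!anyNA(z)) return(G)
  if (any(colSums(!is.na(z)) == 0)) stop("some markers are fully missing", call. = FALSE)
  mu <- colMeans(z, na.rm = TRUE)
  idx <- which(is.na(z), arr.ind = TRUE)
  z[idx] <- mu[idx[, 2]]
  geno_matrix(z, G$map)
}

#' Genetic variance captured by markers
#'
#' `2 * sum_i p_i (1 - p_i) * sigma2_a`, the additive genetic variance
#' explained by markers with allele frequencies `p` each contributing effect
#' variance `sigma2_a`.
#'
#' @param p Allele frequencies in \[0, 1\] (vector), or the tibble returned by
#'   [allele_frequencies()].
#' @param sigma2_a Per-marker effect variance (>= 0).
#' @return The captured variance (scalar).
#' @export
captured_variance <- function(p, sigma2_a) {
  if (is.data.frame(p)) p <- p$p
  stopifnot(all(p >= 0 & p <= 1), sigma2_a >= 0)
  2 * sum(p * (1 - p)) * sigma2_a
}

#' Fit the BayesC mixture model by Gibbs sampling
#'
#' Samples the model `y_i = mu + sum_j z_ij a_j delta_j + e_i` with
#' `delta_j ~ Bernoulli(pi)`, `a_j ~ N(0, sigma2_a)` for included markers and
#' heteroscedastic residuals `e_i ~ N(0, sigma2_e / w_i)` (unit weights for
#' station traits, reliability-derived weights for DEBV pseudo-phenotypes).
#' Each marker's indicator is drawn from its marginalized conditional (effect
#' integrated out); variances have scaled-inverse-chi-square conditionals.
#' Markers are updated in map order and the chain is reproducible bit-for-bit
#' under a fixed seed.
#'
#' The per-marker inclusion probability `P_i` is the post-burn-in frequency of
#' `delta_j = 1`; Bayes Factors are computed from `P_i` (capped away from 0
#' and 1 by half a sample, see [bayes_factor()]) and `logBF = 2 ln BF`.
#'
#' @param G A complete [geno_matrix()] (run [mean_impute()] first if needed).
#' @param phen Phenotype tibble with `animal_id`, `value` and optionally
#'   `weight` (positive; defaults to 1). Must cover the animals of `G`.
#' @param cfg A [model_config()].
#' @return Object of class `bayesc_fit` with elements `posterior` (tibble
#'   `marker_id`, `chrom`, `pos_bp`, `P`, `mean_effect`, `bf`, `logbf`),
#'   `variance` (list: `sigma2_u_hat`, `sigma2_u_prior`, `fraction_captured`,
#'   posterior means of `sigma2_a`/`sigma2_e`), `chain` (kept-sample tibble),
#'   `config`, and `n_animals`/`n_markers`. Use [tidy()][generics::tidy] /
#'   [glance()][generics::glance] to extract tibble summaries.
#' @export
fit_bayesc <- function(G, phen, cfg = model_config()) {
  stopifnot(inherits(G, "geno_matrix"), inherits(cfg, "model_config"))
  if (anyNA(G$geno)) stop("genotypes contain missing calls; run mean_impute() first", call. = FALSE)
  phen <- tibble::as_tibble(phen)
  stopifnot(all(c("animal_id", "value") %in% names(phen)))
  if (!"weight" %in% names(phen)) phen$weight <- 1
  if (anyDuplicated(phen$animal_id)) stop("one phenotype record per animal is required", call. = FALSE)
  idx <- match(rownames(G$geno), phen$animal_id)
  if (anyNA(idx)) stop("phenotypes missing for some genotyped animals", call. = FALSE)
  y <- phen$value[idx]
  w <- phen$weight[idx]
  if (any(w <= 0)) stop("residual weights must be positive", call. = FALSE)
  if (stats::var(y) == 0) stop("phenotype has zero variance", call. = FALSE)

  Z <- G$geno
  p <- (colMeans(Z) + 1) / 2
  sum2pq <- 2 * sum(p * (1 - p))

  vy <- stats::var(y)
  s2u0 <- cfg$sigma2_u_prior %||% (0.5 * vy)
  s2e0 <- cfg$sigma2_e_prior %||% (0.5 * vy)
  s2a0 <- if (sum2pq > 0) s2u0 / (cfg$pi * sum2pq) else s2u0
  scale_a <- cfg$prior_scale_a %||% (s2a0 * max(cfg$prior_df_a - 2, 1) / cfg$prior_df_a)
  scale_e <- cfg$prior_scale_e %||% (s2e0 * max(cfg$prior_df_e - 2, 1) / cfg$prior_df_e)

  update_a <- is.null(cfg$fix_sigma2_a)
  update_e <- is.null(cfg$fix_sigma2_e)
  # start the chain at the prior mean of each variance
  init_from_scale <- function(scale, df) scale * df / max(df - 2, 1)
  s2a_init <- cfg$fix_sigma2_a %||%
    (if (is.null(cfg$prior_scale_a)) s2a0 else init_from_scale(scale_a, cfg$prior_df_a))
  s2e_init <- cfg$fix_sigma2_e %||%
    (if (is.null(cfg$prior_scale_e)) s2e0 else init_from_scale(scale_e, cfg$prior_df_e))

  set.seed(cfg$seed)
  res <- bayesc_gibbs(
    Z, y, w, cfg$pi, cfg$n_iter, cfg$burn_in, cfg$thin,
    cfg$prior_df_a, scale_a, cfg$prior_df_e, scale_e,
    update_a, update_e, s2a_init, s2e_init
  )

  n_kept <- res$n_kept
  # pi = 1 has no prior odds: BF evidence is undefined in the ridge limit
  bf <- if (cfg$pi < 1) {
    bayes_factor(cap_inclusion_prob(res$P, n_kept), cfg$pi)
  } else {
    rep(NA_real_, length(res$P))
  }
  posterior <- tibble::tibble(
    marker_id = G$map$marker_id,
    chrom = G$map$chrom,
    pos_bp = G$map$pos_bp,
    P = res$P,
    mean_effect = res$mean_effect,
    bf = bf,
    logbf = log_bf(bf)
  )
  s2a_hat <- mean(res$chain_sigma2_a)
  s2e_hat <- mean(res$chain_sigma2_e)
  # marginal per-marker effect variance is pi * sigma2_a under the mixture
  sigma2_u_hat <- captured_variance(p, cfg$pi * s2a_hat)
  variance <- list(
    sigma2_u_hat = sigma2_u_hat,
    sigma2_u_prior = s2u0,
    fraction_captured = sigma2_u_hat / s2u0,
    sigma2_a_hat = s2a_hat,
    sigma2_e_hat = s2e_hat,
    sum_2pq = sum2pq
  )
  chain <- tibble::tibble(
    iter = res$chain_iter,
    mu = res$chain_mu,
    sigma2_a = res$chain_sigma2_a,
    sigma2_e = res$chain_sigma2_e,
    n_included = res$chain_n_included
  )
  structure(list(
    posterior = posterior, variance = variance, chain = chain,
    config = cfg, n_animals = nrow(Z), n_markers = ncol(Z),
    n_kept = n_kept
  ), class = "bayesc_fit")
}

#' @export
print.bayesc_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<bayesc_fit> %d animals, %d markers | pi = %g, %d iterations ",
      "(%d burn-in, %d kept)\n  sigma2_a = %.4g, sigma2_e = %.4g, ",
      "captured genetic variance = %.4g (%.0f%% of prior estimate)\n"
    ),
    x$n_animals, x$n_markers, x$config$pi, x$config$n_iter,
    x$config$burn_in, x$n_kept, x$variance$sigma2_a_hat,
    x$variance$sigma2_e_hat, x$variance$sigma2_u_hat,
    100 * x$variance$fraction_captured
  ))
  invisible(x)
}

#' Tidy a BayesC fit into the per-marker posterior table
#'
#' @param x A `bayesc_fit`.
#' @param ... Unused.
#' @return Tibble `marker_id`, `chrom`, `pos_bp`, `P`, `mean_effect`, `bf`,
#'   `logbf`, one row per marker.
#' @export
tidy.bayesc_fit <- function(x, ...) x$posterior

#' One-row summary of a BayesC fit
#'
#' @param x A `bayesc_fit`.
#' @param ... Unused.
#' @return Tibble with chain settings, posterior-mean variance components,
#'   the marker-captured genetic variance and its fraction of the preliminary
#'   genetic variance estimate.
#' @export
glance.bayesc_fit <- function(x, ...) {
  tibble::tibble(
    n_animals = x$n_animals, n_markers = x$n_markers,
    pi = x$config$pi, n_iter = x$config$n_iter, burn_in = x$config$burn_in,
    n_kept = x$n_kept,
    mu_hat = mean(x$chain$mu),
    sigma2_a_hat = x$variance$sigma2_a_hat,
    sigma2_e_hat = x$variance$sigma2_e_hat,
    sigma2_u_hat = x$variance$sigma2_u_hat,
    sigma2_u_prior = x$variance$sigma2_u_prior,
    fraction_captured = x$variance$fraction_captured,
    mean_n_included = mean(x$chain$n_included)
  )
}

#' Genome-wide logBF plot of a BayesC fit
#'
#' Manhattan-style track of per-marker logBF by position, faceted by
#' chromosome, with the QTL evidence thresholds drawn as horizontal lines.
#'
#' @param object A `bayesc_fit`.
#' @param thresholds logBF reference lines (putative/QTL/major).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bayesc_fit <- function(object, thresholds = c(6, 8, 12), ...) {
  plot_logbf_track(object$posterior, thresholds = thresholds)
}

#' @rdname autoplot.bayesc_fit
#' @param track Per-marker tibble with `chrom`, `pos_bp`, `logbf`.
#' @export
plot_logbf_track <- function(track, thresholds = c(6, 8, 12)) {
  ggplot2::ggplot(track, ggplot2::aes(x = .data$pos_bp / 1e6, y = pmax(.data$logbf, 0))) +
    ggplot2::geom_point(size = 0.4, alpha = 0.7) +
    ggplot2::geom_hline(
      yintercept = thresholds, linetype = "dashed", colour = "grey40"
    ) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = "logBF") +
    ggplot2::theme_minimal()
}

#' Write the per-marker posterior table as TSV
#' @param fit A `bayesc_fit` (or its posterior tibble).
#' @param path Output path.
#' @export
write_posterior <- function(fit, path) {
  tab <- if (inherits(fit, "bayesc_fit")) fit$posterior else fit
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(tab)
}
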