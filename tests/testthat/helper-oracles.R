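# Independent oracles used across the suite. Each re-derives the expected
# behaviour from first principles, without calling the implementation paths
# it checks.

# Hardy-Weinberg chi-square p-value via an explicit observed-vs-expected
# table (the implementation uses an algebraic closed form instead).
oracle_hwe_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * n)
  if (p == 0 || p == 1) return(1)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  observed <- c(n_AA, n_Aa, n_aa)
  chi2 <- sum((observed - expected)^2 / expected)
  stats::pchisq(chi2, df = 1, lower.tail = FALSE)
}

# Ridge / SNP-BLUP posterior mean with an unpenalized intercept, by direct
# linear algebra: the closed form the BayesC sampler must approach when
# pi = 1 and both variances are held fixed.
oracle_ridge <- function(Z, y, sigma2_a, sigma2_e, w = rep(1, length(y))) {
  X <- cbind(1, Z)
  D <- diag(c(0, rep(sigma2_e / sigma2_a, ncol(Z))))
  W <- diag(w)
  coef <- solve(t(X) %*% W %*% X + D, t(X) %*% W %*% y)
  list(mu = coef[1], a = coef[-1])
}

# Step-by-step sliding-window region caller: scans one marker at a time,
# mirroring the published extension rule (frontier = outermost marker with
# logBF above the extension threshold within window_mb beyond the current
# frontier; growth stops at previously called regions).
oracle_call_regions <- function(track, peak_threshold = 8,
                                extension_threshold = 3, window_mb = 0.5) {
  track <- track[order(track$chrom, track$pos_bp), ]
  win <- window_mb * 1e6
  out <- list()
  for (ch in unique(track$chrom)) {
    d <- track[track$chrom == ch, ]
    called <- data.frame(start = numeric(0), end = numeric(0))
    cand <- order(-d$logbf, d$pos_bp)
    cand <- cand[d$logbf[cand] > peak_threshold]
    for (i in cand) {
      inside <- FALSE
      for (r in seq_len(nrow(called))) {
        if (d$pos_bp[i] >= called$start[r] && d$pos_bp[i] <= called$end[r]) inside <- TRUE
      }
      if (inside) next
      lim_up <- Inf
      lim_dn <- -Inf
      for (r in seq_len(nrow(called))) {
        if (called$start[r] > d$pos_bp[i]) lim_up <- min(lim_up, called$start[r])
        if (called$end[r] < d$pos_bp[i]) lim_dn <- max(lim_dn, called$end[r])
      }
      grow <- function(dir) {
        frontier <- d$pos_bp[i]
        repeat {
          best <- NA
          for (j in seq_len(nrow(d))) {
            if (d$logbf[j] <= extension_threshold) next
            pj <- d$pos_bp[j]
            ok <- if (dir > 0) {
              pj > frontier && pj <= frontier + win && pj < lim_up
            } else {
              pj < frontier && pj >= frontier - win && pj > lim_dn
            }
            if (ok && (is.na(best) || (dir > 0 && pj > best) || (dir < 0 && pj < best))) {
              best <- pj
            }
          }
          if (is.na(best)) break
          frontier <- best
        }
        frontier
      }
      lo <- grow(-1)
      hi <- grow(+1)
      called <- rbind(called, data.frame(start = lo, end = hi))
      cls <- if (d$logbf[i] > 12) "major" else if (d$logbf[i] > 8) "qtl" else if (d$logbf[i] > 6) "putative" else "none"
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start_bp = lo, end_bp = hi,
        peak_bp = d$pos_bp[i], peak_logbf = d$logbf[i],
        evidence_class = cls
      )
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(
      chrom = character(), start_bp = numeric(), end_bp = numeric(),
      peak_bp = numeric(), peak_logbf = numeric(), evidence_class = character()
    ))
  }
  res[order(res$chrom, res$start_bp), , drop = FALSE]
}

# Random logBF tracks exercising the region caller: clustered signal plus
# background so peaks, extensions and near-boundary windows all occur.
random_track <- function(n_markers = 100, n_chrom = 2) {
  chrom <- sort(sample(as.character(seq_len(n_chrom)), n_markers, replace = TRUE))
  pos <- unlist(lapply(table(chrom), function(k) sort(sample.int(20e6, k))))
  logbf <- stats::rexp(n_markers, rate = 1 / 2.5)
  boost <- sample.int(n_markers, size = max(1, n_markers %/% 20))
  logbf[boost] <- logbf[boost] + stats::runif(length(boost), 4, 12)
  tibble::tibble(chrom = chrom, pos_bp = as.numeric(pos), logbf = logbf)
}

# Small complete genotype fixture with a hand-controllable matrix.
toy_geno <- function(geno, chrom = NULL, pos = NULL) {
  m <- ncol(geno)
  map <- tibble::tibble(
    marker_id = paste0("m", seq_len(m)),
    chrom = chrom %||% rep("1", m),
    pos_bp = pos %||% seq(1e6, by = 1e6, length.out = m)
  )
  colnames(geno) <- map$marker_id
  rownames(geno) <- paste0("a", seq_len(nrow(geno)))
  geno_matrix(geno, map)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
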