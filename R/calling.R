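#' Bayes Factor of marker inclusion
#'
#' Posterior odds of a marker carrying a non-zero effect over its prior odds:
#' `BF = (P / (1 - P)) / (pi / (1 - pi))`.
#'
#' @param P Posterior inclusion probability in \[0, 1); cap estimates from a
#'   finite chain with [cap_inclusion_prob()] first.
#' @param pi Prior inclusion fraction in (0, 1).
#' @return Bayes Factor(s), `>= 0`.
#' @export
bayes_factor <- function(P, pi) {
  if (any(pi <= 0) || any(pi >= 1)) stop("`pi` must lie strictly in (0, 1)", call. = FALSE)
  if (any(P < 0) || any(P >= 1)) stop("`P` must lie in [0, 1)", call. = FALSE)
  (P / (1 - P)) / (pi / (1 - pi))
}

#' logBF scale
#'
#' Twice the natural logarithm of the Bayes Factor, the scale on which the
#' QTL evidence thresholds are defined (comparable to a likelihood-ratio
#' statistic). `bf = 0` maps to `-Inf`.
#'
#' @param bf Bayes Factor(s) `>= 0`.
#' @return `2 * ln(bf)`.
#' @export
log_bf <- function(bf) {
  if (any(bf < 0, na.rm = TRUE)) stop("`bf` must be non-negative", call. = FALSE)
  ifelse(bf == 0, -Inf, 2 * log(bf))
}

#' @rdname log_bf
#' @param logbf Value(s) on the logBF scale.
#' @return `bf_from_logbf()` inverts the transform: `exp(logbf / 2)`.
#' @export
bf_from_logbf <- function(logbf) exp(logbf / 2)

#' Cap inclusion probabilities away from 0 and 1
#'
#' With `S` kept samples, an empirical `P = 1` (or 0) would make the Bayes
#' Factor infinite (or its log undefined); probabilities are clamped to
#' `[1/(2S), 1 - 1/(2S)]`, a half-sample away from the boundary.
#'
#' @param P Empirical inclusion probabilities.
#' @param n_samples Number of kept posterior samples `S`.
#' @return Capped probabilities.
#' @export
cap_inclusion_prob <- function(P, n_samples) {
  stopifnot(n_samples >= 1)
  eps <- 1 / (2 * n_samples)
  pmin(pmax(P, eps), 1 - eps)
}

#' Expected number of markers in the model per iteration
#'
#' @param pi Prior inclusion fraction.
#' @param n_snps Number of markers.
#' @return `round(pi * n_snps)` as an integer count.
#' @export
expected_selected_count <- function(pi, n_snps) {
  stopifnot(n_snps > 0, pi >= 0, pi <= 1)
  as.integer(round(pi * n_snps))
}

#' Classify QTL evidence from a peak logBF
#'
#' Strict thresholds: `major` above 12 (BF about 400), `qtl` above 8
#' (BF about 55), `putative` above 6, otherwise `none`. Vectorized.
#'
#' @param peak_logbf Peak logBF value(s).
#' @return Character vector in `{"none", "putative", "qtl", "major"}`.
#' @export
classify_evidence <- function(peak_logbf) {
  dplyr::case_when(
    peak_logbf > 12 ~ "major",
    peak_logbf > 8 ~ "qtl",
    peak_logbf > 6 ~ "putative",
    .default = "none"
  )
}

evidence_levels <- c("none", "putative", "qtl", "major")

#' Call QTL regions from a per-marker logBF track
#'
#' A region is seeded at each marker whose logBF exceeds `peak_threshold`
#' (peaks are processed in decreasing logBF order; a peak falling inside an
#' already-called region is merged into it). From the peak the region grows
#' independently in each direction through a sliding window of `window_mb`:
#' while at least one marker with logBF above `extension_threshold` lies
#' within `window_mb` beyond the current frontier, the frontier advances to
#' the outermost such marker. Region bounds are the positions of the last
#' markers so absorbed (the peak position alone when none). Growth never
#' crosses into a previously called region, so regions are disjoint and every
#' super-threshold marker belongs to exactly one region.
#'
#' @param track Tibble with `chrom`, `pos_bp`, `logbf` and optionally
#'   `marker_id` and `P`; sorted internally, duplicate `(chrom, pos_bp)` is an
#'   error.
#' @param peak_threshold logBF needed to seed a region (default 8; use 6 to
#'   also call putative regions).
#' @param extension_threshold logBF needed for a marker to extend a region
#'   and be counted a member (default 3).
#' @param window_mb Sliding-window half-width in Mb (default 0.5).
#' @return Tibble of regions: `chrom`, `start_bp`, `end_bp`, `peak_bp`,
#'   `peak_marker_id`, `peak_logbf`, `evidence_class`, `n_members`,
#'   `member_markers` (list column), and `max_P` when `P` is present.
#' @export
call_regions <- function(track, peak_threshold = 8, extension_threshold = 3,
                         window_mb = 0.5) {
  stopifnot(peak_threshold > 0, extension_threshold > 0, window_mb > 0)
  track <- tibble::as_tibble(track)
  stopifnot(all(c("chrom", "pos_bp", "logbf") %in% names(track)))
  if (!"marker_id" %in% names(track)) {
    track$marker_id <- sprintf("m%d", seq_len(nrow(track)))
  }
  track <- dplyr::arrange(track, .data$chrom, .data$pos_bp)
  if (any(duplicated(track[, c("chrom", "pos_bp")]))) {
    stop("duplicate (chrom, pos_bp) in track", call. = FALSE)
  }
  out <- track |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(~ call_regions_chrom(
      .x, .y$chrom, peak_threshold, extension_threshold, window_mb
    )) |>
    dplyr::bind_rows()
  if (nrow(out) == 0) {
    out <- tibble::tibble(
      chrom = character(), start_bp = numeric(), end_bp = numeric(),
      peak_bp = numeric(), peak_marker_id = character(),
      peak_logbf = numeric(), evidence_class = character(),
      n_members = integer(), member_markers = list()
    )
  }
  dplyr::arrange(out, .data$chrom, .data$start_bp)
}

call_regions_chrom <- function(d, chrom, peak_thr, ext_thr, window_mb) {
  pos <- d$pos_bp
  lb <- d$logbf
  win <- window_mb * 1e6
  peaks <- which(lb > peak_thr)
  if (!length(peaks)) return(NULL)
  peaks <- peaks[order(-lb[peaks], pos[peaks])]
  starts <- numeric(0)
  ends <- numeric(0)
  rows <- list()
  for (pk in peaks) {
    if (length(starts) && any(pos[pk] >= starts & pos[pk] <= ends)) {
      next # lower peak inside an already-called region: merged into it
    }
    # growth limits: never enter a previously called region
    up_lim <- if (any(starts > pos[pk])) min(starts[starts > pos[pk]]) else Inf
    dn_lim <- if (any(ends < pos[pk])) max(ends[ends < pos[pk]]) else -Inf
    frontier_up <- pos[pk]
    repeat {
      qual <- which(lb > ext_thr & pos > frontier_up &
        pos <= frontier_up + win & pos < up_lim)
      if (!length(qual)) break
      frontier_up <- max(pos[qual])
    }
    frontier_dn <- pos[pk]
    repeat {
      qual <- which(lb > ext_thr & pos < frontier_dn &
        pos >= frontier_dn - win & pos > dn_lim)
      if (!length(qual)) break
      frontier_dn <- min(pos[qual])
    }
    starts <- c(starts, frontier_dn)
    ends <- c(ends, frontier_up)
    members <- which(pos >= frontier_dn & pos <= frontier_up & lb > ext_thr)
    if (!length(members)) members <- pk
    row <- tibble::tibble(
      chrom = chrom,
      start_bp = frontier_dn, end_bp = frontier_up,
      peak_bp = pos[pk], peak_marker_id = d$marker_id[pk],
      peak_logbf = lb[pk],
      evidence_class = classify_evidence(lb[pk]),
      n_members = length(members),
      member_markers = list(d$marker_id[members])
    )
    if ("P" %in% names(d)) row$max_P <- max(d$P[members])
    rows[[length(rows) + 1L]] <- row
  }
  dplyr::bind_rows(rows)
}

#' Write called regions as TSV and BED
#'
#' The TSV mirrors the published region-table layout (trait, chromosome,
#' start/end/peak in Mb to 6 decimal places, peak logBF, evidence class);
#' the BED uses the 0-based half-open convention (`start_bp - 1`, `end_bp`).
#'
#' @param regions Region tibble from [call_regions()].
#' @param path Output path.
#' @param trait Optional trait label column value.
#' @export
write_regions_tsv <- function(regions, path, trait = NULL) {
  if (is.null(trait)) {
    trait <- if ("trait" %in% names(regions)) regions$trait else NA_character_
  }
  out <- tibble::tibble(
    trait = trait,
    chrom = regions$chrom,
    start_mb = sprintf("%.6f", regions$start_bp / 1e6),
    end_mb = sprintf("%.6f", regions$end_bp / 1e6),
    peak_mb = sprintf("%.6f", regions$peak_bp / 1e6),
    peak_logbf = regions$peak_logbf,
    evidence_class = regions$evidence_class,
    n_members = regions$n_members
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(out)
}

#' @rdname write_regions_tsv
#' @export
write_regions_bed <- function(regions, path, trait = NULL) {
  if (is.null(trait)) {
    trait <- if ("trait" %in% names(regions)) regions$trait else "region"
  }
  name <- paste0(trait, "_", regions$chrom, ":", regions$peak_bp)
  out <- tibble::tibble(
    chrom = regions$chrom,
    start = as.integer(regions$start_bp) - 1L,
    end = as.integer(regions$end_bp),
    name = name,
    score = round(regions$peak_logbf, 3)
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(out)
}

#' Plot a logBF track with called regions
#'
#' @param track Per-marker tibble (`chrom`, `pos_bp`, `logbf`).
#' @param regions Region tibble from [call_regions()].
#' @param thresholds logBF reference lines.
#' @return A ggplot object.
#' @export
plot_regions <- function(track, regions, thresholds = c(6, 8, 12)) {
  p <- plot_logbf_track(track, thresholds = thresholds)
  if (nrow(regions)) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(
        xmin = .data$start_bp / 1e6, xmax = .data$end_bp / 1e6,
        ymin = -Inf, ymax = Inf
      ),
      inherit.aes = FALSE, fill = "firebrick", alpha = 0.15
    )
  }
  p
}
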