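#' Run the QTL-detection pipeline end to end on synthetic data
#'
#' Orchestrates simulate -> qc -> fit -> call -> compare and writes every
#' artifact to `out_dir`. Three traits are simulated on a shared genotype
#' matrix with a core of QTL common to all traits plus trait-specific QTL, so
#' the cross-trait comparison has true common regions to find. Any prefix of
#' the stages can be run alone via `steps`; later stages read the artifacts
#' of earlier ones from `out_dir`.
#'
#' Every artifact is accompanied by a `run_log.txt` recording the seed, the
#' configuration hash, pi and iteration counts, the markers removed by each
#' QC filter and the per-trait region counts by evidence class. Identical
#' configuration and seed reproduce every output byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim_cfg A [sim_config()].
#' @param model_cfg A [model_config()] template (the seed is offset per trait).
#' @param traits Character vector of three trait labels.
#' @param n_shared_qtl Number of QTL common to all three traits (rest of
#'   `sim_cfg$n_qtl` are trait-specific).
#' @param peak_threshold,extension_threshold,window_mb Region-calling
#'   parameters, see [call_regions()].
#' @param min_class Evidence class required for the cross-trait comparison.
#' @param steps Stages to execute; must be a prefix of
#'   `c("simulate", "qc", "fit", "call", "compare")`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the artifact paths and (when computed) the
#'   per-trait fits, regions, common regions and Venn counts.
#' @export
run_pipeline <- function(out_dir, sim_cfg = sim_config(),
                         model_cfg = model_config(),
                         traits = c("trait_a", "trait_b", "trait_c"),
                         n_shared_qtl = max(1L, sim_cfg$n_qtl %/% 2L),
                         peak_threshold = 8, extension_threshold = 3,
                         window_mb = 0.5, min_class = "qtl",
                         steps = c("simulate", "qc", "fit", "call", "compare"),
                         quiet = FALSE) {
  all_steps <- c("simulate", "qc", "fit", "call", "compare")
  steps <- match.arg(steps, all_steps, several.ok = TRUE)
  if (!identical(steps, all_steps[seq_along(steps)])) {
    stop("`steps` must be a prefix of simulate > qc > fit > call > compare", call. = FALSE)
  }
  stopifnot(length(traits) == 3)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(list(sim_cfg, model_cfg, traits, n_shared_qtl,
    peak_threshold, extension_threshold, window_mb, min_class))
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }
  created <- character(0)
  art <- function(name) {
    p <- file.path(out_dir, name)
    created <<- c(created, p)
    p
  }
  res <- list(out_dir = out_dir, config_hash = cfg_hash)
  on_fail <- function(e) {
    unlink(created)
    stop(sprintf("pipeline failed (%s); partial outputs removed", conditionMessage(e)),
      call. = FALSE
    )
  }
  tryCatch({
    say("run: seed=%d config=%s", sim_cfg$seed, cfg_hash)

    if ("simulate" %in% steps) {
      G <- simulate_genotypes(sim_cfg)
      say("simulate: %d animals x %d markers, %.2f%% missing",
        n_animals(G), n_markers(G), 100 * mean(is.na(G$geno)))
      write_genotypes(G, art("genotypes.tsv"), art("markers.map"))
      Gc <- mean_impute(G)
      set.seed(sim_cfg$seed + 100L)
      poly <- which(matrixStats_colVars(Gc$geno) > 0)
      qtl_pool <- sort(sample(poly, sim_cfg$n_qtl + 2L * (sim_cfg$n_qtl - n_shared_qtl)))
      shared <- sample(qtl_pool, n_shared_qtl)
      rest <- setdiff(qtl_pool, shared)
      own <- split(rest, rep_len(seq_len(3), length(rest)))
      for (k in seq_along(traits)) {
        cfg_k <- sim_cfg
        cfg_k$seed <- sim_cfg$seed + k
        sim <- simulate_traits(Gc, cfg_k,
          qtl_indices = sort(c(shared, own[[k]])), trait = traits[k]
        )
        write_phenotypes(sim$phen, art(sprintf("phenotypes_%s.tsv", traits[k])))
        write_sim_truth(sim$truth, art(sprintf("truth_%s.tsv", traits[k])))
      }
      say("simulate: %d QTL shared across traits, %d per-trait",
        n_shared_qtl, length(own[[1]]))
    }

    if ("qc" %in% steps) {
      G <- read_genotypes(file.path(out_dir, "genotypes.tsv"),
        file.path(out_dir, "markers.map"))
      qc <- run_qc(G)
      n_call <- sum(colMeans(!is.na(G$geno)) <= 0.90)
      say("qc: %d markers in, %d removed by call rate, %d removed by HWE, %d kept",
        n_markers(G), n_call,
        n_markers(G) - n_call - n_markers(qc$genotypes),
        n_markers(qc$genotypes))
      write_qc_report(qc$report, art("qc_report.tsv"))
      write_genotypes(qc$genotypes, art("genotypes_qc.tsv"), art("markers_qc.map"))
    }

    if ("fit" %in% steps) {
      G <- mean_impute(read_genotypes(
        file.path(out_dir, "genotypes_qc.tsv"),
        file.path(out_dir, "markers_qc.map")
      ))
      say("fit: pi=%g, %d iterations (%d burn-in)",
        model_cfg$pi, model_cfg$n_iter, model_cfg$burn_in)
      for (k in seq_along(traits)) {
        phen <- read_phenotypes(file.path(out_dir, sprintf("phenotypes_%s.tsv", traits[k])))
        cfg_k <- model_cfg
        cfg_k$seed <- model_cfg$seed + k
        fit <- fit_bayesc(G, phen, cfg_k)
        res$fits[[traits[k]]] <- fit
        write_posterior(fit, art(sprintf("posterior_%s.tsv", traits[k])))
        readr::write_tsv(glance(fit), art(sprintf("chain_summary_%s.tsv", traits[k])),
          progress = FALSE)
        say("fit[%s]: captured %.0f%% of prior genetic variance",
          traits[k], 100 * fit$variance$fraction_captured)
      }
    }

    if ("call" %in% steps) {
      for (k in seq_along(traits)) {
        post <- readr::read_tsv(
          file.path(out_dir, sprintf("posterior_%s.tsv", traits[k])),
          show_col_types = FALSE, progress = FALSE
        )
        regions <- call_regions(post,
          peak_threshold = peak_threshold,
          extension_threshold = extension_threshold, window_mb = window_mb
        )
        res$regions[[traits[k]]] <- regions
        write_regions_tsv(regions, art(sprintf("regions_%s.tsv", traits[k])),
          trait = traits[k])
        write_regions_bed(regions, art(sprintf("regions_%s.bed", traits[k])),
          trait = traits[k])
        tab <- table(factor(regions$evidence_class, levels = evidence_levels))
        say("call[%s]: %d region(s) [%s]", traits[k], nrow(regions),
          paste(sprintf("%s=%d", names(tab), tab), collapse = ", "))
      }
    }

    if ("compare" %in% steps) {
      regs <- purrr::map(setNames(traits, traits), function(tr) {
        read_regions_tsv(file.path(out_dir, sprintf("regions_%s.tsv", tr)))
      })
      pairs <- utils::combn(traits, 2, simplify = FALSE)
      common <- purrr::map(pairs, ~ common_regions(
        regs[[.x[1]]], regs[[.x[2]]],
        trait_a = .x[1], trait_b = .x[2], min_class = min_class
      )) |> dplyr::bind_rows()
      res$common <- common
      write_common_regions_tsv(common, art("common_regions.tsv"))
      venn <- venn_counts(regs, reference = traits[1], min_class = min_class)
      res$venn <- venn
      readr::write_tsv(venn, art("venn_counts.tsv"), progress = FALSE)
      say("compare: %d common region(s) across trait pairs", nrow(common))
    }

    writeLines(log_lines, log_path)
    res$log <- log_path
    res$artifacts <- created
  }, error = on_fail)
  invisible(res)
}

#' Read a regions TSV written by [write_regions_tsv()]
#'
#' @param path File path.
#' @return Region tibble with bp coordinates restored.
#' @export
read_regions_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE) |>
    dplyr::mutate(
      chrom = as.character(.data$chrom),
      start_bp = round(as.numeric(.data$start_mb) * 1e6),
      end_bp = round(as.numeric(.data$end_mb) * 1e6),
      peak_bp = round(as.numeric(.data$peak_mb) * 1e6)
    )
}
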