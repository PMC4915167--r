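#' Genotype matrix container
#'
#' Bundles an animals x markers genotype matrix with its marker map. Genotypes
#' are coded `z = +1` for the homozygote of allele 1, `0` for the heterozygote
#' and `-1` for the other homozygote; missing calls are `NA`. After
#' [mean_impute()] entries may be fractional dosages on the same scale.
#'
#' @param geno Numeric matrix, animals in rows (rownames = animal ids),
#'   markers in columns (colnames = marker ids), values in `{-1, 0, 1, NA}`.
#' @param map Data frame with one row per marker: `marker_id`, `chrom`,
#'   `pos_bp` (1-based base-pair position), sorted by `(chrom, pos_bp)`.
#' @return An object of class `geno_matrix` (list with elements `geno`, `map`).
#' @export
geno_matrix <- function(geno, map) {
  map <- tibble::as_tibble(map)
  stopifnot(
    is.matrix(geno),
    all(c("marker_id", "chrom", "pos_bp") %in% names(map)),
    nrow(map) == ncol(geno)
  )
  if (is.null(colnames(geno))) colnames(geno) <- map$marker_id
  if (!identical(colnames(geno), as.character(map$marker_id))) {
    stop("column names of `geno` must match `map$marker_id` in order", call. = FALSE)
  }
  if (is.null(rownames(geno))) {
    rownames(geno) <- paste0("animal_", seq_len(nrow(geno)))
  }
  vals <- geno[!is.na(geno)]
  if (length(vals) && (min(vals) < -1 || max(vals) > 1)) {
    stop("genotype codes must lie in [-1, 1]", call. = FALSE)
  }
  # map must be sorted within chromosome and positions unique
  ok <- map |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(sorted = !is.unsorted(.data$pos_bp, strictly = TRUE)) |>
    dplyr::pull(.data$sorted)
  if (!all(ok)) stop("marker map must be strictly increasing within chromosome", call. = FALSE)
  structure(list(geno = geno, map = map), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  nmis <- sum(is.na(x$geno))
  cat(sprintf(
    "<geno_matrix> %d animals x %d markers on %d chromosome(s); %.2f%% missing\n",
    nrow(x$geno), ncol(x$geno), dplyr::n_distinct(x$map$chrom),
    100 * nmis / length(x$geno)
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$geno)

#' Number of animals / markers
#' @param G A [geno_matrix()].
#' @return Integer count.
#' @export
n_animals <- function(G) nrow(G$geno)

#' @rdname n_animals
#' @export
n_markers <- function(G) ncol(G$geno)

#' Subset markers of a genotype matrix
#'
#' @param G A [geno_matrix()].
#' @param keep Logical vector (length = markers) or marker ids to retain.
#' @return A `geno_matrix` with the marker subset, map order preserved.
#' @export
subset_markers <- function(G, keep) {
  if (is.character(keep)) keep <- G$map$marker_id %in% keep
  stopifnot(is.logical(keep), length(keep) == n_markers(G))
  geno_matrix(G$geno[, keep, drop = FALSE], G$map[keep, , drop = FALSE])
}

#' Read / write genotype matrices as TSV
#'
#' The TSV dialect stores dosages of allele 1 in `{0, 1, 2}` (`NA` for missing)
#' with marker ids as header and the animal id in the first column; dosage `d`
#' maps to the internal coding `z = d - 1`. The marker map travels in a
#' separate PLINK `.map`-style 4-column file (chrom, marker id, cM placeholder
#' 0, bp).
#'
#' @param G A [geno_matrix()].
#' @param geno_path,map_path Output/input file paths.
#' @return `write_genotypes()` returns `G` invisibly; `read_genotypes()`
#'   returns a `geno_matrix`.
#' @export
write_genotypes <- function(G, geno_path, map_path) {
  dos <- G$geno + 1
  df <- tibble::as_tibble(dos, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(animal_id = rownames(G$geno)), df)
  readr::write_tsv(df, geno_path, progress = FALSE)
  write_marker_map(G$map, map_path)
  invisible(G)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(geno_path, map_path) {
  df <- readr::read_tsv(geno_path, show_col_types = FALSE, progress = FALSE)
  ids <- df$animal_id
  m <- as.matrix(df[, -1, drop = FALSE]) - 1
  rownames(m) <- ids
  geno_matrix(m, read_marker_map(map_path))
}

#' @rdname write_genotypes
#' @param map Marker-map tibble (`marker_id`, `chrom`, `pos_bp`).
#' @param path File path.
#' @export
write_marker_map <- function(map, path) {
  out <- tibble::tibble(
    chrom = map$chrom, marker_id = map$marker_id,
    cm = 0, pos_bp = map$pos_bp
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(map)
}

#' @rdname write_genotypes
#' @export
read_marker_map <- function(path) {
  readr::read_tsv(path,
    col_names = c("chrom", "marker_id", "cm", "pos_bp"),
    col_types = "ccid", progress = FALSE
  ) |>
    dplyr::select("marker_id", "chrom", "pos_bp")
}

#' Write genotypes in PLINK RAW-compatible dosage format
#'
#' Columns `FID IID PAT MAT SEX PHENOTYPE` then one column per marker with
#' allele-1 dosage in `{0, 1, 2}` (`NA` missing), as produced by
#' `plink --recode A`.
#'
#' @param G A [geno_matrix()].
#' @param path Output path.
#' @export
write_plink_raw <- function(G, path) {
  dos <- tibble::as_tibble(G$geno + 1, .name_repair = "minimal")
  lead <- tibble::tibble(
    FID = rownames(G$geno), IID = rownames(G$geno),
    PAT = 0, MAT = 0, SEX = 0, PHENOTYPE = -9
  )
  readr::write_delim(dplyr::bind_cols(lead, dos), path, delim = " ", progress = FALSE)
  invisible(G)
}

#' Read / write phenotype tables
#'
#' Plain TSV with columns `animal_id`, `value`, `weight` (residual weight,
#' 1 for station traits, reliability-derived for DEBV pseudo-phenotypes).
#'
#' @param phen Phenotype tibble.
#' @param path File path.
#' @export
write_phenotypes <- function(phen, path) {
  readr::write_tsv(phen, path, progress = FALSE)
  invisible(phen)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
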