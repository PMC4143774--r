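# Readers and writers for the canonical interchange formats.
#
# All interchange files are headered, tab-separated, UTF-8, '.' decimal,
# except gene annotations which are standard BED (no header, 0-based
# half-open). Reals are serialized with 12 significant digits so rank ties
# stay stable across platforms.

read_tsv_quiet <- function(path, col_types, comment = "") {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "linkassoc_io_error")
  }
  out <- readr::read_tsv(path, col_types = col_types, comment = comment,
                         progress = FALSE)
  probs <- readr::problems(out)
  if (nrow(probs) > 0L) {
    abort(sprintf("Malformed file %s: first problem at line %d (%s).",
                  path, probs$row[1], probs$expected[1]),
          class = "linkassoc_format_error")
  }
  out
}

check_header <- function(path, expected, comment = "") {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "linkassoc_io_error")
  }
  lines <- readLines(path, n = 50L, warn = FALSE)
  if (nzchar(comment)) lines <- lines[!startsWith(lines, comment)]
  if (length(lines) == 0L) {
    abort(sprintf("Empty file: %s", path), class = "linkassoc_format_error")
  }
  got <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(got, expected)) {
    abort(sprintf("Malformed header in %s: expected '%s', got '%s'.",
                  path, paste(expected, collapse = "\t"),
                  paste(got, collapse = "\t")),
          class = "linkassoc_format_error")
  }
  invisible(TRUE)
}

#' Read multipoint linkage tracks
#'
#' Canonical TSV dialect for multipoint linkage output: header
#' `chrom  pos_cm  lod`, one row per grid position; lines starting with `#`
#' are skipped (variance-components linkage software often prepends run
#' metadata).
#'
#' @param path Path to the TSV file.
#' @return A validated linkage-track tibble (`chrom`, `pos_cm`, `lod`).
#' @export
read_linkage_tracks <- function(path) {
  check_header(path, c("chrom", "pos_cm", "lod"), comment = "#")
  out <- read_tsv_quiet(path, readr::cols(chrom = "c", pos_cm = "d", lod = "d"),
                        comment = "#")
  validate_tracks(out, where = sprintf("linkage tracks (%s)", path))
}

#' Read a genetic map
#'
#' Headered TSV `chrom  bp  cm`: per-chromosome anchors mapping physical
#' position to genetic position, strictly increasing in `bp` and
#' non-decreasing in `cm`. Violations are rejected with the offending file
#' line.
#'
#' @inheritParams read_linkage_tracks
#' @return A validated genetic-map tibble (`chrom`, `bp`, `cm`).
#' @export
read_genetic_map <- function(path) {
  check_header(path, c("chrom", "bp", "cm"))
  out <- read_tsv_quiet(path, readr::cols(chrom = "c", bp = "d", cm = "d"))
  validate_genetic_map(out, where = sprintf("genetic map (%s)", path),
                       line_offset = 1L)
}

#' Read gene annotations from BED
#'
#' Standard BED: no header, tab-separated `chrom  start  end  name`,
#' 0-based half-open intervals. Lines starting with `#`, `track` or
#' `browser` are skipped.
#'
#' @inheritParams read_linkage_tracks
#' @return A validated gene tibble (`gene_id`, `chrom`, `start_bp`,
#'   `end_bp`).
#' @export
read_genes_bed <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "linkassoc_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(lines, "#") & !startsWith(lines, "track") &
    !startsWith(lines, "browser") & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  n_col <- lengths(fields)
  if (length(fields) == 0L || any(n_col < 4L)) {
    bad <- which(keep)[which(n_col < 4L)[1]]
    abort(sprintf("Malformed BED %s: fewer than 4 columns%s.", path,
                  if (length(bad)) sprintf(" (line %d)", bad) else ""),
          class = "linkassoc_format_error")
  }
  genes <- tibble::tibble(
    gene_id = purrr::map_chr(fields, 4),
    chrom = purrr::map_chr(fields, 1),
    start_bp = suppressWarnings(as.integer(purrr::map_chr(fields, 2))),
    end_bp = suppressWarnings(as.integer(purrr::map_chr(fields, 3)))
  )
  if (anyNA(genes$start_bp) || anyNA(genes$end_bp)) {
    bad <- which(keep)[which(is.na(genes$start_bp) | is.na(genes$end_bp))[1]]
    abort(sprintf("Malformed BED %s: non-integer coordinates (line %d).", path, bad),
          class = "linkassoc_format_error")
  }
  bad <- which(genes$start_bp >= genes$end_bp)
  if (length(bad) > 0L) {
    abort(sprintf("BED %s: start >= end (line %d, gene %s).", path,
                  which(keep)[bad[1]], genes$gene_id[bad[1]]),
          class = "linkassoc_validation_error")
  }
  genes
}

#' Read gene-based association results
#'
#' Headered TSV `gene_id  p_assoc`; p-values must lie in (0, 1].
#'
#' @inheritParams read_linkage_tracks
#' @return A tibble (`gene_id`, `p_assoc`).
#' @export
read_assoc <- function(path) {
  check_header(path, c("gene_id", "p_assoc"))
  out <- read_tsv_quiet(path, readr::cols(gene_id = "c", p_assoc = "d"))
  bad <- which(!is.finite(out$p_assoc) | out$p_assoc <= 0 | out$p_assoc > 1)
  if (length(bad) > 0L) {
    abort(sprintf("Association table %s: p_assoc outside (0, 1] (line %d).",
                  path, bad[1] + 1L),
          class = "linkassoc_validation_error")
  }
  out
}

#' Read a permutation-statistic matrix
#'
#' Headered TSV `perm_index  z1  z2`, one row per phenotype permutation.
#'
#' @inheritParams read_linkage_tracks
#' @return A validated tibble (`perm_index`, `z1`, `z2`).
#' @export
read_perm <- function(path) {
  check_header(path, c("perm_index", "z1", "z2"))
  out <- read_tsv_quiet(path, readr::cols(perm_index = "i", z1 = "d", z2 = "d"))
  as_perm_matrix(out)
}

# Serialize doubles at 12 significant digits (readr would write full
# precision, which is noisier to diff and can flip rank ties across libms).
format_doubles <- function(df) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.double),
                                  ~ sprintf("%.12g", .x)))
}

#' Write interchange files
#'
#' Writers matching the canonical dialects of the readers
#' ([read_linkage_tracks()] and friends): headered TSV with doubles at 12
#' significant digits; `write_genes_bed()` writes headerless 4-column BED.
#' `write_combined()` writes a combined-evidence table sorted by
#' `rank_combined`.
#'
#' @param x The object to write (a tibble of the matching shape).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @name la_writers
NULL

#' @rdname la_writers
#' @export
write_linkage_tracks <- function(x, path) {
  readr::write_tsv(format_doubles(validate_tracks(x)[, c("chrom", "pos_cm", "lod")]), path)
  invisible(path)
}

#' @rdname la_writers
#' @export
write_genetic_map <- function(x, path) {
  readr::write_tsv(format_doubles(validate_genetic_map(x)[, c("chrom", "bp", "cm")]), path)
  invisible(path)
}

#' @rdname la_writers
#' @export
write_genes_bed <- function(x, path) {
  x <- validate_genes(x)
  readr::write_tsv(x[, c("chrom", "start_bp", "end_bp", "gene_id")], path,
                   col_names = FALSE)
  invisible(path)
}

#' @rdname la_writers
#' @export
write_assoc <- function(x, path) {
  readr::write_tsv(format_doubles(tibble::as_tibble(x)[, c("gene_id", "p_assoc")]), path)
  invisible(path)
}

#' @rdname la_writers
#' @export
write_perm <- function(x, path) {
  x <- tibble::as_tibble(x)
  if (!"perm_index" %in% names(x)) x$perm_index <- seq_len(nrow(x))
  readr::write_tsv(format_doubles(x[, c("perm_index", "z1", "z2")]), path)
  invisible(path)
}

#' @rdname la_writers
#' @export
write_combined <- function(x, path) {
  cols <- c("gene_id", "mean_lod", "p_linkage", "z1", "p_assoc", "z2", "zc",
            "p_combined", "rank_assoc", "rank_combined")
  if (!all(cols %in% names(x))) {
    abort(sprintf("A combined table needs columns %s.", paste(cols, collapse = ", ")),
          class = "linkassoc_invalid_input")
  }
  out <- tibble::as_tibble(x)[, cols]
  out <- out[order(out$rank_combined), ]
  readr::write_tsv(format_doubles(out), path)
  invisible(path)
}

#' Write a full synthetic input set
#'
#' Generates a coherent directory of inputs for the `combine` pipeline — a
#' genetic map, a peaked LOD track, a gene BED, gene-based association
#' p-values (upper tail of the simulated `z2`), a permutation matrix — plus
#' a `config.yaml` recording every generator parameter including the seed.
#' Causal genes are placed under the LOD peak.
#'
#' @param dir Output directory (created if missing).
#' @param config A [sim_config()]; `n_genes` genes are placed on one
#'   chromosome.
#' @param chrom Chromosome label; default "3".
#' @param length_bp,length_cm Chromosome sizes; defaults 2e8 bp / 200 cM.
#' @param peak LOD peak spec as in [simulate_lod_landscape()]; default a
#'   height-2 peak at 60 cM.
#' @return Named character vector of the files written, invisibly.
#' @export
write_simulated_inputs <- function(dir, config = sim_config(), chrom = "3",
                                   length_bp = 2e8, length_cm = 200,
                                   peak = list(pos = 60, height = 2, width = 8)) {
  config <- as_config(config)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  map <- simulate_genetic_map(chrom, length_bp, length_cm, seed = config$seed)
  track <- simulate_lod_landscape(1, length_cm, peak = peak,
                                  seed = config$seed + 1L, chrom = chrom)
  genes <- simulate_genes(config$n_genes, chrom, length_bp,
                          seed = config$seed + 2L)
  pairs <- simulate_stat_pairs(config)
  assoc <- tibble::tibble(gene_id = pairs$gene_id,
                          p_assoc = pnorm(pairs$z2, lower.tail = FALSE))
  perm <- simulate_permutation_matrix(config)
  paths <- c(
    map = file.path(dir, "genetic_map.tsv"),
    tracks = file.path(dir, "linkage_tracks.tsv"),
    genes = file.path(dir, "genes.bed"),
    assoc = file.path(dir, "assoc.tsv"),
    perm = file.path(dir, "perm.tsv"),
    config = file.path(dir, "config.yaml")
  )
  write_genetic_map(map, paths[["map"]])
  write_linkage_tracks(track, paths[["tracks"]])
  write_genes_bed(genes, paths[["genes"]])
  write_assoc(assoc, paths[["assoc"]])
  write_perm(perm, paths[["perm"]])
  yaml::write_yaml(c(unclass(config),
                     list(chrom = chrom, length_bp = length_bp,
                          length_cm = length_cm, peak = peak)),
                   paths[["config"]])
  invisible(paths)
}
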