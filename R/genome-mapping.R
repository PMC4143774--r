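# Physical -> genetic coordinate mapping and gene-level LOD assignment.
#
# Conventions: genes come from BED and are 0-based half-open; genetic-map
# anchors are point positions taken as written; chromosome ids are matched
# after stripping any "chr" prefix ("3" == "chr3").

norm_chrom <- function(x) sub("^chr", "", tolower(as.character(x)))

loc_label <- function(row, line_offset = NULL) {
  if (is.null(line_offset)) sprintf("row %d", row)
  else sprintf("line %d", row + line_offset)
}

validate_genetic_map <- function(map, where = "genetic map", line_offset = NULL) {
  need <- c("chrom", "bp", "cm")
  if (!is.data.frame(map) || !all(need %in% names(map))) {
    abort(sprintf("%s needs columns %s.", where, paste(need, collapse = ", ")),
          class = "linkassoc_invalid_input")
  }
  map <- tibble::as_tibble(map)
  by_chr <- split(seq_len(nrow(map)), norm_chrom(map$chrom))
  for (chr in names(by_chr)) {
    i <- by_chr[[chr]]
    if (length(i) < 2L) {
      abort(sprintf("%s: chromosome %s has fewer than 2 anchors.", where, chr),
            class = "linkassoc_validation_error")
    }
    bp <- map$bp[i]; cm <- map$cm[i]
    if (any(!is.finite(bp)) || any(!is.finite(cm)) || any(bp < 0) || any(cm < 0)) {
      abort(sprintf("%s: chromosome %s has non-finite or negative anchors.", where, chr),
            class = "linkassoc_validation_error")
    }
    if (is.unsorted(bp, strictly = TRUE)) {
      bad <- i[which(diff(bp) <= 0)[1] + 1L]
      abort(sprintf("%s: bp not strictly increasing on chromosome %s (%s).",
                    where, chr, loc_label(bad, line_offset)),
            class = "linkassoc_validation_error")
    }
    if (is.unsorted(cm)) {
      bad <- i[which(diff(cm) < 0)[1] + 1L]
      abort(sprintf("%s: cm decreases on chromosome %s (%s).", where, chr,
                    loc_label(bad, line_offset)),
            class = "linkassoc_validation_error")
    }
  }
  map
}

validate_tracks <- function(tracks, where = "linkage tracks") {
  need <- c("chrom", "pos_cm", "lod")
  if (!is.data.frame(tracks) || !all(need %in% names(tracks))) {
    abort(sprintf("%s need columns %s.", where, paste(need, collapse = ", ")),
          class = "linkassoc_invalid_input")
  }
  tracks <- tibble::as_tibble(tracks)
  if (any(!is.finite(tracks$pos_cm)) || any(!is.finite(tracks$lod))) {
    abort(sprintf("%s: positions and LOD scores must be finite.", where),
          class = "linkassoc_validation_error")
  }
  for (chr in unique(norm_chrom(tracks$chrom))) {
    pos <- tracks$pos_cm[norm_chrom(tracks$chrom) == chr]
    if (is.unsorted(pos, strictly = TRUE)) {
      abort(sprintf("%s: pos_cm not strictly increasing on chromosome %s.", where, chr),
            class = "linkassoc_validation_error")
    }
  }
  tracks
}

validate_genes <- function(genes, where = "gene table") {
  need <- c("gene_id", "chrom", "start_bp", "end_bp")
  if (!is.data.frame(genes) || !all(need %in% names(genes))) {
    abort(sprintf("%s needs columns %s.", where, paste(need, collapse = ", ")),
          class = "linkassoc_invalid_input")
  }
  genes <- tibble::as_tibble(genes)
  bad <- which(!(genes$start_bp < genes$end_bp))
  if (length(bad) > 0L) {
    abort(sprintf("%s: start_bp >= end_bp for gene(s) %s.", where,
                  paste(genes$gene_id[head(bad, 5L)], collapse = ", ")),
          class = "linkassoc_validation_error")
  }
  genes
}

#' Interpolate genetic-map position (cM) at physical positions (bp)
#'
#' Linear interpolation between the flanking map anchors of each query;
#' queries outside the anchored span are clamped to the terminal anchor's cM
#' (no extrapolation, which could go negative). Monotone non-decreasing in
#' `bp`.
#'
#' @param map Genetic map: data frame with columns `chrom`, `bp`, `cm`
#'   (anchors strictly increasing in `bp`, non-decreasing in `cm`, at least
#'   two per chromosome).
#' @param chrom Chromosome id (single value; "3" and "chr3" are equivalent).
#' @param bp Integer vector of physical positions.
#' @return Numeric vector of cM positions.
#' @examples
#' map <- tibble::tibble(chrom = "3", bp = c(1, 1e6), cm = c(0, 1))
#' bp_to_cm(map, "chr3", c(250000, 2e6))
#' @export
bp_to_cm <- function(map, chrom, bp) {
  map <- validate_genetic_map(map)
  sel <- norm_chrom(map$chrom) == norm_chrom(chrom[[1]])
  if (!any(sel)) {
    abort(sprintf("Chromosome %s not present in the genetic map.", chrom[[1]]),
          class = "linkassoc_lookup_error")
  }
  if (length(bp) == 0L) return(numeric(0))
  # rule = 2: clamp to terminal anchors beyond the mapped span
  approx(x = map$bp[sel], y = map$cm[sel], xout = bp, rule = 2, ties = "ordered")$y
}

#' Map gene physical intervals to genetic-map intervals
#'
#' Genes are 0-based half-open (BED); the interval end used for
#' interpolation is `end_bp - 1`, the last base inside the gene, so
#' `cm_start <= cm_end` always holds.
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `start_bp`,
#'   `end_bp`.
#' @inheritParams bp_to_cm
#' @return The gene table with columns `cm_start` and `cm_end` added.
#' @export
gene_interval_cm <- function(genes, map) {
  genes <- validate_genes(genes)
  map <- validate_genetic_map(map)
  if (nrow(genes) == 0L) {
    return(dplyr::mutate(genes, cm_start = numeric(0), cm_end = numeric(0)))
  }
  missing <- setdiff(unique(norm_chrom(genes$chrom)), unique(norm_chrom(map$chrom)))
  if (length(missing) > 0L) {
    off <- genes$gene_id[norm_chrom(genes$chrom) %in% missing]
    abort(sprintf("No genetic-map anchors for chromosome(s) %s (genes: %s).",
                  paste(missing, collapse = ", "),
                  paste(head(off, 5L), collapse = ", ")),
          class = "linkassoc_lookup_error")
  }
  genes |>
    dplyr::group_by(.chr = norm_chrom(.data$chrom)) |>
    dplyr::mutate(
      cm_start = bp_to_cm(map, .data$.chr[1], .data$start_bp),
      cm_end   = bp_to_cm(map, .data$.chr[1], .data$end_bp - 1L)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".chr")
}

#' Assign a gene the mean LOD of its genetic-map interval
#'
#' The gene's LOD is the unweighted mean of the multipoint LOD at all grid
#' positions inside the closed interval `[cm_start, cm_end]`. If no grid
#' position falls inside (a short gene between grid points), the LOD is
#' linearly interpolated at the interval midpoint, clamped to the grid span.
#'
#' @param track A single chromosome's linkage track: data frame with columns
#'   `pos_cm` (strictly increasing) and `lod`.
#' @param cm_start,cm_end Closed genetic interval in cM, `cm_start <= cm_end`.
#' @return The gene-level mean LOD (scalar).
#' @export
assign_gene_lod <- function(track, cm_start, cm_end) {
  if (!is.data.frame(track) || nrow(track) == 0L ||
      !all(c("pos_cm", "lod") %in% names(track))) {
    abort("`track` must be a non-empty data frame with columns pos_cm, lod.",
          class = "linkassoc_invalid_input")
  }
  if (!is.finite(cm_start) || !is.finite(cm_end) || cm_start > cm_end) {
    abort("Need finite cm_start <= cm_end.", class = "linkassoc_invalid_input")
  }
  inside <- track$pos_cm >= cm_start & track$pos_cm <= cm_end
  if (any(inside)) {
    return(mean(track$lod[inside]))
  }
  if (nrow(track) == 1L) return(track$lod[[1]])
  mid <- min(max((cm_start + cm_end) / 2, min(track$pos_cm)), max(track$pos_cm))
  approx(track$pos_cm, track$lod, xout = mid, rule = 2, ties = "ordered")$y
}

#' Gene-level linkage evidence table
#'
#' Vectorised composition of the mapping pipeline: map each gene's physical
#' interval to cM ([gene_interval_cm()]), assign the mean LOD of the mapped
#' region ([assign_gene_lod()]), and convert it to a one-sided linkage
#' p-value and z-score ([lod_to_pvalue()], [pvalue_to_z()]).
#'
#' @inheritParams gene_interval_cm
#' @param tracks Linkage tracks for all needed chromosomes: data frame with
#'   columns `chrom`, `pos_cm`, `lod`.
#' @return The gene table with `cm_start`, `cm_end`, `mean_lod`, `p_linkage`,
#'   `z1` added; row order preserved.
#' @examples
#' map <- tibble::tibble(chrom = "3", bp = c(1, 2e6), cm = c(0, 2))
#' trk <- tibble::tibble(chrom = "3", pos_cm = 0:2, lod = c(0, 1, 2))
#' genes <- tibble::tibble(gene_id = "G1", chrom = "3",
#'                         start_bp = 0L, end_bp = 2000000L)
#' gene_linkage_table(genes, tracks = trk, map = map)
#' @export
gene_linkage_table <- function(genes, tracks, map) {
  genes <- validate_genes(genes)
  tracks <- validate_tracks(tracks)
  if (nrow(genes) == 0L) {
    return(dplyr::mutate(genes, cm_start = numeric(0), cm_end = numeric(0),
                         mean_lod = numeric(0), p_linkage = numeric(0),
                         z1 = numeric(0)))
  }
  missing <- setdiff(unique(norm_chrom(genes$chrom)), unique(norm_chrom(tracks$chrom)))
  if (length(missing) > 0L) {
    off <- genes$gene_id[norm_chrom(genes$chrom) %in% missing]
    abort(sprintf("No linkage track for chromosome(s) %s (genes: %s).",
                  paste(missing, collapse = ", "),
                  paste(head(off, 5L), collapse = ", ")),
          class = "linkassoc_lookup_error")
  }
  genes <- gene_interval_cm(genes, map)
  track_split <- split(tracks, norm_chrom(tracks$chrom))
  genes |>
    dplyr::mutate(
      mean_lod = purrr::pmap_dbl(
        list(norm_chrom(.data$chrom), .data$cm_start, .data$cm_end),
        function(chr, a, b) assign_gene_lod(track_split[[chr]], a, b)
      ),
      p_linkage = lod_to_pvalue(.data$mean_lod),
      z1 = pvalue_to_z(.data$p_linkage)
    )
}
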