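# Join linkage and association evidence, rank genes, evaluate top-K
# detection power and rank improvements.

#' Combine gene-level linkage and association evidence
#'
#' Inner-joins the gene-level linkage table (from [gene_linkage_table()])
#' with gene-based association p-values, inverse-normal transforms the
#' association p to `z2`, combines `z1` and `z2` by the unweighted Liptak
#' method under `phi`, and ranks genes by both the association and the
#' combined p-value (rank 1 = smallest; ties broken by ascending `gene_id`).
#' Genes present in only one input are skipped and reported.
#'
#' @param linkage Gene-level linkage table: data frame with at least
#'   `gene_id`, `mean_lod`, `p_linkage`, `z1` (extra columns are carried
#'   through).
#' @param assoc Data frame with columns `gene_id`, `p_assoc` (p in (0, 1]).
#' @param phi 2x2 correlation matrix; default identity ([phi_matrix()]).
#' @param alpha Significance screen reported by [glance()]; default 0.001.
#' @return A `la_combined` tibble sorted by `rank_combined`, with columns
#'   `gene_id`, `mean_lod`, `p_linkage`, `z1`, `p_assoc`, `z2`, `zc`,
#'   `p_combined`, `rank_assoc`, `rank_combined`. Skipped ids are in
#'   `attr(, "skipped")`; the Phi used is in `attr(, "phi")`.
#' @examples
#' linkage <- tibble::tibble(gene_id = c("MAP4", "FLNB"),
#'                           mean_lod = c(0.82, 0.53))
#' linkage$p_linkage <- lod_to_pvalue(linkage$mean_lod)
#' linkage$z1 <- pvalue_to_z(linkage$p_linkage)
#' assoc <- tibble::tibble(gene_id = c("MAP4", "FLNB"),
#'                         p_assoc = c(0.0137, 0.195))
#' combine_genes(linkage, assoc)
#' @export
combine_genes <- function(linkage, assoc, phi = phi_matrix(), alpha = 0.001) {
  validate_phi(phi)
  need_l <- c("gene_id", "mean_lod", "p_linkage", "z1")
  if (!is.data.frame(linkage) || !all(need_l %in% names(linkage))) {
    abort(sprintf("`linkage` needs columns %s.", paste(need_l, collapse = ", ")),
          class = "linkassoc_invalid_input")
  }
  if (!is.data.frame(assoc) || !all(c("gene_id", "p_assoc") %in% names(assoc))) {
    abort("`assoc` needs columns gene_id, p_assoc.", class = "linkassoc_invalid_input")
  }
  if (any(!is.finite(assoc$p_assoc)) || any(assoc$p_assoc <= 0) || any(assoc$p_assoc > 1)) {
    abort("`p_assoc` values must lie in (0, 1].", class = "linkassoc_validation_error")
  }
  linkage <- tibble::as_tibble(linkage)
  # the association input is authoritative for these columns
  linkage <- linkage[, setdiff(names(linkage), c("p_assoc", "z2", "zc", "p_combined",
                                                 "rank_assoc", "rank_combined"))]
  assoc <- tibble::as_tibble(assoc)[, c("gene_id", "p_assoc")]
  joined <- dplyr::inner_join(linkage, assoc, by = "gene_id")
  if (nrow(joined) == 0L) {
    abort("No genes shared between the linkage and association inputs.",
          class = "linkassoc_no_overlap")
  }
  skipped <- c(setdiff(linkage$gene_id, joined$gene_id),
               setdiff(assoc$gene_id, joined$gene_id))
  if (length(skipped) > 0L) {
    warn(sprintf("%d gene(s) present in only one input were skipped.",
                 length(skipped)))
  }
  comb <- liptak_combine(joined$z1, pvalue_to_z(joined$p_assoc), phi)
  out <- joined |>
    dplyr::mutate(
      z2 = comb$z2, zc = comb$zc, p_combined = comb$p_combined,
      rank_assoc = rank_genes(.data$p_assoc, .data$gene_id),
      rank_combined = rank_genes(.data$p_combined, .data$gene_id)
    ) |>
    dplyr::arrange(.data$rank_combined)
  attr(out, "skipped") <- skipped
  attr(out, "phi") <- phi
  attr(out, "alpha") <- alpha
  class(out) <- c("la_combined", class(out))
  out
}

#' Rank genes by p-value with a deterministic tie-break
#'
#' Rank 1 goes to the smallest p-value; tied p-values receive consecutive
#' ranks in ascending `gene_id` order, so the output is always a permutation
#' of `1..n`.
#'
#' @param p Numeric vector of p-values in (0, 1].
#' @param gene_id Character vector of gene ids (same length as `p`).
#' @return Integer vector of ranks.
#' @export
rank_genes <- function(p, gene_id) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    abort("`p` must be finite with all values in (0, 1].",
          class = "linkassoc_invalid_input")
  }
  if (length(gene_id) != length(p)) {
    abort("`p` and `gene_id` must have equal length.",
          class = "linkassoc_invalid_input")
  }
  ord <- order(p, as.character(gene_id), method = "radix")
  ranks <- integer(length(p))
  ranks[ord] <- seq_along(p)
  ranks
}

#' Top-K detection power across replicates
#'
#' A causal gene is detected in a replicate when its rank is at most `k`
#' (mimicking a validation strategy that follows up the top `k` candidates).
#' Power is the detected fraction across replicates.
#'
#' @param ranks Integer vector: the gene's rank in each replicate.
#' @param k Detection threshold; default 49.
#' @return Proportion of replicates with rank `<= k`.
#' @examples
#' detection_power(c(10, 201, 479, 55, 86, 9, 18, 154, 3, 35))
#' @export
detection_power <- function(ranks, k = 49) {
  if (length(ranks) < 1L || any(!is.finite(ranks))) {
    abort("`ranks` must be a non-empty finite vector.",
          class = "linkassoc_invalid_input")
  }
  mean(ranks <= k)
}

#' Count rank improvements from combining evidence
#'
#' A replicate counts as an improvement when the association-only rank is
#' beyond `k` but the combined rank is within `k` — the combination moved
#' the gene into the followed-up top `k`.
#'
#' @param ranks_assoc,ranks_combined Equal-length integer vectors of
#'   per-replicate ranks under the two methods.
#' @inheritParams detection_power
#' @return Integer count of improvements.
#' @export
count_improvements <- function(ranks_assoc, ranks_combined, k = 49) {
  if (length(ranks_assoc) != length(ranks_combined)) {
    abort("Rank vectors must have equal length.", class = "linkassoc_invalid_input")
  }
  sum(ranks_assoc > k & ranks_combined <= k)
}
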