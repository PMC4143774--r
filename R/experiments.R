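# Packaged simulation experiments: type-I error calibration and top-K
# detection power, plus the power report recomputed from the rank fixture.

#' Empirical type-I error of the combined p-value
#'
#' Draws `n_genes * n_replicates` null statistic pairs (effect shifts forced
#' to zero) with latent correlation `rho`, combines them under either the
#' identity Phi or a Phi estimated from a matched simulated permutation
#' matrix, and reports the pooled fraction of combined p-values below
#' `alpha`.
#'
#' @param config A [sim_config()]; effect shifts are ignored (set to 0).
#' @param phi_mode `"identity"` or `"estimate"` (permutation-estimated).
#' @return A one-row tibble: `rate`, `n_tests`, `alpha`, `phi12`, `phi_mode`.
#' @examples
#' run_type1_experiment(sim_config(n_genes = 2000, n_replicates = 2, seed = 3))
#' @export
run_type1_experiment <- function(config, phi_mode = c("identity", "estimate")) {
  config <- as_config(config)
  phi_mode <- match.arg(phi_mode)
  config$effect_z1 <- 0
  config$effect_z2 <- 0
  config$n_causal <- 0L
  phi <- if (phi_mode == "estimate") {
    estimate_phi(simulate_permutation_matrix(config))
  } else {
    phi_matrix()
  }
  set_run_seed(config$seed)
  hits <- 0L
  n_tests <- 0L
  for (r in seq_len(config$n_replicates)) {
    pairs <- sim_stat_pairs_draw(config)
    p <- liptak_combine(pairs$z1, pairs$z2, phi)$p_combined
    hits <- hits + sum(p < config$alpha)
    n_tests <- n_tests + length(p)
  }
  tibble::tibble(rate = hits / n_tests, n_tests = n_tests,
                 alpha = config$alpha, phi12 = phi[1, 2], phi_mode = phi_mode)
}

#' Top-K detection-power experiment
#'
#' Runs `n_replicates` simulation replicates. In each, every gene gets a
#' `(z1, z2)` pair (causal genes shifted by the configured effects), both
#' are converted to one-sided p-values, genes are ranked by the association
#' p alone and by the combined p, and each causal gene's ranks are recorded.
#' Power is the fraction of replicates in which the causal gene ranks within
#' the top `k`; improvements count replicates moved from beyond `k` into the
#' top `k` by combining.
#'
#' @inheritParams run_type1_experiment
#' @return A `la_power` tibble, one row per causal gene: `gene_id`, `k`,
#'   `n_replicates`, `detected_assoc`, `detected_combined`, `power_assoc`,
#'   `power_combined`, `n_improvements`. Per-replicate ranks are in
#'   `attr(, "ranks")`.
#' @examples
#' cfg <- sim_config(n_genes = 500, effect_z1 = 2, effect_z2 = 2,
#'                   n_replicates = 20, seed = 2)
#' run_power_experiment(cfg)
#' @export
run_power_experiment <- function(config, phi_mode = c("identity", "estimate")) {
  config <- as_config(config)
  phi_mode <- match.arg(phi_mode)
  if (config$n_causal < 1L) {
    abort("The power experiment needs at least one causal gene.",
          class = "linkassoc_invalid_config")
  }
  phi <- if (phi_mode == "estimate") {
    estimate_phi(simulate_permutation_matrix(config))
  } else {
    phi_matrix()
  }
  set_run_seed(config$seed)
  per_rep <- purrr::map_dfr(seq_len(config$n_replicates), function(r) {
    pairs <- sim_stat_pairs_draw(config)
    p_assoc <- pnorm(pairs$z2, lower.tail = FALSE)
    p_comb <- liptak_combine(pairs$z1, pairs$z2, phi)$p_combined
    tibble::tibble(
      replicate = r,
      gene_id = pairs$gene_id[pairs$is_causal],
      rank_assoc = rank_genes(p_assoc, pairs$gene_id)[pairs$is_causal],
      rank_combined = rank_genes(p_comb, pairs$gene_id)[pairs$is_causal]
    )
  })
  report <- per_rep |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      k = config$k,
      n_replicates = config$n_replicates,
      detected_assoc = sum(.data$rank_assoc <= config$k),
      detected_combined = sum(.data$rank_combined <= config$k),
      n_improvements = count_improvements(.data$rank_assoc,
                                          .data$rank_combined, config$k),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      power_assoc = .data$detected_assoc / .data$n_replicates,
      power_combined = .data$detected_combined / .data$n_replicates
    ) |>
    dplyr::relocate("n_improvements", .after = "power_combined")
  attr(report, "ranks") <- per_rep
  attr(report, "config") <- config
  attr(report, "phi_mode") <- phi_mode
  class(report) <- c("la_power", class(report))
  report
}

#' Detection power and improvements from the packaged rank fixture
#'
#' Recomputes, per causal gene and trait, the top-`k` detection power under
#' the association-only and the combined ranking, and the number of rank
#' improvements, from the 10-replicate rank fixture ([table1_fixture()]).
#'
#' @param k Top-K detection threshold; default 49.
#' @return A `la_power` tibble with one row per gene x trait and columns
#'   `gene_id`, `trait`, `k`, `n_replicates`, `detected_assoc`,
#'   `detected_combined`, `power_assoc`, `power_combined`,
#'   `n_improvements`.
#' @examples
#' table1_power_report()
#' @export
table1_power_report <- function(k = 49) {
  wide <- table1_fixture() |>
    tidyr::pivot_wider(names_from = "method", values_from = "rank")
  report <- wide |>
    dplyr::group_by(gene_id = .data$gene, trait = .data$trait) |>
    dplyr::summarise(
      k = k,
      n_replicates = dplyr::n(),
      detected_assoc = sum(.data$assoc <= k),
      detected_combined = sum(.data$combined <= k),
      n_improvements = count_improvements(.data$assoc, .data$combined, k),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      power_assoc = .data$detected_assoc / .data$n_replicates,
      power_combined = .data$detected_combined / .data$n_replicates
    ) |>
    dplyr::relocate("n_improvements", .after = "power_combined")
  attr(report, "ranks") <- wide |>
    dplyr::rename(gene_id = "gene", rank_assoc = "assoc",
                  rank_combined = "combined")
  class(report) <- c("la_power", class(report))
  report
}
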