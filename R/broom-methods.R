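# broom-style accessors for the two result types.

#' Tidy a combined-evidence table
#'
#' Returns the per-gene rows as a plain tibble (drops the `la_combined`
#' class and attributes).
#'
#' @param x A `la_combined` object from [combine_genes()].
#' @param ... Unused.
#' @return A tibble with one row per gene.
#' @method tidy la_combined
#' @export
tidy.la_combined <- function(x, ...) {
  out <- x
  attr(out, "skipped") <- NULL
  attr(out, "phi") <- NULL
  attr(out, "alpha") <- NULL
  class(out) <- setdiff(class(out), "la_combined")
  tibble::as_tibble(out)
}

#' Summarise a combined-evidence table
#'
#' @inheritParams tidy.la_combined
#' @return A one-row tibble: `n_genes`, `phi12` (off-diagonal of the Phi
#'   used), `n_skipped` (ids present in only one input), `alpha` and
#'   `n_significant` (genes with combined p below `alpha`).
#' @method glance la_combined
#' @export
glance.la_combined <- function(x, ...) {
  alpha <- attr(x, "alpha") %||% 0.001
  tibble::tibble(
    n_genes = nrow(x),
    phi12 = (attr(x, "phi") %||% phi_matrix())[1, 2],
    n_skipped = length(attr(x, "skipped")),
    alpha = alpha,
    n_significant = sum(x$p_combined < alpha)
  )
}

#' Tidy a power report
#'
#' Returns the per-replicate causal-gene ranks underlying the report.
#'
#' @param x A `la_power` object from [run_power_experiment()] or
#'   [table1_power_report()].
#' @param ... Unused.
#' @return A tibble of per-replicate ranks (`gene_id`, `replicate`,
#'   `rank_assoc`, `rank_combined`, plus `trait` for the fixture report).
#' @method tidy la_power
#' @export
tidy.la_power <- function(x, ...) {
  tibble::as_tibble(attr(x, "ranks"))
}

#' Summarise a power report
#'
#' @inheritParams tidy.la_power
#' @return The per-gene summary rows as a plain tibble.
#' @method glance la_power
#' @export
glance.la_power <- function(x, ...) {
  out <- x
  attr(out, "ranks") <- NULL
  attr(out, "config") <- NULL
  attr(out, "phi_mode") <- NULL
  class(out) <- setdiff(class(out), "la_power")
  tibble::as_tibble(out)
}
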