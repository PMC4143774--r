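# Tiny in-code fixtures shared across test files.

toy_map <- function(chrom = "3") {
  tibble::tibble(chrom = chrom, bp = c(0, 1e6), cm = c(0, 1))
}

# Map with a flat (zero-recombination) segment between 1 and 2 Mb.
flat_segment_map <- function(chrom = "3") {
  tibble::tibble(chrom = chrom, bp = c(0, 1e6, 2e6, 3e6), cm = c(0, 1, 1, 3))
}

ramp_track <- function(chrom = "3") {
  tibble::tibble(chrom = chrom, pos_cm = 0:3, lod = c(0, 1, 2, 3))
}

toy_genes <- function(chrom = "3") {
  tibble::tibble(
    gene_id = c("G1", "G2"),
    chrom = chrom,
    start_bp = c(250000L, 0L),
    end_bp = c(750001L, 1000001L)
  )
}

# Toy visit table with known structure for phenotype tests.
toy_visits <- function(n_ind = 200, seed = 11, ...) {
  simulate_visit_table(n_ind = n_ind, seed = seed, ...)
}
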