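# Synthetic-data generators and the packaged experiments.

test_that("sim_config validates its fields", {
  cfg <- sim_config()
  expect_s3_class(cfg, "la_config")
  expect_equal(cfg$n_genes, 8047L)
  expect_equal(cfg$k, 49L)
  expect_equal(cfg$alpha, 0.001)
  expect_equal(cfg$n_replicates, 10L)
  expect_error(sim_config(rho = 1), class = "linkassoc_invalid_config")
  expect_error(sim_config(n_genes = 0), class = "linkassoc_invalid_config")
  expect_error(sim_config(alpha = 0), class = "linkassoc_invalid_config")
})

test_that("simulate_stat_pairs hits the requested correlation and effects", {
  big <- sim_config(n_genes = 50000, n_causal = 0, seed = 21)
  pairs0 <- simulate_stat_pairs(big)
  expect_lt(abs(cor(pairs0$z1, pairs0$z2)), 0.015)
  big$rho <- 0.5
  pairs5 <- simulate_stat_pairs(big)
  expect_lt(abs(cor(pairs5$z1, pairs5$z2) - 0.5), 0.015)
  # unit marginals
  expect_lt(abs(sd(pairs5$z1) - 1), 0.02)
  expect_lt(abs(sd(pairs5$z2) - 1), 0.02)
  # zero effects: causal flag does not change the law
  cfg <- sim_config(n_genes = 4000, n_causal = 2000, seed = 4)
  pairs <- simulate_stat_pairs(cfg)
  ks <- suppressWarnings(ks.test(pairs$z1[pairs$is_causal],
                                 pairs$z1[!pairs$is_causal]))
  expect_gt(ks$p.value, 0.001)
  # nonzero effects shift the causal means
  shifted <- simulate_stat_pairs(sim_config(n_genes = 5000, n_causal = 2500,
                                            effect_z1 = 2, effect_z2 = 3,
                                            seed = 4))
  expect_lt(abs(mean(shifted$z1[shifted$is_causal]) - 2), 0.1)
  expect_lt(abs(mean(shifted$z2[shifted$is_causal]) - 3), 0.1)
})

test_that("simulate_permutation_matrix preserves rho under the null", {
  pm0 <- simulate_permutation_matrix(sim_config(n_perms = 10000, seed = 9))
  expect_lt(abs(estimate_phi(pm0)[1, 2]), 0.03)
  pm7 <- simulate_permutation_matrix(sim_config(rho = 0.7, n_perms = 10000,
                                                seed = 9))
  expect_lt(abs(estimate_phi(pm7)[1, 2] - 0.7), 0.03)
  tiny <- simulate_permutation_matrix(sim_config(n_perms = 2, seed = 1))
  expect_equal(nrow(tiny), 2L)
})

test_that("simulate_lod_landscape draws the LOD-scale mixture null", {
  trk <- simulate_lod_landscape(spacing_cm = 1, chrom_length_cm = 200, seed = 14)
  expect_equal(nrow(trk), 201L)
  expect_true(all(trk$lod >= 0))
  # point mass: about half the grid sits at exactly 0
  big <- simulate_lod_landscape(spacing_cm = 0.1, chrom_length_cm = 1000,
                                seed = 15)
  frac0 <- mean(big$lod == 0)
  bounds <- qbinom(c(0.005, 0.995), nrow(big), 0.5) / nrow(big)
  expect_gte(frac0, bounds[1]); expect_lte(frac0, bounds[2])
  # nonzero values follow the scaled chi-square: p-values uniform given > 0
  p_pos <- 2 * lod_to_pvalue(big$lod[big$lod > 0])  # condition on the chi part
  ks <- suppressWarnings(ks.test(p_pos, "punif"))
  expect_lt(unname(ks$statistic), 0.02)
  pk <- simulate_lod_landscape(peak = list(pos = 60, height = 3, width = 5),
                               seed = 16)
  near <- pk$lod[abs(pk$pos_cm - 60) <= 5]
  expect_gte(max(near), 2.5)
  expect_error(simulate_lod_landscape(spacing_cm = 0),
               class = "linkassoc_invalid_config")
})

test_that("generators are reproducible by seed and vary across seeds", {
  cfg <- sim_config(n_genes = 200, seed = 33)
  expect_identical(simulate_stat_pairs(cfg), simulate_stat_pairs(cfg))
  cfg2 <- sim_config(n_genes = 200, seed = 34)
  expect_false(identical(simulate_stat_pairs(cfg)$z1,
                         simulate_stat_pairs(cfg2)$z1))
  expect_identical(simulate_genetic_map(seed = 5), simulate_genetic_map(seed = 5))
  expect_identical(simulate_visit_table(n_ind = 20, seed = 2),
                   simulate_visit_table(n_ind = 20, seed = 2))
})

test_that("simulated maps and genes satisfy the mapping invariants", {
  map <- simulate_genetic_map(seed = 3)
  expect_true(all(diff(map$bp) > 0))
  expect_true(all(diff(map$cm) >= 0))
  genes <- simulate_genes(n_genes = 300, seed = 3)
  expect_true(all(genes$start_bp < genes$end_bp))
  # the composed pipeline runs end to end on generated inputs
  trk <- simulate_lod_landscape(seed = 3)
  out <- gene_linkage_table(genes, trk, map)
  expect_true(all(out$mean_lod >= min(trk$lod) & out$mean_lod <= max(trk$lod)))
})

test_that("type-I error is calibrated at alpha and trivially 1 at alpha = 1", {
  r <- run_type1_experiment(sim_config(n_genes = 20000, n_replicates = 1,
                                       seed = 6, alpha = 0.05))
  bounds <- qbinom(c(0.005, 0.995), r$n_tests, 0.05) / r$n_tests
  expect_gte(r$rate, bounds[1]); expect_lte(r$rate, bounds[2])
  r1 <- run_type1_experiment(sim_config(n_genes = 1000, n_replicates = 1,
                                        seed = 6, alpha = 1))
  expect_equal(r1$rate, 1)
})

test_that("corrected type-I calibration holds across rho values", {
  for (rho in c(0, 0.3, 0.6)) {
    r <- run_type1_experiment(
      sim_config(n_genes = 20000, n_replicates = 1, rho = rho,
                 n_perms = 10000, seed = 41, alpha = 0.05),
      phi_mode = "estimate"
    )
    bounds <- qbinom(c(0.005, 0.995), r$n_tests, 0.05) / r$n_tests
    expect_gte(r$rate, bounds[1])
    expect_lte(r$rate, bounds[2])
  }
})

test_that("power experiment saturates, matches the null rate, and reports shape", {
  # saturated association signal: assoc power 1 regardless of linkage
  sat <- run_power_experiment(sim_config(n_genes = 300, n_causal = 1,
                                         effect_z2 = 10, n_replicates = 10,
                                         seed = 19))
  expect_equal(sat$power_assoc, 1)
  expect_equal(sat$detected_assoc, 10L)
  # no effect: detection is just the chance of a top-K null rank, ~ K/n
  null <- run_power_experiment(sim_config(n_genes = 100, n_causal = 30,
                                          n_replicates = 30, k = 10, seed = 23))
  expect_lt(abs(mean(null$power_assoc) - 0.1), 0.03)
  ranks <- tidy(null)
  expect_equal(nrow(ranks), 30L * 30L)
  expect_true(all(ranks$rank_assoc >= 1 & ranks$rank_assoc <= 100))
  expect_error(run_power_experiment(sim_config(n_causal = 0)),
               class = "linkassoc_invalid_config")
})

test_that("table1_fixture carries the published ranks exactly", {
  fx <- table1_fixture()
  expect_equal(nrow(fx), 80L)
  expect_true(all(fx$rank >= 1 & fx$rank <= 8047))
  expect_equal(
    fx$rank[fx$gene == "MAP4" & fx$trait == "mean_sbp" & fx$method == "combined"],
    c(7L, 12L, 12L, 3L, 5L, 3L, 4L, 6L, 2L, 3L)
  )
  expect_equal(
    fx$rank[fx$gene == "FLNB" & fx$trait == "mean_sbp" & fx$method == "assoc"],
    c(681L, 5660L, 335L, 317L, 905L, 668L, 590L, 2372L, 104L, 5674L)
  )
  q1 <- dplyr::filter(fx, trait == "Q1")
  expect_true(all(table(q1$gene, q1$method) == 10L))
})
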