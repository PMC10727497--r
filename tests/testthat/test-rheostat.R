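test_that("build_genome realizes the parameterized repertoire in mixed clusters", {
  p <- small_params()
  g <- build_genome(p)
  expect_equal(nrow(g), p$n_class_i + sum(p$n_per_zone))
  expect_true(all(g$start < g$end))
  expect_gte(length(unique(g$chrom)), 2)
  mix <- g |>
    dplyr::group_by(cluster_id) |>
    dplyr::summarise(k = dplyr::n_distinct(ifelse(is.na(zone), "I", zone)))
  expect_true(all(mix$k >= 2))
  # zones are consistent with the drawn continuous indices
  ii <- !is.na(g$zonal_index)
  expect_identical(g$zone[ii], bin_zone(g$zonal_index[ii]))

  expect_error(
    build_genome(rheostat_params(n_class_i = 0L, n_per_zone = rep(0L, 5))),
    "zero OR genes"
  )
})

test_that("build_genome is seed-deterministic with a seed-invariant census", {
  p <- small_params(seed = 9)
  expect_identical(build_genome(p), build_genome(p))
  g1 <- build_genome(p, seed = 1)
  g2 <- build_genome(p, seed = 2)
  expect_identical(zone_census(g1), zone_census(g2))
  expect_false(identical(g1$start, g2$start))
})

test_that("dorsal cells transcribe only dorsal identities at zero leak", {
  p <- small_params()
  g <- build_genome(p)
  cell <- simulate_cell(p, g, dv_zone = 1, stage = "INP", seed = 4)
  labs <- ifelse(g$or_class == "I", "I", as.character(g$zone))
  got <- labs[match(names(cell$transcribed), g$gene_id)]
  expect_true(all(got %in% c("I", "1")))

  # a ventral mature neuron respects the latent-state invariants
  cell5 <- simulate_cell(p, g, dv_zone = 5, stage = "mOSN", seed = 4)
  expect_true(all(cell5$silenced %in% names(cell5$transcribed)))
  expect_false(is.na(cell5$chosen))
  expect_true(cell5$chosen %in%
                setdiff(names(cell5$transcribed), cell5$silenced))
  # class I never transcribed outside zone 1
  got5 <- labs[match(names(cell5$transcribed), g$gene_id)]
  expect_false(any(got5 == "I"))
})

test_that("tissues are seed-deterministic and every mature neuron chooses one OR", {
  p <- small_params(seed = 5)
  g <- build_genome(p)
  t1 <- simulate_tissue(p, genome = g, n_cells_per_zone = 10)
  t2 <- simulate_tissue(p, genome = g, n_cells_per_zone = 10)
  expect_identical(t1$cells, t2$cells)
  expect_identical(t1$transcribed, t2$transcribed)
  expect_identical(t1$silenced, t2$silenced)
  expect_equal(nrow(t1$cells), 50)
  expect_false(anyNA(t1$cells$chosen))
  # chosen ORs are unsilenced survivors
  for (j in seq_len(ncol(t1$transcribed))) {
    ch <- match(t1$cells$chosen[j], rownames(t1$transcribed))
    expect_true(t1$transcribed[ch, j])
    expect_false(t1$silenced[ch, j])
  }
  # per-zone choice frequencies sum to 1
  cf <- choice_frequencies(t1)
  sums <- cf |> dplyr::group_by(dv_zone) |> dplyr::summarise(s = sum(freq))
  expect_equal(sums$s, rep(1, 5))
})

test_that("tissue simulation does not depend on which zones are simulated together", {
  p <- small_params(seed = 8)
  g <- build_genome(p)
  whole <- simulate_tissue(p, genome = g, n_cells_per_zone = 8)
  alone <- simulate_tissue(p, genome = g, n_cells_per_zone = 8, zones = 3)
  w3 <- whole$cells |> dplyr::filter(dv_zone == 3)
  expect_identical(w3$chosen, alone$cells$chosen)
})

test_that("choice frequencies track surviving propensity", {
  p <- small_params(seed = 2)
  g <- build_genome(p)
  tis <- simulate_tissue(p, genome = g, n_cells_per_zone = 10000, zones = 2)
  mats <- orzone:::or_propensities(p, g)
  w <- mats$p_t[2, ] * (1 - mats$p_sil[2, ]) * mats$prop[2, ]
  obs <- table(factor(tis$cells$chosen, levels = g$gene_id)) / nrow(tis$cells)
  expect_gt(stats::cor(as.numeric(obs), w), 0.95)
})

test_that("silencing probability is non-decreasing in dorsal offset", {
  p <- small_params()
  g <- build_genome(p)
  mats <- orzone:::or_propensities(p, g)
  # for a fixed zone-1 class II gene, silencing grows with the cell's zone
  g1 <- which(g$or_class == "II" & g$zone == 1)[1]
  expect_true(all(diff(mats$p_sil[, g1]) >= 0))
  # repertoire permission is monotone in the cell zone
  expect_true(all(diff(rowSums(mats$p_t > 0)) >= 0))
})

test_that("NFI knockout clamps class II regulation to an effective zone of 2", {
  p <- small_params(seed = 6)
  g <- build_genome(p)
  ko <- apply_nfi_knockout(p)
  mats <- orzone:::or_propensities(ko, g)
  wt <- orzone:::or_propensities(p, g)
  # ventral KO cells transcribe no zone 3-5 ORs at zero leak
  ventral_or <- which(g$or_class == "II" & g$zone >= 3)
  expect_true(all(mats$p_t[5, ventral_or] == 0))
  # zone-1 cells are untouched; zones >= 2 behave exactly like zone 2
  expect_identical(mats$p_t[1, ], wt$p_t[1, ])
  expect_identical(mats$p_sil[1, ], wt$p_sil[1, ])
  for (z in 3:5) {
    expect_identical(mats$p_t[z, ], mats$p_t[2, ])
    expect_identical(mats$p_sil[z, ], mats$p_sil[2, ])
  }
})

test_that("strong induction dominates choice in every zone", {
  p <- small_params(seed = 3)
  g <- build_genome(p)
  ind <- g$gene_id[which(g$or_class == "II" & g$zone == 2)][1]
  tis <- simulate_tissue(induce_or(p, ind, 1e9), genome = g,
                         n_cells_per_zone = 200)
  f <- tis$cells |>
    dplyr::group_by(dv_zone) |>
    dplyr::summarise(f = mean(chosen == ind))
  expect_true(all(f$f > 0.9))
  expect_error(
    simulate_tissue(induce_or(p, "NotAGene", 10), genome = g,
                    n_cells_per_zone = 2),
    "NotAGene"
  )
})

test_that("parameter validation and YAML round trip", {
  expect_error(rheostat_params(promoter_strength = c(1, 2, 1, 1, 1)),
               "non-increasing")
  expect_error(rheostat_params(sil_own = 1.2), "\\[0, 1\\]")
  expect_error(rheostat_params(n_chromosomes = 1), "at least 2")
  p <- small_params(seed = 77)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_params_yaml(p, f)
  expect_equal(read_params_yaml(f), p)
})
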