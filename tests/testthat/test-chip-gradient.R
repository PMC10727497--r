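test_that("gene-body density normalizes depth and length", {
  # raw depth 0.1 over a 2 kb gene in a 20M-read library: the 1e7/2e7 factor
  # halves it, total 100 over 2000 bp = 0.05 per bp
  track <- coverage_track(
    tibble::tibble(chrom = "chr1", start = 0L, end = 4000L, depth = 0.1),
    library_size = 2e7
  )
  expect_error(gene_body_density(track, NULL), "normalized")
  track <- normalize_track(track)
  gene <- tibble::tibble(gene_id = "g", chrom = "chr1",
                         start = 0L, end = 2000L)
  expect_equal(gene_body_density(track, gene)$density, 0.05)

  # zero coverage
  zero <- normalize_track(coverage_track(
    tibble::tibble(chrom = "chr1", start = 0L, end = 4000L, depth = 0),
    library_size = 1e7
  ))
  expect_equal(gene_body_density(zero, gene)$density, 0)

  # gene beyond the track extent errors with its name
  far <- tibble::tibble(gene_id = "gX", chrom = "chr1",
                        start = 5000L, end = 6000L)
  expect_error(gene_body_density(track, far), "gX")
})

test_that("density on a stepwise track matches per-base summation", {
  set.seed(14)
  runs <- tibble::tibble(
    chrom = "chr1",
    start = seq(0L, 900L, by = 100L),
    end = seq(100L, 1000L, by = 100L),
    depth = round(runif(10, 0, 5), 2)
  )
  track <- coverage_track(runs, 1e7, normalized = TRUE)
  genes <- tibble::tibble(
    gene_id = c("a", "b", "c"), chrom = "chr1",
    start = c(35L, 150L, 420L), end = c(275L, 900L, 421L)
  )
  got <- gene_body_density(track, genes)$density
  oracle <- vapply(seq_len(3), function(i) {
    brute_interval_mean(track, "chr1", genes$start[i], genes$end[i], step = 1)
  }, numeric(1))
  expect_equal(got, oracle, tolerance = 1e-9)

  # additivity: splitting a run into chunks leaves densities unchanged
  split_runs <- dplyr::bind_rows(
    runs |> dplyr::mutate(end = start + 50L),
    runs |> dplyr::mutate(start = start + 50L)
  )
  track2 <- coverage_track(split_runs, 1e7, normalized = TRUE)
  expect_equal(gene_body_density(track2, genes)$density, got,
               tolerance = 1e-9)
})

test_that("metagene rows are flat for uniform coverage and flank signal stays in flanks", {
  gene <- tibble::tibble(gene_id = "g", chrom = "chr1",
                         start = 10000L, end = 16000L, strand = "+")
  uni <- coverage_track(
    tibble::tibble(chrom = "chr1", start = 0L, end = 30000L, depth = 2),
    1e7, normalized = TRUE
  )
  m <- scaled_metagene_matrix(uni, gene, n_bins = 50)
  expect_equal(as.numeric(m), rep(2, 50), tolerance = 1e-9)

  flank_only <- coverage_track(
    tibble::tibble(chrom = "chr1", start = 8000L, end = 10000L, depth = 3),
    1e7, normalized = TRUE
  )
  m2 <- scaled_metagene_matrix(flank_only, gene, n_bins = 50)
  breaks <- attr(m2, "bin_breaks")
  in_flank <- utils::head(breaks, -1) < 0
  expect_true(all(m2[1, in_flank] > 0))
  expect_true(all(m2[1, !in_flank] == 0))

  # minus-strand genes are reversed: signal at the 3' genomic end appears 5'
  gene_m <- gene |> dplyr::mutate(strand = "-")
  m3 <- scaled_metagene_matrix(flank_only, gene_m, n_bins = 50)
  in_right_flank <- utils::head(breaks, -1) >= 6000
  expect_true(all(m3[1, in_right_flank] > 0))
  expect_true(all(m3[1, !in_right_flank] == 0))
})

test_that("metagene resampling matches a fine-grid oracle", {
  set.seed(3)
  runs <- tibble::tibble(
    chrom = "chr1",
    start = seq(0L, 19800L, by = 200L),
    end = seq(200L, 20000L, by = 200L),
    depth = round(runif(100, 0, 4), 2)
  )
  track <- coverage_track(runs, 1e7, normalized = TRUE)
  gene <- tibble::tibble(gene_id = "g", chrom = "chr1",
                         start = 5000L, end = 8000L, strand = "+")
  m <- scaled_metagene_matrix(track, gene, body_len = 6000, flank = 2000,
                              n_bins = 100)
  breaks <- attr(m, "bin_breaks")
  to_genomic <- function(u) {
    g <- ifelse(u < 0, u, ifelse(u <= 6000, u * 3000 / 6000, 3000 + u - 6000))
    5000 + g
  }
  oracle <- vapply(seq_len(100), function(j) {
    brute_interval_mean(track, "chr1", to_genomic(breaks[j]),
                        to_genomic(breaks[j + 1]))
  }, numeric(1))
  expect_equal(as.numeric(m), oracle, tolerance = 0.02)

  # row means over body columns equal the gene-body density for uniform tracks
  uni <- coverage_track(
    tibble::tibble(chrom = "chr1", start = 0L, end = 30000L, depth = 1.7),
    1e7, normalized = TRUE
  )
  mu <- scaled_metagene_matrix(uni, gene, n_bins = 100)
  body_cols <- utils::head(breaks, -1) >= 0 & utils::head(breaks, -1) < 6000
  expect_equal(mean(mu[1, body_cols]),
               gene_body_density(uni, gene)$density, tolerance = 1e-6)
})

test_that("zonal gradient statistic detects perfect ordering and flat tables", {
  perfect <- tibble::tibble(
    zone = rep(1:5, each = 10), or_class = "II",
    density = rep(c(5, 4, 3, 2, 1), each = 10)
  )
  tr <- zonal_gradient_stat(perfect, n_perm = 500)
  expect_equal(tr$trend, -1)
  expect_lt(tr$p_value, 0.01)

  flat <- perfect |> dplyr::mutate(density = 1)
  tr2 <- zonal_gradient_stat(flat, n_perm = 500)
  expect_equal(tr2$trend, 0)
  expect_gt(tr2$p_value, 0.99)

  expect_error(
    zonal_gradient_stat(tibble::tibble(zone = 1, or_class = "II", density = 1)),
    "at least 2 zones"
  )

  # permutation p is exchangeable-valid on a null table
  set.seed(1)
  null_tab <- tibble::tibble(
    zone = rep(1:5, each = 30), or_class = "II", density = rnorm(150)
  )
  ps <- vapply(1:20, function(i) {
    shuffled <- null_tab |> dplyr::mutate(density = sample(density))
    zonal_gradient_stat(shuffled, n_perm = 400, seed = i)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.25) # uniform p-values average 0.5
  expect_gt(min(ps), 0.0024)
})

test_that("tidy and glance summarize the trend object", {
  perfect <- tibble::tibble(
    zone = rep(1:3, each = 4), or_class = "II",
    density = rep(c(3, 2, 1), each = 4)
  )
  tr <- zonal_gradient_stat(perfect, n_perm = 200)
  expect_equal(nrow(tidy(tr)), 3)
  expect_equal(glance(tr)$trend, -1)
})
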