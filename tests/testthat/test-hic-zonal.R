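toy_matrix <- function() {
  # two chromosomes, 3 + 3 bins at 50 kb
  bins <- tibble::tibble(
    chrom = rep(c("chrA", "chrB"), each = 3),
    start = rep(c(0L, 50000L, 100000L), 2)
  )
  pixels <- tibble::tibble(
    bin1 = c(1L, 1L, 2L, 1L, 4L, 3L),
    bin2 = c(1L, 2L, 3L, 4L, 5L, 6L),
    count = c(10, 5, 2, 8, 4, 6)
  )
  contact_matrix(bins, pixels, 50000L)
}

test_that("counts-per-billion normalization scales and conserves the total", {
  cm <- contact_matrix(
    tibble::tibble(chrom = "chrA", start = c(0L, 50000L)),
    tibble::tibble(bin1 = c(1L, 1L), bin2 = c(1L, 2L),
                   count = c(500000, 250000)),
    50000L
  )
  # symmetric total: 500000 + 2 * 250000 = 1e6
  expect_equal(cm$total_raw, 1e6)
  cmn <- normalize_cpb(cm)
  expect_equal(cmn$pixels$count[1], 5e8) # 500000 * 1e9 / 1e6
  sym_sum <- sum(cmn$pixels$count *
                   ifelse(cmn$pixels$bin1 == cmn$pixels$bin2, 1, 2))
  expect_equal(sym_sum, 1e9)
  expect_error(normalize_cpb(cmn), "already normalized")
  empty <- contact_matrix(
    tibble::tibble(chrom = "chrA", start = 0L),
    tibble::tibble(bin1 = integer(), bin2 = integer(), count = numeric()),
    50000L
  )
  expect_error(normalize_cpb(empty), "zero total")
})

test_that("cis block extraction matches exhaustive pixel lookup", {
  bins <- tibble::tibble(chrom = "chrA", start = as.integer(0:5 * 50000))
  set.seed(2)
  px <- tidyr::expand_grid(bin1 = 1:6, bin2 = 1:6) |>
    dplyr::filter(bin1 <= bin2) |>
    dplyr::mutate(count = rpois(dplyr::n(), 40))
  cm <- normalize_cpb(contact_matrix(bins, px, 50000L))
  block <- extract_cis_block(
    cm,
    region_a = list(chrom = "chrA", start = 0, end = 100000),
    region_b = list(chrom = "chrA", start = 150000, end = 300000),
    resolution = 50000, cap = 150
  )
  # oracle: direct lookups of the normalized pixels
  get <- function(i, j) {
    v <- cm$pixels$count[cm$pixels$bin1 == min(i, j) &
                           cm$pixels$bin2 == max(i, j)]
    if (length(v) == 0) 0 else v
  }
  oracle <- outer(1:2, 4:6, Vectorize(get))
  expect_equal(unname(block$block), oracle)
  # display copy capped, raw block untouched
  expect_true(all(block$display <= 150))
  expect_equal(mean(block$block), mean(oracle))

  # aggregation to coarser bins sums the finer ones
  block2 <- extract_cis_block(
    cm,
    region_a = list(chrom = "chrA", start = 0, end = 100000),
    region_b = list(chrom = "chrA", start = 200000, end = 300000),
    resolution = 100000
  )
  expect_equal(
    unname(block2$block[1, 1]),
    get(1, 5) + get(2, 5) + get(1, 6) + get(2, 6)
  )

  expect_error(
    extract_cis_block(
      cm,
      region_a = list(chrom = "chrA", start = 0, end = 200000),
      region_b = list(chrom = "chrA", start = 150000, end = 300000)
    ),
    "overlap"
  )

  # empty region pair yields a zero block
  empty_px <- contact_matrix(
    bins, tibble::tibble(bin1 = 1L, bin2 = 1L, count = 1e6), 50000L
  ) |> normalize_cpb()
  zb <- extract_cis_block(
    empty_px,
    region_a = list(chrom = "chrA", start = 50000, end = 100000),
    region_b = list(chrom = "chrA", start = 150000, end = 200000)
  )
  expect_true(all(zb$block == 0))
})

test_that("zone-pair map reproduces a hand computation on a toy genome", {
  genes <- tibble::tibble(
    gene_id = paste0("g", 1:4),
    chrom = rep(c("chrA", "chrB"), each = 2),
    start = rep(c(10000L, 60000L), 2),
    end = rep(c(20000L, 70000L), 2),
    strand = "+",
    or_class = "II",
    zone = c(1L, 1L, 5L, 5L)
  )
  bins <- annotate_bins(genes, 50000L)
  cm_bins <- tibble::tibble(
    chrom = rep(c("chrA", "chrB"), each = 2),
    start = rep(c(0L, 50000L), 2)
  )
  # trans pixels: (1,3)=8, (1,4)=2, (2,3)=4; (2,4) absent = 0
  px <- tibble::tibble(
    bin1 = c(1L, 1L, 2L, 1L),
    bin2 = c(3L, 4L, 3L, 2L),
    count = c(8, 2, 4, 99) # cis pixel must not leak into the trans map
  )
  cm <- contact_matrix(cm_bins, px, 50000L)
  cm$normalization <- "counts_per_billion" # hand-set values, no rescaling
  zm <- zone_pair_trans_map(cm, bins)
  expect_equal(zm$map["1", "5"], (8 + 2 + 4 + 0) / 4)
  expect_equal(zm$map["5", "1"], zm$map["1", "5"])
  expect_true(is.na(zm$map["1", "1"])) # both zone-1 bins on one chromosome
  expect_equal(zm$n_pairs["1", "5"], 4)

  # class I bins appear only when requested
  genes_i <- genes
  genes_i$or_class[1] <- "I"
  genes_i$zone[1] <- NA
  bins_i <- annotate_bins(genes_i, 50000L)
  zmi <- zone_pair_trans_map(cm, bins_i, exclude_class_i = FALSE)
  expect_equal(rownames(zmi$map), c("I", as.character(1:5)))
  expect_equal(zmi$map["I", "5"], (8 + 2) / 2)

  # identical pixel values everywhere give a constant map
  px_const <- tidyr::expand_grid(bin1 = 1:4, bin2 = 1:4) |>
    dplyr::filter(bin1 <= bin2) |>
    dplyr::mutate(count = 7)
  cmc <- contact_matrix(cm_bins, px_const, 50000L)
  cmc$normalization <- "counts_per_billion"
  zmc <- zone_pair_trans_map(cmc, bins)
  vals <- zmc$map[!is.na(zmc$map)]
  expect_true(all(vals == 7))
})

test_that("zone-pair map equals the brute-force bin-pair scan", {
  p <- small_params(seed = 13)
  g <- build_genome(p)
  tis <- simulate_tissue(p, genome = g, n_cells_per_zone = 4)
  cm <- normalize_cpb(emit_hic_contacts(tis, 4, n_trans_noise = 300L))
  bins <- annotate_bins(g, 50000)
  expect_lte(nrow(bins), 200)
  zm <- zone_pair_trans_map(cm, bins)
  oracle <- brute_zone_pair_map(cm, bins)
  expect_equal(unclass(zm$map), oracle, tolerance = 1e-9)
  expect_identical(zm$map, t(zm$map))
})

test_that("contact matrices round-trip through bins + pixels TSV", {
  cm <- toy_matrix()
  b <- withr::local_tempfile(fileext = ".tsv")
  x <- withr::local_tempfile(fileext = ".tsv")
  write_contacts(cm, b, x)
  back <- read_contacts(b, x, resolution = 50000L)
  expect_equal(back$bins, cm$bins)
  expect_equal(back$pixels, cm$pixels)
  expect_equal(back$total_raw, cm$total_raw)
})
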