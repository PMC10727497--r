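toy_spots <- function(counts, zone_label, band = NULL) {
  genes <- tibble::tibble(
    gene_id = rownames(counts),
    is_or = TRUE,
    zone_label = zone_label
  )
  spots <- tibble::tibble(
    barcode = colnames(counts),
    x = seq_len(ncol(counts)), y = 1L
  )
  if (!is.null(band)) spots$band_zone <- band
  spot_matrix(counts, spots, genes)
}

test_that("spot filtering keeps spots with enough OR genes and UMIs", {
  counts <- cbind(
    keep = c(2, 1, 0),      # 2 OR genes, 3 UMIs: kept
    one_gene = c(10, 0, 0), # 1 OR gene: removed
    empty = c(0, 0, 0)      # no OR transcripts: removed
  )
  rownames(counts) <- c("OrA", "OrB", "OrC")
  m <- toy_spots(counts, zone_label = c("1", "2", "5"))
  kept <- filter_spots(m)
  expect_equal(kept$spots$barcode, "keep")

  # monotone in both thresholds
  for (mg in 1:3) {
    for (mu in 1:4) {
      sub <- filter_spots(m, min_or_genes = mg, min_or_umis = mu)
      sup <- filter_spots(m, min_or_genes = mg - 1, min_or_umis = mu - 1)
      expect_true(all(sub$spots$barcode %in% sup$spots$barcode))
    }
  }

  # a zero-OR spot is assigned "none" on the unfiltered matrix
  assign <- assign_spot_zone(m)
  expect_equal(assign$zone[assign$barcode == "empty"], "none")
})

test_that("spot assignment follows the argmax of summed normalized counts", {
  counts <- cbind(s1 = c(3, 5), s2 = c(4, 4), s3 = c(0, 0))
  rownames(counts) <- c("Or1", "Or2")
  m <- toy_spots(counts, zone_label = c("1", "2"))
  # hand-set normalized layer so the sums are transparent
  m$normalized <- Matrix::Matrix(counts, sparse = TRUE)
  dimnames(m$normalized) <- dimnames(m$counts)
  a <- assign_spot_zone(m)
  expect_equal(a$zone[a$barcode == "s1"], "2") # 5 > 3
  expect_equal(a$zone[a$barcode == "s2"], "1") # tie goes dorsal
  expect_equal(a$zone[a$barcode == "s3"], "none")

  # scale invariance: rescaling one spot's normalized vector keeps its label
  m2 <- m
  m2$normalized[, "s1"] <- m2$normalized[, "s1"] * 37
  expect_equal(assign_spot_zone(m2)$zone, a$zone)

  # class I wins merge into zone 1 unless merging is disabled
  counts_i <- cbind(s = c(9, 1))
  rownames(counts_i) <- c("OrI", "Or2")
  mi <- toy_spots(counts_i, zone_label = c("I", "2"))
  mi$normalized <- Matrix::Matrix(counts_i, sparse = TRUE)
  dimnames(mi$normalized) <- dimnames(mi$counts)
  ai <- assign_spot_zone(mi)
  expect_equal(ai$zone, "1")
  expect_equal(ai$zone_raw, "I")
  expect_equal(assign_spot_zone(mi, merge_class_i = FALSE)$zone, "I")
})

test_that("signature scores average normalized expression with absent genes as zero", {
  counts <- cbind(s1 = c(2, 4, 6), s2 = c(0, 0, 0), s3 = c(1, 0, 3))
  rownames(counts) <- c("OrA", "OrB", "OrC")
  m <- toy_spots(counts, zone_label = c("1", "1", "2"))
  m$normalized <- Matrix::Matrix(counts, sparse = TRUE)
  dimnames(m$normalized) <- dimnames(m$counts)
  sigs <- list("1" = c("OrA", "OrB"), "2" = "OrC")
  sc <- zone_signature_score(m, sigs)
  expect_equal(sc$score[sc$barcode == "s1" & sc$zone == "1"], 3) # (2+4)/2
  expect_equal(sc$score[sc$barcode == "s1" & sc$zone == "2"], 6) # one-gene
  expect_equal(sc$score[sc$barcode == "s2" & sc$zone == "1"], 0)
  expect_warning(
    sc2 <- zone_signature_score(m, list("9" = c("OrA", "Missing"))),
    "absent"
  )
  expect_equal(sc2$score[sc2$barcode == "s1"], 1) # (2 + 0)/2

  # top-n signatures pick the highest expressed genes per zone
  sigs_auto <- make_zone_signatures(m, n = 1)
  expect_equal(sigs_auto[["1"]], "OrB")
  expect_equal(sigs_auto[["2"]], "OrC")
})

test_that("clustering separates well-separated blobs and is deterministic", {
  set.seed(4)
  blob <- function(center, n) {
    matrix(rpois(20 * n, lambda = rep(center, n)), nrow = 20)
  }
  counts <- cbind(blob(c(rep(60, 10), rep(1, 10)), 30),
                  blob(c(rep(1, 10), rep(60, 10)), 30))
  rownames(counts) <- sprintf("Or%02d", 1:20)
  colnames(counts) <- sprintf("s%02d", 1:60)
  m <- toy_spots(counts, zone_label = rep(c("1", "5"), each = 10))
  cl <- cluster_spots(m, n_pcs = 3, k = 2, seed = 11)
  truth <- rep(1:2, each = 30)
  agreement <- max(
    mean(cl$cluster == truth),
    mean(cl$cluster == 3 - truth)
  )
  expect_equal(agreement, 1)
  expect_identical(cl, cluster_spots(m, n_pcs = 3, k = 2, seed = 11))

  # duplicated expression profiles get identical labels
  dup <- which(cl$cluster == cl$cluster[1])[1:2]
  expect_equal(cl$cluster[dup[1]], cl$cluster[dup[2]])

  expect_error(cluster_spots(m, k = 100), "fewer spots")
})

test_that("assignment accuracy degrades with ambient noise", {
  p <- small_params(seed = 19)
  g <- build_genome(p)
  tis <- simulate_tissue(p, genome = g, n_cells_per_zone = 60)
  curve <- assignment_sensitivity(
    tis, ambient_levels = c(0.001, 5, 50), grid_shape = c(10L, 4L)
  )
  expect_gt(curve$accuracy[1], curve$accuracy[3])
  expect_true(all(diff(curve$accuracy) <= 0))
})

test_that("dorsalization index summarizes control-to-perturbed shifts", {
  mk_assign <- function(zones) {
    tibble::tibble(
      barcode = sprintf("b%02d", seq_along(zones)),
      x = seq_along(zones), y = 1, zone = zones, zone_raw = zones
    )
  }
  ctrl <- mk_assign(c("1", "2", "3", "4", "5", "none"))
  pert <- mk_assign(c("1", "2", "2", "2", "2", "none"))
  di <- dorsalization_index(ctrl, pert)
  expect_equal(di$index, 1)
  shift <- tidyr::pivot_longer(di$shift, -control)
  expect_equal(sum(shift$value), 6)

  same <- dorsalization_index(ctrl, ctrl)
  long <- tidyr::pivot_longer(same$shift, -control)
  expect_true(all(long$value[long$control != long$name] == 0))
})
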