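toy_structure <- function(df, cell_id = "toy") {
  structure_3d(df, cell_id = cell_id)
}

test_that("pairwise distances are Euclidean, symmetric, haplotype-resolved", {
  st <- toy_structure(tibble::tibble(
    chrom_hap = c("chr1(mat)", "chr1(mat)", "chr2(mat)"),
    pos = c(0L, 20000L, 0L),
    x = c(0, 3, 0), y = c(0, 4, 0), z = c(0, 0, 1)
  ))
  loci <- tibble::tibble(gene_id = c("a", "b"), chrom = c("chr1", "chr2"),
                         pos = c(20000, 0))
  d <- pairwise_distances(st, loci)
  expect_equal(d["a|chr1(mat)", "b|chr2(mat)"],
               sqrt(3^2 + 4^2 + 1^2))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))

  # a locus present on two haplotypes yields two suffixed rows
  st2 <- toy_structure(tibble::tibble(
    chrom_hap = c("chr1(mat)", "chr1(pat)"),
    pos = 0L, x = c(0, 3), y = c(0, 4), z = 0
  ))
  d2 <- pairwise_distances(st2, loci[1, ])
  expect_equal(rownames(d2), c("a|chr1(mat)", "a|chr1(pat)"))
  expect_equal(d2[1, 2], 5)

  expect_error(
    pairwise_distances(st2, tibble::tibble(gene_id = "zz", chrom = "chrX",
                                           pos = 1)),
    "zz"
  )
})

test_that("pairwise distances match a brute-force double loop", {
  set.seed(8)
  st <- toy_structure(tibble::tibble(
    chrom_hap = rep(c("c1(mat)", "c2(mat)"), each = 10),
    pos = rep(as.integer(0:9 * 20000), 2),
    x = rnorm(20), y = rnorm(20), z = rnorm(20)
  ))
  loci <- tibble::tibble(
    gene_id = sprintf("g%02d", 1:10),
    chrom = rep(c("c1", "c2"), 5),
    pos = as.integer(c(0:4, 0:4) * 20000 + 500)
  )
  d <- pairwise_distances(st, loci)
  res <- orzone:::resolve_loci(st, loci)
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      expect_equal(
        d[res$bead_id[i], res$bead_id[j]],
        sqrt(sum((unlist(res[i, c("x", "y", "z")]) -
                    unlist(res[j, c("x", "y", "z")]))^2)),
        tolerance = 1e-12
      )
    }
  }
})

test_that("aggregates are proximity components of at least two loci", {
  # chain of 3 OR beads at spacing 9 on three chromosomes: one aggregate
  st <- toy_structure(tibble::tibble(
    chrom_hap = c("c1(mat)", "c2(mat)", "c3(mat)"),
    pos = 0L, x = c(0, 9, 18), y = 0, z = 0
  ))
  loci <- tibble::tibble(gene_id = c("a", "b", "c"),
                         chrom = c("c1", "c2", "c3"), pos = 0)
  ag <- or_aggregates(st, loci, radius = 10)
  expect_equal(length(ag$components), 1)
  expect_equal(ag$sizes, 3L)
  expect_equal(ag$n_chromosomes, 3L)

  # all pairwise distances above the radius: no aggregates
  far <- toy_structure(tibble::tibble(
    chrom_hap = c("c1(mat)", "c2(mat)", "c3(mat)"),
    pos = 0L, x = c(0, 50, 100), y = 0, z = 0
  ))
  expect_equal(length(or_aggregates(far, loci, radius = 10)$components), 0)
})

test_that("aggregate calling equals brute-force connected components", {
  set.seed(31)
  n <- 60
  beads <- tibble::tibble(
    chrom_hap = paste0("c", sample(1:4, n, replace = TRUE), "(mat)"),
    x = runif(n, 0, 40), y = runif(n, 0, 40), z = runif(n, 0, 40)
  ) |>
    dplyr::group_by(chrom_hap) |>
    dplyr::mutate(pos = as.integer((dplyr::row_number() - 1) * 20000)) |>
    dplyr::ungroup()
  st <- toy_structure(beads)
  loci <- beads |>
    dplyr::mutate(
      gene_id = sprintf("g%02d", dplyr::row_number()),
      chrom = sub("\\(mat\\)", "", chrom_hap)
    ) |>
    dplyr::select(gene_id, chrom, pos)
  for (radius in c(6, 12)) {
    ag <- or_aggregates(st, loci, radius = radius, include_cis = TRUE)
    res <- orzone:::resolve_loci(st, loci)
    comps <- brute_components(
      as.matrix(res[, c("x", "y", "z")]), res$bead_id, res$chrom_hap,
      radius, include_cis = TRUE
    )
    oracle <- sort(unname(vapply(
      Filter(function(s) length(s) >= 2, comps),
      function(s) paste(sort(s), collapse = "+"), character(1)
    )))
    got <- sort(vapply(ag$components, function(s) {
      paste(sort(s), collapse = "+")
    }, character(1)))
    expect_equal(got, oracle)
  }
})

test_that("aggregate membership is invariant to rigid motion", {
  p <- small_params(seed = 17)
  g <- build_genome(p)
  tis <- simulate_tissue(p, genome = g, n_cells_per_zone = 1, zones = 5)
  st <- emit_structure(tis, seed = 7)
  ag <- or_aggregates(st, g)
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), 0,
                  -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(st$beads[, c("x", "y", "z")]) %*% rot
  st2 <- st
  st2$beads$x <- xyz[, 1] + 5
  st2$beads$y <- xyz[, 2] - 3
  st2$beads$z <- xyz[, 3] + 100
  ag2 <- or_aggregates(st2, g)
  expect_equal(lapply(ag$components, sort), lapply(ag2$components, sort))
})

test_that("contact density counts OR-proximal contacts per eligible pair", {
  loci <- tibble::tibble(gene_id = c("a", "b"), chrom = c("c1", "c2"),
                         pos = c(100000, 200000))
  contacts <- tibble::tibble(
    chrom_a = c("c1(mat)", "c1(mat)", "c1(mat)", "c3(mat)", "c1(pat)"),
    pos_a = c(100000, 105000, 500000, 100000, 99000),
    chrom_b = c("c2(mat)", "c2(pat)", "c2(mat)", "c2(mat)", "c2(pat)"),
    pos_b = c(200000, 201000, 200000, 200000, 210000)
  )
  # eligible pairs: 4 haplotype loci -> choose(4,2) = 6; qualifying contacts
  # (both ends within 20 kb of a locus): rows 1, 2, 5
  expect_equal(contact_density(contacts, loci, neighborhood = 20000), 3 / 6)
  # doubling the contacts doubles the density
  expect_equal(
    contact_density(dplyr::bind_rows(contacts, contacts), loci, 20000),
    6 / 6
  )
  # no OR-OR contacts
  none <- contacts |> dplyr::mutate(pos_a = pos_a + 5e6, pos_b = pos_b + 5e6)
  expect_equal(contact_density(none, loci, 20000), 0)
  expect_warning(
    contact_density(contacts[0, ], loci, 20000), "empty"
  )
})

test_that("contact-count quality filter drops shallow cells", {
  lists <- list(
    deep = tibble::tibble(chrom_a = rep("c1(mat)", 25000), pos_a = 1,
                          chrom_b = "c1(mat)", pos_b = 2),
    shallow = tibble::tibble(chrom_a = "c1(mat)", pos_a = 1,
                             chrom_b = "c1(mat)", pos_b = 2)
  )
  expect_message(kept <- filter_cells_by_contacts(lists), "removed 1")
  expect_equal(names(kept), "deep")
})

test_that("rank-sum test matches exact enumeration and the reference", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$U, 0)
  expect_equal(rs$p_value, 0.1)
  expect_match(rs$method, "exact")

  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2))$p_value, 1)

  # exact branch agrees with the reference implementation without ties
  set.seed(5)
  for (i in 1:5) {
    a <- rnorm(6)
    b <- rnorm(8, mean = 0.5)
    ours <- rank_sum_test(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$U, unname(ref$statistic))
  }

  # large separated groups: normal approximation matches the reference
  a <- rnorm(40)
  b <- rnorm(45, mean = 2)
  ours <- rank_sum_test(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
  expect_lt(ours$p_value, 1e-6)

  # tie-corrected approximation against the reference
  a <- rep(1:5, 4)
  b <- rep(2:6, 4)
  expect_equal(
    rank_sum_test(a, b)$p_value,
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
    tolerance = 1e-10
  )
})

test_that("zone composition of aggregates separates ventral from dorsal loci", {
  p <- small_params(seed = 23)
  g <- build_genome(p)
  tis <- simulate_tissue(p, genome = g, n_cells_per_zone = 4, zones = 5)
  fr <- purrr::map_dfr(1:4, function(i) {
    st <- emit_structure(tis, tis$cells$cell_id[i], seed = 50 + i)
    or_aggregates(st, g)$zone_fraction
  })
  agg <- fr |>
    dplyr::group_by(zone_label) |>
    dplyr::summarise(f = mean(fraction_in_aggregate))
  dorsal <- mean(agg$f[agg$zone_label %in% c("1", "2")])
  ventral5 <- agg$f[agg$zone_label == "5"]
  expect_lt(ventral5, dorsal)
})
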