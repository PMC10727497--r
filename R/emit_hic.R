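#' Emit a synthetic binned Hi-C contact matrix for one zone's neurons
#'
#' Raw counts are Poisson draws around three components: (i) for every pair
#' of OR-carrying bins (cis long-range and trans), the expected count is
#' `hic_gain` times the mean joint silencing probability of the residing OR
#' genes in cells of the tissue's zone, plus a uniform `hic_floor`
#' (compartment contacts form between heterochromatic ORs, so class I bins
#' stay near background); (ii) a cis distance-decay background along every
#' chromosome; (iii) sparse uniform trans noise. The result is raw and can
#' be normalized with [normalize_cpb()].
#'
#' @param tissue An `or_tissue`.
#' @param zone Dorsoventral zone of the sorted population (1-5).
#' @param resolution Bin width in bp (50 kb default).
#' @param cis_window Number of diagonals of cis background to emit.
#' @param n_trans_noise Number of random trans noise pixels.
#' @param seed Seed for the contact substream.
#' @return A raw `contact_matrix` covering the whole synthetic genome.
#' @export
emit_hic_contacts <- function(tissue, zone, resolution = 50000,
                              cis_window = 20L, n_trans_noise = 20000L,
                              seed = tissue$seed) {
  stopifnot(inherits(tissue, "or_tissue"), zone %in% 1:5)
  params <- tissue$params
  genome <- tissue$genome
  sizes <- chrom_sizes(genome)
  bins <- purrr::map_dfr(names(sizes), function(ch) {
    tibble(
      chrom = ch,
      start = as.integer(seq(0, sizes[[ch]] - 1, by = resolution))
    )
  }) |>
    mutate(bin_id = dplyr::row_number())

  # per-bin mean silencing probability of residing ORs
  q <- expected_silencing(params, genome, zone, tissue$latent)
  ann <- annotate_bins(genome, resolution)
  key <- paste(bins$chrom, bins$start)
  or_bin_ids <- bins$bin_id[match(paste(ann$chrom, ann$start), key)]
  gene_bins <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    b <- seq.int(genome$start[i] %/% resolution,
                 (genome$end[i] - 1L) %/% resolution)
    tibble(chrom = genome$chrom[i], binstart = as.integer(b * resolution),
           q = q[i])
  })
  qbar <- gene_bins |>
    group_by(.data$chrom, .data$binstart) |>
    summarise(q = mean(.data$q), .groups = "drop") |>
    mutate(bin_id = bins$bin_id[match(
      paste(.data$chrom, .data$binstart), key
    )])

  with_substream(rz_seed(seed, "hic", zone), {
    # OR-bin x OR-bin component (all pairs, cis and trans); expected count is
    # gain * qbar_i * qbar_j + floor (mean joint silencing probability of the
    # residing ORs under independent per-gene silencing)
    n_or <- nrow(qbar)
    ij <- which(upper.tri(matrix(0, n_or, n_or), diag = FALSE),
                arr.ind = TRUE)
    mu <- params$hic_gain * qbar$q[ij[, 1]] * qbar$q[ij[, 2]] +
      params$hic_floor
    or_px <- tibble(
      bin1 = pmin(qbar$bin_id[ij[, 1]], qbar$bin_id[ij[, 2]]),
      bin2 = pmax(qbar$bin_id[ij[, 1]], qbar$bin_id[ij[, 2]]),
      count = stats::rpois(length(mu), mu)
    )

    # cis distance decay
    cis_px <- purrr::map_dfr(names(sizes), function(ch) {
      ids <- bins$bin_id[bins$chrom == ch]
      purrr::map_dfr(seq_len(min(cis_window, length(ids) - 1L)), function(k) {
        i <- ids[seq_len(length(ids) - k)]
        tibble(
          bin1 = i, bin2 = i + k,
          count = stats::rpois(length(i), params$hic_cis_scale / (1 + k))
        )
      })
    })

    # uniform trans noise
    noise_i <- sample.int(nrow(bins), n_trans_noise, replace = TRUE)
    noise_j <- sample.int(nrow(bins), n_trans_noise, replace = TRUE)
    keep <- bins$chrom[noise_i] != bins$chrom[noise_j]
    noise_px <- tibble(
      bin1 = pmin(noise_i[keep], noise_j[keep]),
      bin2 = pmax(noise_i[keep], noise_j[keep]),
      count = 1
    )

    pixels <- bind_rows(or_px, cis_px, noise_px) |>
      filter(.data$count > 0)
    contact_matrix(bins, pixels, resolution, normalization = "raw")
  })
}

# Model-derived expectation of the zone-pair map for an emitted matrix on the
# raw-count scale: the exact mean of gain * qbar_i * qbar_j + floor over the
# same eligible interchromosomal bin pairs the aggregation uses. Serves as the
# generator-side oracle for the emitted map.
expected_zone_pair_map <- function(tissue, zone, resolution = 50000) {
  params <- tissue$params
  genome <- tissue$genome
  q <- expected_silencing(params, genome, zone, tissue$latent)
  ann <- annotate_bins(genome, resolution)
  gene_bins <- purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    b <- seq.int(genome$start[i] %/% resolution,
                 (genome$end[i] - 1L) %/% resolution)
    tibble(chrom = genome$chrom[i], start = as.integer(b * resolution),
           q = q[i])
  })
  qbar <- gene_bins |>
    group_by(.data$chrom, .data$start) |>
    summarise(q = mean(.data$q), .groups = "drop")
  ann <- ann |>
    left_join(qbar, by = c("chrom", "start"))
  zlabels <- as.character(1:5)
  Z <- matrix(0, nrow(ann), 5, dimnames = list(NULL, zlabels))
  for (i in seq_len(nrow(ann))) {
    labs <- intersect(ann$zone_labels[[i]], zlabels)
    Z[i, labs] <- 1
  }
  trans <- outer(ann$chrom, ann$chrom, "!=") * 1
  mu <- params$hic_gain * outer(ann$q, ann$q) + params$hic_floor
  num <- t(Z) %*% (mu * trans) %*% Z
  cnt <- t(Z) %*% trans %*% Z
  map <- num / cnt
  map[cnt == 0] <- NA_real_
  dimnames(map) <- list(zlabels, zlabels)
  map
}
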