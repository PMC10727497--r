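# Unconditional per-gene silencing probability for cells of one zone:
# P(transcribed) * P(silenced | transcribed). Class I genes are never
# silenced, so their expected density is background only.
expected_silencing <- function(params, genome, zone,
                               mats = or_propensities(params, genome)) {
  mats$p_t[zone, ] * mats$p_sil[zone, ]
}

#' Emit heterochromatin ChIP coverage for one zone's mature neurons
#'
#' The expected gene-body density of an OR is proportional to the frequency
#' with which it is heterochromatically silenced in cells of the tissue's
#' zone (the mean of the per-cell silencing indicators, taken at its
#' expectation so that a noiseless emission is exactly the model gradient),
#' plus an additive background; per-gene lognormal measurement noise with
#' coefficient of variation `chip_noise` is applied on top. A stepwise
#' coverage track (uniform over each gene body, already normalized to 10^7
#' reads) is emitted alongside the density table.
#'
#' @param tissue An `or_tissue` (supplies genome, parameters and the
#'   perturbation state).
#' @param zone Dorsoventral zone of the sorted cell population (1-5).
#' @param noise Override for the lognormal CV (default `params$chip_noise`;
#'   0 gives the exact expected gradient).
#' @param seed Seed for the noise substream.
#' @return A list with `densities` (tibble `gene_id, zone, or_class, density,
#'   tissue_zone`) and `track` (a normalized `coverage_track`).
#' @export
emit_chip_coverage <- function(tissue, zone,
                               noise = tissue$params$chip_noise,
                               seed = tissue$seed) {
  stopifnot(inherits(tissue, "or_tissue"), zone %in% 1:5)
  params <- tissue$params
  genome <- tissue$genome
  expected <- expected_silencing(params, genome, zone, tissue$latent) +
    params$chip_background
  density <- if (noise > 0) {
    sdlog <- sqrt(log(1 + noise^2))
    with_substream(
      rz_seed(seed, "chip", zone),
      expected * stats::rlnorm(length(expected), -sdlog^2 / 2, sdlog)
    )
  } else {
    expected
  }
  tz <- as.integer(zone)
  densities <- tibble(
    gene_id = genome$gene_id,
    zone = genome$zone,
    or_class = genome$or_class,
    density = unname(density),
    tissue_zone = tz
  )
  track <- coverage_track(
    tibble(
      chrom = genome$chrom,
      start = genome$start,
      end = genome$end,
      depth = unname(density)
    ),
    library_size = 1e7,
    normalized = TRUE
  )
  list(densities = densities, track = track)
}

#' Emit ChIP density tables across several zones
#'
#' Convenience wrapper running [emit_chip_coverage()] for each requested
#' zone and binding the density tables (the layout expected by
#' [fit_silencing_gradient()]).
#'
#' @inheritParams emit_chip_coverage
#' @param zones Zones of the sorted tissues.
#' @return A tibble of per-gene densities with `tissue_zone`.
#' @export
emit_chip_gradient <- function(tissue, zones = 1:5,
                               noise = tissue$params$chip_noise,
                               seed = tissue$seed) {
  purrr::map_dfr(
    zones,
    function(z) emit_chip_coverage(tissue, z, noise, seed)$densities
  )
}
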