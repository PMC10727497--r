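#' Parameters of the generative zonal OR-choice model
#'
#' The model formalizes singular OR choice as two opposing dorsoventrally
#' graded processes. In progenitors, each class II OR `o` with zone `z_o` is
#' transcribed in a cell of zone `z_c` with probability
#' `1 - exp(-a0 * s(z_o) * A)`, where the promoter strength `s(z)` decreases
#' from dorsal to ventral and the permission `A` is 1 for `z_o <= z_c` and
#' `ectopic_leak` otherwise. Class I ORs are transcribed only in zone-1 cells
#' and are never silenced. Each transcribed OR is then silenced with
#' probability `sigma(d) * exp(-propensity / escape_scale)`, where
#' `d = z_c - z_o` and `sigma(d) = sil_own + (1 - sil_own) * (1 - exp(-sil_shape * d))`
#' for `d >= 0`, extended as `sil_own * exp(sil_shape * d)` for `d < 0` so that
#' silencing keeps decreasing in more dorsal cells. A mature neuron chooses
#' one OR among the transcribed, unsilenced survivors with probability
#' proportional to its transcriptional propensity `a0 * s(z_o) * A`; an empty
#' survivor set triggers a fresh redraw.
#'
#' Transcriptional induction of one allele (`induced_or`, `induction_tau`)
#' multiplies its propensity by `1 + induction_tau` and makes it transcribable
#' in every zone, and the multiplicative escape term lets a strongly induced
#' allele evade silencing: the timing/level of induction arbitrates between
#' silencing and choice. `nfi_ko = TRUE` clamps the effective zone of class II
#' regulation to `min(z_c, 2)` (both permission and silencing offset),
#' leaving zone-1 and class I behavior unchanged.
#'
#' Default repertoire composition matches the annotated mouse OR repertoire
#' (115 class I genes; 261/283/164/144/44 class II genes in zones 1-5).
#'
#' @param n_class_i Number of class I OR genes.
#' @param n_per_zone Integer vector of class II gene counts for zones 1-5.
#' @param n_clusters Number of genomic OR clusters.
#' @param n_chromosomes Number of synthetic chromosomes (>= 2).
#' @param promoter_strength `s(z)`, positive and non-increasing over zones 1-5.
#' @param class_i_strength Promoter strength of class I ORs (zone-1 cells only).
#' @param base_rate `a0`, scales transcription propensity.
#' @param ectopic_leak Permission for ORs more ventral than the cell (in `[0,1]`).
#' @param sil_own Probability of silencing an OR of the cell's own zone.
#' @param sil_shape Rate at which silencing grows with dorsal offset `d`.
#' @param escape_scale Propensity scale of the multiplicative silencing escape.
#' @param nfi_ko Clamp class II regulation to an effective zone of at most 2.
#' @param induced_or Gene id of a transcriptionally induced allele, or `NULL`.
#' @param induction_tau Non-negative induction strength (propensity multiplier
#'   `1 + induction_tau`).
#' @param redraw_max Maximum redraws when a cell's survivor set is empty.
#' @param hk_genes,hk_total Number of non-OR background genes and their summed
#'   expected UMIs per cell (sequencing-depth realism for QC).
#' @param mito_genes,mito_frac Number of mitochondrial genes and their expected
#'   fraction of background UMIs.
#' @param chosen_mean Expected UMIs of the chosen OR in a mature neuron.
#' @param inp_umi_per_propensity Expected UMIs per unit propensity for
#'   polygenically transcribed ORs in progenitors.
#' @param basal_mean Expected UMIs of non-chosen surviving ORs in mature
#'   neurons (post-choice baseline).
#' @param ambient Expected ambient UMIs per gene per cell.
#' @param chip_noise Lognormal coefficient of variation of emitted per-gene
#'   ChIP densities (0 = noiseless).
#' @param chip_background Additive background density (normalized reads/bp).
#' @param hic_gain Expected Hi-C counts per unit joint-silencing probability
#'   per OR bin pair.
#' @param hic_floor Expected background Hi-C counts per trans OR bin pair.
#' @param hic_cis_scale Expected counts of the cis distance-decay background
#'   at distance one bin.
#' @param bead_bp 3D-structure bead spacing in bp.
#' @param territory_radius Chromosome-territory placement radius (particle radii).
#' @param territory_sd Stationary spread of a chromosome backbone around its
#'   territory center (particle radii).
#' @param n_attractors_mean Mean number of OR-compartment attractor points per
#'   nucleus (at least 2 are drawn).
#' @param attractor_sd Spread of attractor points around the nuclear center.
#' @param aggregate_jitter Spread of silenced OR beads around their attractor.
#' @param contact_radius Distance (particle radii) within which OR bead pairs
#'   register a single-cell contact.
#' @param n_background_contacts Background (non-OR) contacts per cell.
#' @param spot_cells_range Range of mature neurons pooled per spatial spot.
#' @param band_overlap Probability that a spot cell is drawn from an adjacent
#'   dorsoventral band.
#' @param seed Integer seed; all randomness in the generator derives from it.
#' @return An object of class `rheostat_params` (a validated named list).
#' @export
rheostat_params <- function(n_class_i = 115L,
                            n_per_zone = c(261L, 283L, 164L, 144L, 44L),
                            n_clusters = 30L,
                            n_chromosomes = 4L,
                            promoter_strength = c(1, 0.8, 0.6, 0.45, 0.35),
                            class_i_strength = 0.5,
                            base_rate = 0.02,
                            ectopic_leak = 0,
                            sil_own = 0.6,
                            sil_shape = 4,
                            escape_scale = 2e6,
                            nfi_ko = FALSE,
                            induced_or = NULL,
                            induction_tau = 0,
                            redraw_max = 1000L,
                            hk_genes = 1500L,
                            hk_total = 28000,
                            mito_genes = 13L,
                            mito_frac = 0.02,
                            chosen_mean = 200,
                            inp_umi_per_propensity = 600,
                            basal_mean = 0.2,
                            ambient = 0.001,
                            chip_noise = 0.03,
                            chip_background = 2e-4,
                            hic_gain = 1e5,
                            hic_floor = 0.2,
                            hic_cis_scale = 30,
                            bead_bp = 20000L,
                            territory_radius = 100,
                            territory_sd = 12,
                            n_attractors_mean = 3,
                            attractor_sd = 15,
                            aggregate_jitter = 2,
                            contact_radius = 10,
                            n_background_contacts = 25000L,
                            spot_cells_range = c(5L, 30L),
                            band_overlap = 0.1,
                            seed = 1L) {
  params <- list(
    n_class_i = as.integer(n_class_i),
    n_per_zone = as.integer(n_per_zone),
    n_clusters = as.integer(n_clusters),
    n_chromosomes = as.integer(n_chromosomes),
    promoter_strength = as.numeric(promoter_strength),
    class_i_strength = as.numeric(class_i_strength),
    base_rate = as.numeric(base_rate),
    ectopic_leak = as.numeric(ectopic_leak),
    sil_own = as.numeric(sil_own),
    sil_shape = as.numeric(sil_shape),
    escape_scale = as.numeric(escape_scale),
    nfi_ko = isTRUE(nfi_ko),
    induced_or = induced_or,
    induction_tau = as.numeric(induction_tau),
    redraw_max = as.integer(redraw_max),
    hk_genes = as.integer(hk_genes),
    hk_total = as.numeric(hk_total),
    mito_genes = as.integer(mito_genes),
    mito_frac = as.numeric(mito_frac),
    chosen_mean = as.numeric(chosen_mean),
    inp_umi_per_propensity = as.numeric(inp_umi_per_propensity),
    basal_mean = as.numeric(basal_mean),
    ambient = as.numeric(ambient),
    chip_noise = as.numeric(chip_noise),
    chip_background = as.numeric(chip_background),
    hic_gain = as.numeric(hic_gain),
    hic_floor = as.numeric(hic_floor),
    hic_cis_scale = as.numeric(hic_cis_scale),
    bead_bp = as.integer(bead_bp),
    territory_radius = as.numeric(territory_radius),
    territory_sd = as.numeric(territory_sd),
    n_attractors_mean = as.numeric(n_attractors_mean),
    attractor_sd = as.numeric(attractor_sd),
    aggregate_jitter = as.numeric(aggregate_jitter),
    contact_radius = as.numeric(contact_radius),
    n_background_contacts = as.integer(n_background_contacts),
    spot_cells_range = as.integer(spot_cells_range),
    band_overlap = as.numeric(band_overlap),
    seed = as.integer(seed)
  )
  class(params) <- "rheostat_params"
  validate_rheostat_params(params)
}

validate_rheostat_params <- function(params) {
  s <- params$promoter_strength
  if (length(s) != 5 || any(s <= 0) || any(diff(s) > 0)) {
    abort("promoter_strength must be 5 positive values, non-increasing over zones")
  }
  if (length(params$n_per_zone) != 5 || any(params$n_per_zone < 0)) {
    abort("n_per_zone must be 5 non-negative counts")
  }
  probs <- c(params$ectopic_leak, params$sil_own, params$band_overlap,
             params$mito_frac)
  if (any(probs < 0 | probs > 1)) {
    abort("ectopic_leak, sil_own, band_overlap and mito_frac must be in [0, 1]")
  }
  if (params$sil_shape <= 0 || params$escape_scale <= 0 ||
      params$base_rate <= 0) {
    abort("sil_shape, escape_scale and base_rate must be positive")
  }
  if (params$induction_tau < 0) {
    abort("induction_tau must be non-negative")
  }
  if (params$n_chromosomes < 2) {
    abort("n_chromosomes must be at least 2")
  }
  params
}

#' @export
print.rheostat_params <- function(x, ...) {
  cat("<rheostat_params>\n")
  cat(sprintf(
    "  repertoire: %d class I + %s class II ORs in %d clusters on %d chromosomes\n",
    x$n_class_i, paste(x$n_per_zone, collapse = "/"), x$n_clusters,
    x$n_chromosomes
  ))
  cat(sprintf(
    "  transcription: a0 = %g, s(z) = %s, leak = %g\n",
    x$base_rate, paste(x$promoter_strength, collapse = ", "), x$ectopic_leak
  ))
  cat(sprintf(
    "  silencing: sil_own = %g, sil_shape = %g, escape_scale = %g\n",
    x$sil_own, x$sil_shape, x$escape_scale
  ))
  if (x$nfi_ko) cat("  NFI knockout: effective zone clamped to <= 2\n")
  if (!is.null(x$induced_or)) {
    cat(sprintf("  induced allele: %s (tau = %g)\n", x$induced_or,
                x$induction_tau))
  }
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Apply the NFI triple-knockout perturbation to model parameters
#'
#' Cells with a dorsoventral zone of 2 or greater behave with an effective
#' zone of 2 for class II regulation: both the transcription permission and
#' the silencing offset use the clamped zone, so ventral-identity ORs are
#' never transcribed (hence never silenced) and the tissue dorsalizes toward
#' a zone-2 identity. Zone-1 cells and class I ORs are unaffected.
#'
#' @param params A [rheostat_params()] object.
#' @return The perturbed parameter object.
#' @export
apply_nfi_knockout <- function(params) {
  stopifnot(inherits(params, "rheostat_params"))
  params$nfi_ko <- TRUE
  params
}

#' Set transcriptional induction of one OR allele
#'
#' @param params A [rheostat_params()] object.
#' @param gene_id Gene to induce (tetO-style transcriptional activation in
#'   progenitors).
#' @param tau Induction strength; the allele's propensity is multiplied by
#'   `1 + tau` and it becomes transcribable in every zone.
#' @return The perturbed parameter object.
#' @export
induce_or <- function(params, gene_id, tau) {
  stopifnot(inherits(params, "rheostat_params"), tau >= 0)
  params$induced_or <- gene_id
  params$induction_tau <- as.numeric(tau)
  params
}

#' Write / read the full parameter set as a YAML config
#'
#' @param params A [rheostat_params()] object.
#' @param path File path.
#' @return `path` (write) or a `rheostat_params` object (read).
#' @export
write_params_yaml <- function(params, path) {
  stopifnot(inherits(params, "rheostat_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' @rdname write_params_yaml
#' @export
read_params_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(rheostat_params, vals)
}
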