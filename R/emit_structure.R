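# Deterministic territory centers: 2 * n_chrom points on a circle of radius
# territory_radius in the xy plane, guaranteeing wide separation between
# haplotype-chromosome backbones.
territory_centers <- function(n_chrom, radius) {
  k <- 2L * n_chrom
  angle <- 2 * pi * (seq_len(k) - 1) / k
  cbind(radius * cos(angle), radius * sin(angle), 0)
}

#' Emit a haplotype-resolved 3D structure for one simulated cell
#'
#' Each haplotype-chromosome backbone is a tethered random walk (AR(1) per
#' axis) around a well-separated territory center, one bead per `bead_bp` bp,
#' in particle-radius units. The beads of heterochromatically silenced OR
#' genes (both haplotypes) are displaced to one of a small random number of
#' nuclear attractor points plus jitter, forming multi-chromosomal OR
#' aggregates; unsilenced OR beads stay on their backbone.
#'
#' @param tissue An `or_tissue`.
#' @param cell_id Id of the cell to model (defaults to the first mOSN).
#' @param seed Seed for the structure substream (vary to obtain alternative
#'   conformations of the same latent state).
#' @return A `structure_3d`.
#' @export
emit_structure <- function(tissue, cell_id = NULL, seed = tissue$seed) {
  stopifnot(inherits(tissue, "or_tissue"))
  params <- tissue$params
  genome <- tissue$genome
  if (is.null(cell_id)) {
    cell_id <- tissue$cells$cell_id[tissue$cells$stage == "mOSN"][1]
  }
  j <- match(cell_id, tissue$cells$cell_id)
  if (is.na(j)) abort(sprintf("cell '%s' not in tissue", cell_id))
  silenced_genes <- which(tissue$silenced[, j])

  sizes <- chrom_sizes(genome)
  haps <- c("(mat)", "(pat)")
  centers <- territory_centers(length(sizes), params$territory_radius)
  rho <- 0.99
  innov <- params$territory_sd * sqrt(1 - rho^2)

  with_substream(rz_seed(seed, "structure", cell_id), {
    beads <- list()
    ti <- 0L
    for (ch in names(sizes)) {
      n_beads <- max(2L, ceiling(sizes[[ch]] / params$bead_bp))
      for (h in haps) {
        ti <- ti + 1L
        ctr <- centers[ti, ]
        steps <- matrix(stats::rnorm(3L * n_beads, sd = innov), n_beads, 3)
        xyz <- matrix(0, n_beads, 3)
        xyz[1, ] <- ctr + stats::rnorm(3, sd = params$territory_sd)
        for (t in 2:n_beads) {
          xyz[t, ] <- ctr + rho * (xyz[t - 1, ] - ctr) + steps[t, ]
        }
        beads[[length(beads) + 1L]] <- tibble(
          chrom_hap = paste0(ch, h),
          pos = as.integer((seq_len(n_beads) - 1L) * params$bead_bp),
          x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
        )
      }
    }
    beads <- bind_rows(beads)

    if (length(silenced_genes) > 0) {
      n_attr <- 2L + stats::rpois(1, max(params$n_attractors_mean - 2, 0))
      attractors <- matrix(
        stats::rnorm(3L * n_attr, sd = params$attractor_sd), n_attr, 3
      )
      mid <- (genome$start[silenced_genes] + genome$end[silenced_genes]) / 2
      bead_pos <- as.integer(round(mid / params$bead_bp) * params$bead_bp)
      for (k in seq_along(silenced_genes)) {
        for (h in haps) {
          key <- which(
            beads$chrom_hap == paste0(genome$chrom[silenced_genes[k]], h)
          )
          row <- key[which.min(abs(beads$pos[key] - bead_pos[k]))]
          a <- attractors[sample.int(n_attr, 1), ]
          beads$x[row] <- a[1] + stats::rnorm(1, sd = params$aggregate_jitter)
          beads$y[row] <- a[2] + stats::rnorm(1, sd = params$aggregate_jitter)
          beads$z[row] <- a[3] + stats::rnorm(1, sd = params$aggregate_jitter)
        }
      }
    }
    structure_3d(beads, cell_id = cell_id)
  })
}

#' Emit a haplotype-resolved single-cell contact list
#'
#' Derives contacts from an emitted structure: every interchromosomal OR
#' bead pair within `contact_radius` particle radii contributes a contact,
#' plus `n_background_contacts` short-range cis background contacts sampled
#' along the backbones (geometric genomic separations), so that cells clear
#' the standard contact-count quality filter.
#'
#' @param structure A `structure_3d` from [emit_structure()].
#' @param genome The genome tibble.
#' @param params Model parameters.
#' @param seed Seed for the contact substream.
#' @return A tibble `chrom_a, pos_a, chrom_b, pos_b`.
#' @export
emit_cell_contacts <- function(structure, genome, params,
                               seed = params$seed) {
  stopifnot(inherits(structure, "structure_3d"))
  res <- resolve_loci(structure, genome)
  d <- as.matrix(stats::dist(as.matrix(res[, c("x", "y", "z")])))
  trans <- outer(res$chrom_hap, res$chrom_hap, "!=")
  prox <- which(d <= params$contact_radius & trans & upper.tri(d),
                arr.ind = TRUE)
  mid <- (genome$start + genome$end) / 2
  res$gpos <- as.integer(
    round(mid[match(res$gene_id, genome$gene_id)] / params$bead_bp) *
      params$bead_bp
  )
  with_substream(rz_seed(seed, "contacts", structure$cell_id), {
    or_contacts <- tibble(
      chrom_a = res$chrom_hap[prox[, 1]],
      pos_a = res$gpos[prox[, 1]],
      chrom_b = res$chrom_hap[prox[, 2]],
      pos_b = res$gpos[prox[, 2]]
    )
    sizes <- structure$beads |>
      group_by(.data$chrom_hap) |>
      summarise(size = max(.data$pos), .groups = "drop")
    n_bg <- params$n_background_contacts
    ch <- sample(sizes$chrom_hap, n_bg, replace = TRUE)
    size_of <- stats::setNames(sizes$size, sizes$chrom_hap)
    pos_a <- floor(stats::runif(n_bg, 0, size_of[ch]))
    sep <- stats::rgeom(n_bg, prob = 1 / 10) + 1
    pos_b <- pmin(pos_a + sep * params$bead_bp, size_of[ch])
    bg <- tibble(
      chrom_a = ch, pos_a = as.integer(pos_a),
      chrom_b = ch, pos_b = as.integer(pos_b)
    )
    bind_rows(or_contacts, bg)
  })
}
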