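# Per-zone regulatory probabilities of the rheostat model.
#
# Returns, for each cell zone (rows 1..5) and gene (columns), the
# transcriptional propensity, the transcription probability and the
# conditional silencing probability. Class I genes are transcribable only in
# zone-1 cells and never silenced. Under NFI knockout, class II regulation
# uses an effective cell zone of min(zone, 2).
or_propensities <- function(params, genome) {
  G <- nrow(genome)
  zones <- 1:5
  s <- params$promoter_strength
  a0 <- params$base_rate
  is_i <- genome$or_class == "I"
  z_o <- genome$zone
  induced <- if (is.null(params$induced_or)) {
    rep(FALSE, G)
  } else {
    genome$gene_id == params$induced_or
  }
  if (!is.null(params$induced_or) && !any(induced)) {
    abort(sprintf("induced_or '%s' is not in the genome", params$induced_or))
  }
  prop <- p_t <- p_sil <- matrix(0, nrow = 5, ncol = G,
                                 dimnames = list(NULL, genome$gene_id))
  for (z_c in zones) {
    z_reg <- if (params$nfi_ko) min(z_c, 2L) else z_c

    # class II
    ii <- !is_i
    A <- ifelse(z_o[ii] <= z_reg, 1, params$ectopic_leak)
    mult <- ifelse(induced[ii], 1 + params$induction_tau, 1)
    A[induced[ii]] <- 1 # induction overrides zonal permission
    pr <- a0 * s[z_o[ii]] * A * mult
    d <- z_reg - z_o[ii]
    sig <- ifelse(
      d >= 0,
      params$sil_own + (1 - params$sil_own) *
        (1 - exp(-params$sil_shape * d)),
      params$sil_own * exp(params$sil_shape * d)
    )
    prop[z_c, ii] <- pr
    p_t[z_c, ii] <- 1 - exp(-pr)
    p_sil[z_c, ii] <- sig * exp(-pr / params$escape_scale)

    # class I: zone-1 cells only, never silenced
    if (z_c == 1L) {
      pr_i <- a0 * params$class_i_strength
      prop[z_c, is_i] <- pr_i
      p_t[z_c, is_i] <- 1 - exp(-pr_i)
    }
  }
  list(prop = prop, p_t = p_t, p_sil = p_sil)
}

stage_levels <- function() c("GBC", "INP", "iOSN", "mOSN")

# Vectorized simulation of one (zone, stage) block of cells. Draws are made in
# row-chunks to bound memory; mature neurons redraw transcription + silencing
# with fresh randomness until the survivor set is non-empty.
sim_block <- function(n, zone, stage, mats, params) {
  G <- ncol(mats$p_t)
  p_t <- mats$p_t[zone, ]
  p_sil <- mats$p_sil[zone, ]
  prop <- mats$prop[zone, ]
  silencing_on <- stage %in% c("iOSN", "mOSN")
  log_prop <- suppressWarnings(log(prop))

  # draws are sparse past the transcription step: silencing and choice only
  # touch transcribed (cell, gene) entries
  draw_once <- function(m) {
    t_mat <- matrix(stats::runif(m * G), m, G) <
      matrix(p_t, m, G, byrow = TRUE)
    t_idx <- which(t_mat, arr.ind = TRUE)
    s_flag <- if (silencing_on && nrow(t_idx) > 0) {
      stats::runif(nrow(t_idx)) < p_sil[t_idx[, 2]]
    } else {
      rep(FALSE, nrow(t_idx))
    }
    chosen <- rep(NA_integer_, m)
    if (stage == "mOSN" && any(!s_flag)) {
      surv <- t_idx[!s_flag, , drop = FALSE]
      # Gumbel-max: choose gene with prob proportional to propensity per row
      score <- log_prop[surv[, 2]] -
        log(-log(stats::runif(nrow(surv))))
      ord <- order(surv[, 1], -score)
      first <- !duplicated(surv[ord, 1])
      chosen[surv[ord, 1][first]] <- surv[ord, 2][first]
    }
    list(
      t_idx = t_idx,
      s_idx = t_idx[s_flag, , drop = FALSE],
      chosen = chosen
    )
  }

  chunk <- max(1L, 2e6 %/% G)
  t_idx <- vector("list", 0)
  s_idx <- vector("list", 0)
  chosen <- rep(NA_integer_, n)
  attempts <- rep(1L, n)
  starts <- seq(1L, n, by = chunk)
  for (st in starts) {
    rows <- st:min(st + chunk - 1L, n)
    m <- length(rows)
    d <- draw_once(m)
    if (stage == "mOSN") {
      empty <- which(is.na(d$chosen))
      tries <- 1L
      while (length(empty) > 0) {
        tries <- tries + 1L
        if (tries > params$redraw_max) {
          abort(sprintf(
            paste0(
              "no surviving OR after %d redraws for zone-%d %s cells; ",
              "parameters leave the survivor set empty ",
              "(sil_own = %g, sil_shape = %g, base_rate = %g)"
            ),
            params$redraw_max, zone, stage,
            params$sil_own, params$sil_shape, params$base_rate
          ))
        }
        rd <- draw_once(length(empty))
        attempts[rows[empty]] <- tries
        # replace the latent state of the redrawn cells wholesale
        remap <- function(old, new) {
          rbind(
            old[!(old[, 1] %in% empty), , drop = FALSE],
            cbind(empty[new[, 1]], new[, 2], deparse.level = 0)
          )
        }
        d$t_idx <- remap(d$t_idx, rd$t_idx)
        d$s_idx <- remap(d$s_idx, rd$s_idx)
        filled <- !is.na(rd$chosen)
        d$chosen[empty[filled]] <- rd$chosen[filled]
        empty <- empty[!filled]
      }
    }
    t_idx[[length(t_idx) + 1L]] <-
      cbind(rows[d$t_idx[, 1]], d$t_idx[, 2], deparse.level = 0)
    if (silencing_on) {
      s_idx[[length(s_idx) + 1L]] <-
        cbind(rows[d$s_idx[, 1]], d$s_idx[, 2], deparse.level = 0)
    }
    chosen[rows] <- d$chosen
  }
  list(
    t_idx = do.call(rbind, t_idx),
    s_idx = do.call(rbind, s_idx),
    chosen = chosen,
    attempts = attempts
  )
}

#' Simulate a single cell of the olfactory lineage
#'
#' Draws the latent regulatory state of one cell: the polygenically
#' transcribed OR set with propensities (INP onward), the heterochromatically
#' silenced subset (iOSN onward), and for mature neurons the single chosen OR
#' (probability proportional to propensity among unsilenced survivors, with
#' redraws on an empty survivor set).
#'
#' @param params A [rheostat_params()] object.
#' @param genome Genome tibble from [build_genome()].
#' @param dv_zone Dorsoventral zone of the cell (1-5).
#' @param stage One of `"GBC"`, `"INP"`, `"iOSN"`, `"mOSN"`.
#' @param seed Seed for this cell's substream.
#' @return A list with `stage`, `dv_zone`, `transcribed` (named propensity
#'   vector), `silenced` (character), `chosen` (character or `NA`), and
#'   `attempts`.
#' @export
simulate_cell <- function(params, genome, dv_zone, stage = "mOSN",
                          seed = params$seed) {
  stopifnot(dv_zone %in% 1:5, stage %in% stage_levels())
  mats <- or_propensities(params, genome)
  with_substream(rz_seed(seed, "cell", dv_zone, stage), {
    if (stage == "GBC") {
      blk <- list(
        t_idx = matrix(integer(), 0, 2), s_idx = matrix(integer(), 0, 2),
        chosen = NA_integer_, attempts = 1L
      )
    } else {
      blk <- sim_block(1L, dv_zone, stage, mats, params)
    }
    t_genes <- if (is.null(blk$t_idx)) integer() else blk$t_idx[, 2]
    s_genes <- if (is.null(blk$s_idx)) integer() else blk$s_idx[, 2]
    list(
      stage = stage,
      dv_zone = as.integer(dv_zone),
      transcribed = stats::setNames(
        mats$prop[dv_zone, t_genes],
        genome$gene_id[t_genes]
      ),
      silenced = genome$gene_id[s_genes],
      chosen = if (is.na(blk$chosen[1])) NA_character_ else {
        genome$gene_id[blk$chosen[1]]
      },
      attempts = blk$attempts[1]
    )
  })
}

#' Simulate a tissue of olfactory cells across dorsoventral zones
#'
#' @param params A [rheostat_params()] object.
#' @param genome Genome tibble from [build_genome()]; built from `params` if
#'   omitted.
#' @param n_cells_per_zone Number of cells per zone and stage.
#' @param stage_mix Character vector of stages to simulate (each stage gets
#'   `n_cells_per_zone` cells per zone).
#' @param zones Zones to populate (default 1-5).
#' @param seed Base seed; per-(zone, stage) substreams are derived from it by
#'   counter, so results do not depend on simulation order.
#' @return An `or_tissue` object: list with `cells` (tibble: `cell_id, stage,
#'   dv_zone, chosen, attempts`), sparse logical gene-by-cell matrices
#'   `transcribed` and `silenced`, the `genome`, the regulatory probability
#'   matrices (`latent`), and `params`.
#' @export
simulate_tissue <- function(params, genome = build_genome(params),
                            n_cells_per_zone = 100L,
                            stage_mix = "mOSN",
                            zones = 1:5,
                            seed = params$seed) {
  stopifnot(n_cells_per_zone >= 1, all(stage_mix %in% stage_levels()))
  mats <- or_propensities(params, genome)
  G <- nrow(genome)
  cells <- list()
  t_trip <- list()
  s_trip <- list()
  offset <- 0L
  for (stage in stage_mix) {
    for (z in zones) {
      blk <- with_substream(
        rz_seed(seed, "tissue", z, stage),
        if (stage == "GBC") {
          list(
            t_idx = NULL, s_idx = NULL,
            chosen = rep(NA_integer_, n_cells_per_zone),
            attempts = rep(1L, n_cells_per_zone)
          )
        } else {
          sim_block(n_cells_per_zone, z, stage, mats, params)
        }
      )
      cells[[length(cells) + 1L]] <- tibble(
        cell_id = sprintf("cell_%s_z%d_%05d", stage, z,
                          seq_len(n_cells_per_zone)),
        stage = stage,
        dv_zone = as.integer(z),
        chosen = ifelse(is.na(blk$chosen), NA_character_,
                        genome$gene_id[blk$chosen]),
        attempts = blk$attempts
      )
      if (!is.null(blk$t_idx) && nrow(blk$t_idx) > 0) {
        t_trip[[length(t_trip) + 1L]] <-
          cbind(blk$t_idx[, 2], blk$t_idx[, 1] + offset)
      }
      if (!is.null(blk$s_idx) && nrow(blk$s_idx) > 0) {
        s_trip[[length(s_trip) + 1L]] <-
          cbind(blk$s_idx[, 2], blk$s_idx[, 1] + offset)
      }
      offset <- offset + n_cells_per_zone
    }
  }
  cells <- bind_rows(cells)
  make_sparse <- function(trip) {
    if (length(trip) == 0) {
      return(Matrix::sparseMatrix(
        i = integer(), j = integer(), dims = c(G, offset),
        dimnames = list(genome$gene_id, cells$cell_id)
      ) > 0)
    }
    trip <- do.call(rbind, trip)
    Matrix::sparseMatrix(
      i = trip[, 1], j = trip[, 2], dims = c(G, offset),
      dimnames = list(genome$gene_id, cells$cell_id)
    ) > 0
  }
  tissue <- list(
    cells = cells,
    transcribed = make_sparse(t_trip),
    silenced = make_sparse(s_trip),
    latent = mats,
    genome = genome,
    params = params,
    seed = seed
  )
  class(tissue) <- "or_tissue"
  tissue
}

#' @export
print.or_tissue <- function(x, ...) {
  cat(sprintf(
    "<or_tissue> %d cells (%s) x %d OR genes; zones %s%s\n",
    nrow(x$cells),
    paste(unique(x$cells$stage), collapse = "/"),
    nrow(x$genome),
    paste(sort(unique(x$cells$dv_zone)), collapse = ","),
    if (x$params$nfi_ko) "; NFI knockout" else ""
  ))
  invisible(x)
}

#' Latent choice summary of a tissue
#'
#' Frequencies of chosen ORs per zone (mature neurons only), with the zonal
#' identity of each chosen gene.
#'
#' @param tissue An `or_tissue`.
#' @return Tibble with `dv_zone, gene_id, zone_label, n, freq` (freq sums to
#'   1 within each zone).
#' @export
choice_frequencies <- function(tissue) {
  genome <- tissue$genome
  tissue$cells |>
    filter(.data$stage == "mOSN") |>
    count(.data$dv_zone, gene_id = .data$chosen) |>
    left_join(
      tibble(
        gene_id = genome$gene_id,
        zone_label = gene_zone_label(genome)
      ),
      by = "gene_id"
    ) |>
    group_by(.data$dv_zone) |>
    mutate(freq = .data$n / sum(.data$n)) |>
    ungroup()
}
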