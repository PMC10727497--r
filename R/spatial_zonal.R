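#' Construct a spatial spot matrix
#'
#' @param counts Sparse genes x spots count matrix with dimnames.
#' @param spots Tibble with `barcode, x, y` (unique coordinates) and
#'   optionally `band_zone` (the generating dorsoventral band).
#' @param genes Gene metadata with `gene_id` and `is_or`.
#' @param sample Sample label (`"control"`, `"perturbed"`, ...).
#' @return A `spot_matrix` object (with a `normalized` slot filled by
#'   [normalize_spots()]).
#' @export
spot_matrix <- function(counts, spots, genes, sample = "control") {
  counts <- methods::as(
    methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
    "CsparseMatrix"
  )
  stopifnot(nrow(counts) == nrow(genes), ncol(counts) == nrow(spots))
  if (length(counts) > 0 && min(counts) < 0) {
    abort("spot counts must be non-negative")
  }
  if (anyDuplicated(spots[, c("x", "y")]) > 0) {
    abort("spot coordinates must be unique")
  }
  dimnames(counts) <- list(genes$gene_id, spots$barcode)
  structure(
    list(
      counts = counts, spots = as_tibble(spots), genes = as_tibble(genes),
      normalized = NULL, sample = sample
    ),
    class = "spot_matrix"
  )
}

#' @export
print.spot_matrix <- function(x, ...) {
  cat(sprintf(
    "<spot_matrix> %s: %d genes x %d spots%s\n",
    x$sample, nrow(x$counts), ncol(x$counts),
    if (is.null(x$normalized)) "" else " (normalized)"
  ))
  invisible(x)
}

#' Emit synthetic spatial transcriptomics spots from a simulated tissue
#'
#' The grid's rows map monotonically onto the five dorsoventral bands; each
#' spot pools the UMI profile of several mature neurons drawn from its
#' band's zone (with `band_overlap` probability from an adjacent band),
#' Poisson-sampled exactly like the single-cell emission.
#'
#' @param tissue An `or_tissue` containing mOSN cells of all zones.
#' @param grid_shape `c(rows, cols)`; rows run dorsal (row 1) to ventral.
#' @param params Model parameters (defaults to the tissue's).
#' @param sample Sample label recorded on the matrix.
#' @param seed Seed for the spatial substream.
#' @return A `spot_matrix` with `band_zone` recorded per spot.
#' @export
emit_spatial <- function(tissue, grid_shape = c(20L, 10L),
                         params = tissue$params, sample = "control",
                         seed = tissue$seed) {
  stopifnot(inherits(tissue, "or_tissue"), length(grid_shape) == 2)
  genome <- tissue$genome
  G <- nrow(genome)
  mosn <- which(tissue$cells$stage == "mOSN")
  if (length(mosn) == 0) abort("tissue has no mature neurons")
  zones_avail <- sort(unique(tissue$cells$dv_zone[mosn]))
  n_rows <- grid_shape[1]
  n_cols <- grid_shape[2]
  band_of_row <- pmin(5L, pmax(1L, ceiling(seq_len(n_rows) * 5 / n_rows)))
  chosen_idx <- match(tissue$cells$chosen, genome$gene_id)
  prop <- tissue$latent$prop

  with_substream(rz_seed(seed, "spatial", sample), {
    spots <- tidyr::expand_grid(row = seq_len(n_rows), col = seq_len(n_cols))
    n_spots <- nrow(spots)
    counts <- matrix(0L, G, n_spots)
    band <- integer(n_spots)
    for (s in seq_len(n_spots)) {
      b <- band_of_row[spots$row[s]]
      band[s] <- b
      n_cells <- sample(
        params$spot_cells_range[1]:params$spot_cells_range[2], 1
      )
      zone_draw <- vapply(seq_len(n_cells), function(i) {
        z <- if (stats::runif(1) < params$band_overlap) {
          b + sample(c(-1L, 1L), 1)
        } else {
          b
        }
        as.integer(min(max(z, 1L), 5L))
      }, integer(1))
      mu <- rep(params$ambient * n_cells, G)
      for (z in zone_draw) {
        pool <- mosn[tissue$cells$dv_zone[mosn] == z]
        if (length(pool) == 0) {
          abort(sprintf("no mOSN cells of zone %d available for spots", z))
        }
        j <- pool[sample.int(length(pool), 1)]
        surv <- which(tissue$transcribed[, j] & !tissue$silenced[, j])
        mu[surv] <- mu[surv] + params$basal_mean
        if (!is.na(chosen_idx[j])) {
          mu[chosen_idx[j]] <- mu[chosen_idx[j]] + params$chosen_mean
        }
      }
      counts[, s] <- stats::rpois(G, mu)
    }
    spot_matrix(
      counts,
      spots = tibble(
        barcode = sprintf("spot_%04d", seq_len(n_spots)),
        x = spots$col, y = spots$row, band_zone = band
      ),
      genes = tibble(
        gene_id = genome$gene_id,
        is_or = TRUE,
        zone_label = gene_zone_label(genome)
      ),
      sample = sample
    )
  })
}

#' Filter spatial spots on OR content
#'
#' Keeps spots with at least `min_or_genes` distinct detected OR genes and
#' at least `min_or_umis` total OR UMIs. Spots with zero OR transcripts are
#' dropped here (they are excluded from clustering) but receive the label
#' `"none"` when assigned with [assign_spot_zone()] on the unfiltered
#' matrix.
#'
#' @param m A `spot_matrix`.
#' @param min_or_genes Minimum distinct OR genes per spot.
#' @param min_or_umis Minimum total OR UMIs per spot.
#' @return The filtered `spot_matrix`.
#' @export
filter_spots <- function(m, min_or_genes = 2, min_or_umis = 3) {
  stopifnot(inherits(m, "spot_matrix"))
  orm <- m$counts[m$genes$is_or, , drop = FALSE]
  keep <- Matrix::colSums(orm > 0) >= min_or_genes &
    Matrix::colSums(orm) >= min_or_umis
  m$counts <- m$counts[, keep, drop = FALSE]
  m$spots <- m$spots[keep, , drop = FALSE]
  if (!is.null(m$normalized)) {
    m$normalized <- m$normalized[, keep, drop = FALSE]
  }
  m
}

#' Normalize spot counts
#'
#' Depth-scaled log counts: each spot is scaled to the median spot depth and
#' log1p-transformed — a simple documented stand-in for variance-stabilizing
#' normalization.
#'
#' @param m A `spot_matrix`.
#' @return The matrix with its `normalized` slot filled.
#' @export
normalize_spots <- function(m) {
  stopifnot(inherits(m, "spot_matrix"))
  depth <- Matrix::colSums(m$counts)
  med <- stats::median(depth[depth > 0])
  scale <- ifelse(depth > 0, med / depth, 0)
  norm <- m$counts %*% Matrix::Diagonal(x = scale)
  m$normalized <- log1p(norm)
  dimnames(m$normalized) <- dimnames(m$counts)
  m
}

#' Cluster spatial spots on OR expression
#'
#' PCA on the normalized OR-gene expression (spots in rows), then seeded
#' k-means on the first `n_pcs` principal components.
#'
#' @param m A normalized, filtered `spot_matrix`.
#' @param n_pcs Number of principal components.
#' @param k Number of clusters.
#' @param seed Seed for k-means initialization.
#' @return Tibble `barcode, cluster`.
#' @export
cluster_spots <- function(m, n_pcs = 5, k = 5, seed = 1L) {
  stopifnot(inherits(m, "spot_matrix"))
  if (is.null(m$normalized)) m <- normalize_spots(m)
  if (ncol(m$counts) < k) {
    abort(sprintf("fewer spots (%d) than clusters (%d)", ncol(m$counts), k))
  }
  expr <- t(as.matrix(m$normalized[m$genes$is_or, , drop = FALSE]))
  keep <- apply(expr, 2, stats::sd) > 0
  pcs <- stats::prcomp(expr[, keep, drop = FALSE], center = TRUE,
                       scale. = FALSE)
  emb <- pcs$x[, seq_len(min(n_pcs, ncol(pcs$x))), drop = FALSE]
  cl <- with_substream(
    rz_seed(seed, "kmeans"),
    stats::kmeans(emb, centers = k, nstart = 10, iter.max = 100)
  )
  tibble(barcode = m$spots$barcode, cluster = as.integer(cl$cluster))
}

#' Top-n per-zone OR signatures
#'
#' The `n` highest expressed OR genes (mean normalized expression across
#' spots) for each zonal category present in the gene metadata.
#'
#' @param m A normalized `spot_matrix` with `zone_label` gene metadata.
#' @param n Genes per signature.
#' @return Named list of gene-id vectors (one per zonal category).
#' @export
make_zone_signatures <- function(m, n = 20) {
  stopifnot(inherits(m, "spot_matrix"))
  if (is.null(m$normalized)) m <- normalize_spots(m)
  means <- Matrix::rowMeans(m$normalized)
  genes <- m$genes |> mutate(mean_norm = means)
  genes |>
    filter(.data$is_or, !is.na(.data$zone_label)) |>
    group_by(.data$zone_label) |>
    arrange(dplyr::desc(.data$mean_norm), .data$gene_id, .by_group = TRUE) |>
    slice(seq_len(min(n, dplyr::n()))) |>
    summarise(genes = list(.data$gene_id), .groups = "drop") |>
    (\(df) stats::setNames(df$genes, df$zone_label))()
}

#' Per-spot per-zone signature scores
#'
#' Mean normalized expression of each zone's signature genes in each spot;
#' signature genes absent from the matrix score 0 with a warning.
#'
#' @param m A normalized `spot_matrix`.
#' @param signatures Named list of gene-id vectors per zone.
#' @return Tibble `barcode, zone, score`.
#' @export
zone_signature_score <- function(m, signatures) {
  stopifnot(inherits(m, "spot_matrix"), length(signatures) > 0)
  if (is.null(m$normalized)) m <- normalize_spots(m)
  purrr::imap_dfr(signatures, function(genes, zone) {
    present <- intersect(genes, rownames(m$normalized))
    absent <- setdiff(genes, present)
    if (length(absent) > 0) {
      warn(sprintf("%d signature gene(s) absent for zone %s; scored as 0",
                   length(absent), zone))
    }
    total <- if (length(present) > 0) {
      Matrix::colSums(m$normalized[present, , drop = FALSE])
    } else {
      rep(0, ncol(m$normalized))
    }
    tibble(
      barcode = m$spots$barcode,
      zone = zone,
      score = as.numeric(total) / length(genes)
    )
  })
}

#' Assign each spot a zonal identity
#'
#' Each spot is designated to the zone with the largest summed normalized OR
#' counts (class I ORs form their own gene set but are reported merged with
#' zone 1); spots without any OR transcript are labelled `"none"`; exact
#' ties go to the most dorsal zone.
#'
#' @param m A `spot_matrix` (normalized on the fly if needed).
#' @param zone_sets Optional named list of gene-id vectors per zonal
#'   category (defaults to the `zone_label` gene metadata).
#' @param merge_class_i Report class I wins as zone `"1"`.
#' @return A tibble `barcode, x, y, zone, zone_raw` of class
#'   `spot_assignment`.
#' @export
assign_spot_zone <- function(m, zone_sets = NULL, merge_class_i = TRUE) {
  stopifnot(inherits(m, "spot_matrix"))
  if (is.null(m$normalized)) m <- normalize_spots(m)
  if (is.null(zone_sets)) {
    labs <- m$genes |> filter(.data$is_or, !is.na(.data$zone_label))
    zone_sets <- split(labs$gene_id, labs$zone_label)
  }
  order_levels <- intersect(zone_levels(), names(zone_sets))
  zone_sets <- zone_sets[order_levels]
  scores <- vapply(zone_sets, function(genes) {
    present <- intersect(genes, rownames(m$normalized))
    if (length(present) == 0) {
      return(rep(0, ncol(m$normalized)))
    }
    as.numeric(Matrix::colSums(m$normalized[present, , drop = FALSE]))
  }, numeric(ncol(m$normalized)))
  scores <- matrix(scores, ncol = length(zone_sets),
                   dimnames = list(NULL, names(zone_sets)))
  or_umis <- Matrix::colSums(m$counts[m$genes$is_or, , drop = FALSE])
  # argmax with ties to the most dorsal (first) category
  raw <- names(zone_sets)[apply(scores, 1, which.max)]
  raw[or_umis == 0] <- "none"
  zone <- raw
  if (merge_class_i) zone[zone == "I"] <- "1"
  out <- tibble(
    barcode = m$spots$barcode,
    x = m$spots$x,
    y = m$spots$y,
    zone = zone,
    zone_raw = raw
  )
  if ("band_zone" %in% names(m$spots)) {
    out$band_zone <- m$spots$band_zone
  }
  class(out) <- c("spot_assignment", class(out))
  out
}

#' Spot assignment accuracy against the generating bands
#'
#' @param assignment A `spot_assignment` with a `band_zone` column.
#' @return Fraction of spots whose assigned zone equals the generating band.
#' @export
spot_assignment_accuracy <- function(assignment) {
  assert_columns(assignment, c("zone", "band_zone"))
  mean(assignment$zone == as.character(assignment$band_zone))
}

#' Assignment accuracy as a function of ambient noise
#'
#' Re-emits spatial spots from the same tissue under increasing ambient
#' noise and records the zonal assignment accuracy against the generating
#' bands — a sensitivity curve for the argmax assignment rule.
#'
#' @param tissue An `or_tissue` with mature neurons.
#' @param ambient_levels Ambient UMI rates per gene per cell to scan.
#' @param grid_shape Spatial grid.
#' @param seed Seed for the emissions.
#' @return Tibble `ambient, accuracy`.
#' @export
assignment_sensitivity <- function(tissue,
                                   ambient_levels = c(0.001, 0.1, 1, 10),
                                   grid_shape = c(20L, 10L),
                                   seed = tissue$seed) {
  purrr::map_dfr(ambient_levels, function(a) {
    params <- tissue$params
    params$ambient <- a
    spots <- emit_spatial(tissue, grid_shape = grid_shape, params = params,
                          sample = sprintf("ambient_%g", a), seed = seed)
    acc <- spot_assignment_accuracy(assign_spot_zone(normalize_spots(spots)))
    tibble(ambient = a, accuracy = acc)
  })
}

#' Dorsalization index and per-zone assignment shift
#'
#' Summarizes a perturbation: among perturbed spots assigned a zone other
#' than 1 (and not `"none"`), the fraction assigned zone 2; plus the
#' control-to-perturbed assignment shift table (spots matched by barcode or,
#' failing that, by coordinates).
#'
#' @param assign_control,assign_perturbed `spot_assignment` tibbles on
#'   comparable grids.
#' @return List with `index` (in `[0, 1]`) and `shift` (a contingency tibble
#'   of control vs perturbed labels).
#' @export
dorsalization_index <- function(assign_control, assign_perturbed) {
  joined <- dplyr::inner_join(
    assign_control |> select("barcode", control = "zone"),
    assign_perturbed |> select("barcode", perturbed = "zone"),
    by = "barcode"
  )
  if (nrow(joined) == 0) {
    joined <- dplyr::inner_join(
      assign_control |> select("x", "y", control = "zone"),
      assign_perturbed |> select("x", "y", perturbed = "zone"),
      by = c("x", "y")
    )
  }
  non_dorsal <- assign_perturbed |>
    filter(!.data$zone %in% c("1", "none"))
  index <- if (nrow(non_dorsal) == 0) {
    NA_real_
  } else {
    mean(non_dorsal$zone == "2")
  }
  shift <- joined |>
    count(.data$control, .data$perturbed) |>
    tidyr::pivot_wider(
      names_from = "perturbed", values_from = "n", values_fill = 0L
    )
  list(index = index, shift = shift)
}
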