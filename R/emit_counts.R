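#' Emit a synthetic single-cell UMI count matrix
#'
#' Poisson sampling from the latent state of a simulated tissue. Progenitors
#' (INP) express every transcribed OR at a mean proportional to its
#' propensity; immature neurons (iOSN) express only the unsilenced survivors;
#' mature neurons (mOSN) express the chosen OR at `chosen_mean` with the
#' remaining survivors at the post-choice baseline `basal_mean`. Non-OR
#' background genes (including mitochondrial genes) with fixed lognormal
#' per-gene means provide sequencing-depth realism for QC, stage-specific
#' marker genes (high in the cell's own differentiation stage) support
#' marker-based stage assignment, and `ambient` adds a uniform low-rate term
#' to every gene.
#'
#' @param tissue An `or_tissue` from [simulate_tissue()].
#' @param params Model parameters (defaults to the tissue's).
#' @param seed Seed for the counts substream.
#' @return An `or_counts` object: list with a sparse `counts` matrix
#'   (genes x cells), a `genes` tibble (`gene_id, type, is_or, is_mito,
#'   zone_label`), and a `cells` tibble (cell metadata with dissection
#'   `origin`: dorsal = zones 1-2, ventral = zones 3-5).
#' @export
emit_sc_counts <- function(tissue, params = tissue$params,
                           seed = tissue$seed) {
  stopifnot(inherits(tissue, "or_tissue"))
  genome <- tissue$genome
  G <- nrow(genome)
  n_cells <- nrow(tissue$cells)
  if (n_cells == 0) abort("tissue has no cells")

  stages <- stage_levels()
  n_marker <- 8L
  genes <- tibble(
    gene_id = c(
      genome$gene_id,
      sprintf("Bg%04d", seq_len(params$hk_genes)),
      sprintf("mt-Gene%02d", seq_len(params$mito_genes)),
      sprintf("Mk%s%02d", rep(stages, each = n_marker), seq_len(n_marker))
    ),
    type = c(
      rep("OR", G),
      rep("background", params$hk_genes),
      rep("mito", params$mito_genes),
      rep("marker", length(stages) * n_marker)
    ),
    marker_stage = c(
      rep(NA_character_, G + params$hk_genes + params$mito_genes),
      rep(stages, each = n_marker)
    )
  ) |>
    mutate(
      is_or = .data$type == "OR",
      is_mito = .data$type == "mito",
      zone_label = c(gene_zone_label(genome),
                     rep(NA_character_,
                         params$hk_genes + params$mito_genes +
                           length(stages) * n_marker))
    )

  # fixed per-gene background means, a property of the parameter set
  hk_means <- with_substream(rz_seed(params$seed, "counts", "hk"), {
    mu <- stats::rlnorm(params$hk_genes, meanlog = 0, sdlog = 1.5)
    mu * (params$hk_total * (1 - params$mito_frac)) / sum(mu)
  })
  mito_means <- rep(
    params$hk_total * params$mito_frac / params$mito_genes,
    params$mito_genes
  )

  chosen_idx <- match(tissue$cells$chosen, genome$gene_id)
  prop <- tissue$latent$prop
  counts_chunks <- list()
  chunk <- max(1L, 5e5 %/% nrow(genes))
  starts <- seq(1L, n_cells, by = chunk)
  for (ci in seq_along(starts)) {
    cols <- starts[ci]:min(starts[ci] + chunk - 1L, n_cells)
    m <- length(cols)
    mu_or <- matrix(params$ambient, G, m)
    for (k in seq_len(m)) {
      j <- cols[k]
      stage <- tissue$cells$stage[j]
      zone <- tissue$cells$dv_zone[j]
      if (stage == "INP") {
        tr <- which(tissue$transcribed[, j])
        mu_or[tr, k] <- mu_or[tr, k] +
          params$inp_umi_per_propensity * prop[zone, tr]
      } else if (stage == "iOSN") {
        surv <- which(tissue$transcribed[, j] & !tissue$silenced[, j])
        mu_or[surv, k] <- mu_or[surv, k] +
          params$inp_umi_per_propensity * prop[zone, surv]
      } else if (stage == "mOSN") {
        surv <- which(tissue$transcribed[, j] & !tissue$silenced[, j])
        mu_or[surv, k] <- mu_or[surv, k] + params$basal_mean
        if (!is.na(chosen_idx[j])) {
          mu_or[chosen_idx[j], k] <-
            params$ambient + params$chosen_mean
        }
      }
    }
    # stage markers: high in the cell's own stage, low otherwise
    marker_mu <- vapply(cols, function(j) {
      ifelse(rep(stages, each = n_marker) == tissue$cells$stage[j], 40, 0.5)
    }, numeric(length(stages) * n_marker))
    marker_mu <- matrix(marker_mu, ncol = m)
    mu <- rbind(
      mu_or,
      matrix(hk_means + params$ambient, params$hk_genes, m),
      matrix(mito_means + params$ambient, params$mito_genes, m),
      marker_mu + params$ambient
    )
    x <- with_substream(
      rz_seed(seed, "counts", "draw", ci),
      matrix(stats::rpois(length(mu), mu), nrow(genes), m)
    )
    counts_chunks[[ci]] <- methods::as(
      methods::as(Matrix::Matrix(x, sparse = TRUE), "generalMatrix"),
      "CsparseMatrix"
    )
  }
  counts <- do.call(cbind, counts_chunks)
  dimnames(counts) <- list(genes$gene_id, tissue$cells$cell_id)
  cells <- tissue$cells |>
    mutate(origin = ifelse(.data$dv_zone <= 2, "dorsal", "ventral"))
  or_counts(counts, genes, cells)
}

#' Construct a single-cell count container
#'
#' @param counts Sparse (or dense) genes x cells count matrix with dimnames.
#' @param genes Gene metadata tibble with at least `gene_id`; `is_or` and
#'   `is_mito` flags are required by the QC and profiling functions.
#' @param cells Cell metadata tibble with at least `cell_id`.
#' @return An `or_counts` object.
#' @export
or_counts <- function(counts, genes, cells) {
  counts <- methods::as(
    methods::as(Matrix::Matrix(counts, sparse = TRUE), "generalMatrix"),
    "CsparseMatrix"
  )
  if (anyDuplicated(genes$gene_id) > 0) abort("gene ids must be unique")
  if (length(counts) > 0 && min(counts) < 0) {
    abort("counts must be non-negative")
  }
  stopifnot(nrow(counts) == nrow(genes), ncol(counts) == nrow(cells))
  dimnames(counts) <- list(genes$gene_id, cells$cell_id)
  structure(
    list(counts = counts, genes = as_tibble(genes), cells = as_tibble(cells)),
    class = "or_counts"
  )
}

#' @export
print.or_counts <- function(x, ...) {
  cat(sprintf(
    "<or_counts> %d genes x %d cells (%d OR genes, %.0f median UMIs/cell)\n",
    nrow(x$counts), ncol(x$counts), sum(x$genes$is_or),
    stats::median(Matrix::colSums(x$counts))
  ))
  invisible(x)
}

#' Write / read a count matrix as MTX + features + barcodes
#'
#' Plain-text MatrixMarket triplet plus `features.tsv` (gene metadata) and
#' `barcodes.tsv` (cell metadata), mirroring the common single-cell exchange
#' layout.
#'
#' @param x An `or_counts` object.
#' @param dir Directory to write into (created if needed).
#' @return The directory (write) or an `or_counts` object (read).
#' @export
write_counts_mtx <- function(x, dir) {
  stopifnot(inherits(x, "or_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  readr::write_tsv(x$genes, file.path(dir, "features.tsv"))
  readr::write_tsv(x$cells, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(dir) {
  counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readr::read_tsv(file.path(dir, "features.tsv"),
                           show_col_types = FALSE)
  cells <- readr::read_tsv(file.path(dir, "barcodes.tsv"),
                           show_col_types = FALSE)
  dimnames(counts) <- list(genes$gene_id, cells$cell_id)
  or_counts(counts, genes, cells)
}
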