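#' Quality-control filter for single cells
#'
#' Keeps cells with at least `min_genes` detected genes (>= 1 UMI), at least
#' `min_umi` total UMIs, and a mitochondrial UMI fraction strictly below
#' `max_mito` (inequalities as stated: "less than 1000 genes", "less than 5%
#' mitochondrial reads" are discarded).
#'
#' @param x An `or_counts` object with `is_mito` gene flags.
#' @param min_genes Minimum detected genes.
#' @param min_umi Minimum total UMIs.
#' @param max_mito Maximum mitochondrial fraction (exclusive).
#' @return A list with `counts` (the filtered `or_counts`) and `report`
#'   (tibble of per-criterion removal counts; a cell failing several criteria
#'   is counted under each).
#' @export
qc_filter_cells <- function(x, min_genes = 1000, min_umi = 20000,
                            max_mito = 0.05) {
  stopifnot(inherits(x, "or_counts"))
  if (!"is_mito" %in% names(x$genes)) {
    abort("gene metadata must carry an is_mito flag")
  }
  total <- Matrix::colSums(x$counts)
  genes_detected <- Matrix::colSums(x$counts > 0)
  mito <- Matrix::colSums(x$counts[x$genes$is_mito, , drop = FALSE])
  mito_frac <- ifelse(total > 0, mito / total, 0)
  fail_genes <- genes_detected < min_genes
  fail_umi <- total < min_umi
  fail_mito <- mito_frac >= max_mito
  keep <- !(fail_genes | fail_umi | fail_mito)
  if (!any(keep)) {
    warn("all cells removed by QC")
  }
  report <- tibble(
    criterion = c("min_genes", "min_umi", "max_mito", "any", "kept"),
    threshold = c(min_genes, min_umi, max_mito, NA, NA),
    n_cells = c(sum(fail_genes), sum(fail_umi), sum(fail_mito),
                sum(!keep), sum(keep))
  )
  filtered <- or_counts(
    x$counts[, keep, drop = FALSE],
    x$genes,
    x$cells[keep, , drop = FALSE]
  )
  list(counts = filtered, report = report)
}

#' Detect expressed ORs per cell
#'
#' An OR counts as expressed in a cell iff it has at least `min_umi` UMIs
#' (3 by default).
#'
#' @param x An `or_counts` object with `is_or` gene flags.
#' @param min_umi UMI threshold.
#' @return A tibble `cell_id, gene_id, umi` with one row per expressed OR.
#' @export
detect_expressed_ors <- function(x, min_umi = 3) {
  stopifnot(inherits(x, "or_counts"))
  if (!"is_or" %in% names(x$genes)) {
    abort("gene metadata must carry an is_or flag")
  }
  or_counts_mat <- x$counts[x$genes$is_or, , drop = FALSE]
  trip <- Matrix::summary(or_counts_mat)
  trip <- trip[trip$x >= min_umi, , drop = FALSE]
  tibble(
    cell_id = colnames(or_counts_mat)[trip$j],
    gene_id = rownames(or_counts_mat)[trip$i],
    umi = trip$x
  ) |>
    arrange(.data$cell_id, .data$gene_id)
}

#' Polygenic zonal OR profile per cell
#'
#' For each cell, the expressed OR set (>= `min_umi` UMIs), the dominant OR
#' (highest UMI; ties broken to the most dorsal zonal identity, then by gene
#' id), its zonal identity, and the zone composition of the expressed set.
#' The summary counts, relative to each cell's dissection origin (dorsal =
#' zones 1-2, ventral = zones 3-5), how many cells express at least one OR
#' of dorsal identity (more dorsal than the origin band) and at least one of
#' the origin band's own (ventral-identity for ventral cells) category.
#'
#' @param x An `or_counts` object; cells need an `origin` column (`dorsal` /
#'   `ventral`); cells without one are skipped with a warning.
#' @param annotation OR gene tibble with `gene_id, or_class, zone`.
#' @param min_umi Expression threshold per OR.
#' @return A list with `profiles` (per-cell tibble: `cell_id, origin,
#'   n_expressed, dominant_or, dominant_zone, zone_composition`
#'   (list-column)) and `summary` (per-origin counts of cells with
#'   dorsal-identity and with ventral-identity ORs).
#' @export
polygenic_zone_profile <- function(x, annotation, min_umi = 3) {
  stopifnot(inherits(x, "or_counts"))
  if (!"origin" %in% names(x$cells)) {
    abort("cell metadata must carry an origin column (dorsal/ventral)")
  }
  no_origin <- is.na(x$cells$origin)
  if (any(no_origin)) {
    warn(sprintf("skipping %d cell(s) without origin", sum(no_origin)))
  }
  lab <- tibble(
    gene_id = annotation$gene_id,
    zone_label = ifelse(annotation$or_class == "I", "I",
                        as.character(annotation$zone))
  )
  expressed <- detect_expressed_ors(x, min_umi) |>
    left_join(lab, by = "gene_id") |>
    left_join(
      x$cells |> select("cell_id", "origin"),
      by = "cell_id"
    ) |>
    filter(!is.na(.data$origin))
  levels_order <- zone_levels()
  profiles <- expressed |>
    group_by(.data$cell_id, .data$origin) |>
    summarise(
      n_expressed = dplyr::n(),
      dominant_or = {
        ord <- order(-.data$umi, match(.data$zone_label, levels_order),
                     .data$gene_id)
        .data$gene_id[ord][1]
      },
      dominant_zone = {
        ord <- order(-.data$umi, match(.data$zone_label, levels_order),
                     .data$gene_id)
        .data$zone_label[ord][1]
      },
      zone_composition = list(table(.data$zone_label)),
      .groups = "drop"
    )
  # origin-relative identity categories (class I grouped with zone 1)
  zone_num <- function(zl) {
    ifelse(zl == "I", 1L, suppressWarnings(as.integer(zl)))
  }
  expressed <- expressed |>
    mutate(
      z = zone_num(.data$zone_label),
      category = dplyr::case_when(
        .data$origin == "ventral" & .data$z <= 2 ~ "dorsal_identity",
        .data$origin == "ventral" & .data$z >= 3 ~ "ventral_identity",
        .data$origin == "dorsal" & .data$z <= 2 ~ "own_identity",
        TRUE ~ "ventral_identity"
      )
    )
  all_cells <- x$cells |>
    filter(!is.na(.data$origin)) |>
    select("cell_id", "origin")
  summary <- expressed |>
    group_by(.data$origin, .data$category) |>
    summarise(n_cells = dplyr::n_distinct(.data$cell_id), .groups = "drop") |>
    tidyr::pivot_wider(
      names_from = "category", values_from = "n_cells", values_fill = 0L
    ) |>
    left_join(
      all_cells |> count(.data$origin, name = "n_cells_total"),
      by = "origin"
    )
  list(profiles = profiles, summary = summary)
}

#' Assign differentiation stages from marker expression
#'
#' Scores each cell against user-supplied marker gene lists (mean of
#' depth-scaled log counts over each list) and assigns the stage with the
#' highest score — a deliberate simplification of graph-based clustering
#' followed by marker inspection.
#'
#' @param x An `or_counts` object.
#' @param markers Named list of marker gene-id vectors, one per stage.
#' @return Tibble `cell_id, stage, score` with one row per cell.
#' @export
assign_stage <- function(x, markers) {
  stopifnot(inherits(x, "or_counts"), length(markers) > 0)
  depth <- Matrix::colSums(x$counts)
  med <- stats::median(depth[depth > 0])
  scores <- vapply(markers, function(genes) {
    present <- intersect(genes, rownames(x$counts))
    if (length(present) == 0) {
      return(rep(0, ncol(x$counts)))
    }
    sub <- x$counts[present, , drop = FALSE]
    as.numeric(Matrix::colSums(log1p(
      sub %*% Matrix::Diagonal(x = ifelse(depth > 0, med / depth, 0))
    ))) / length(genes)
  }, numeric(ncol(x$counts)))
  scores <- matrix(scores, ncol = length(markers),
                   dimnames = list(NULL, names(markers)))
  best <- apply(scores, 1, which.max)
  tibble(
    cell_id = x$cells$cell_id,
    stage = names(markers)[best],
    score = scores[cbind(seq_len(nrow(scores)), best)]
  )
}

#' Threshold filter for a differential-expression table
#'
#' Applies conjunctive filters: adjusted p below `max_padj`, absolute fold
#' change of at least `min_fold`, and expression of at least `min_expr`;
#' optionally retains the `top_n` most significant genes (ordered by padj,
#' then decreasing |fold|, then gene id).
#'
#' @param de_table Tibble with `gene`, `log2fc` (or `fold`), `padj`, and an
#'   expression column (`expr`, `tpm` or `base_mean`).
#' @param min_fold Minimum fold change (linear scale, e.g. 3 for threefold).
#' @param max_padj Adjusted p-value cutoff (exclusive).
#' @param min_expr Minimum expression level.
#' @param top_n Optional cap on the number of returned genes.
#' @return The filtered, deterministically ordered table.
#' @export
threshold_de_table <- function(de_table, min_fold = 2, max_padj = 0.05,
                               min_expr = 0, top_n = NULL) {
  assert_columns(de_table, c("gene", "padj"), "DE table")
  if ("log2fc" %in% names(de_table)) {
    fold <- 2^abs(de_table$log2fc)
  } else if ("fold" %in% names(de_table)) {
    fold <- abs(de_table$fold)
  } else {
    abort("DE table needs a log2fc or fold column")
  }
  expr_col <- intersect(c("expr", "tpm", "base_mean"), names(de_table))
  if (length(expr_col) == 0) {
    abort("DE table needs an expression column (expr, tpm or base_mean)")
  }
  expr <- de_table[[expr_col[1]]]
  out <- de_table |>
    mutate(.fold = fold, .expr = expr) |>
    filter(
      .data$padj < max_padj,
      .data$.fold >= min_fold,
      .data$.expr >= min_expr
    ) |>
    arrange(.data$padj, dplyr::desc(.data$.fold), .data$gene) |>
    select(-".fold", -".expr")
  if (!is.null(top_n)) {
    out <- utils::head(out, top_n)
  }
  out
}
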