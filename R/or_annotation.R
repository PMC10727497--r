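#' Convert a continuous zonal index to an integer zone
#'
#' OR genes carry a continuous dorsoventral expression index on the 1 (dorsal)
#' to 5 (ventral) scale; the discrete zone is the nearest integer, with
#' half-integers rounded up (towards the ventral zone) so that the mapping is
#' deterministic and monotone.
#'
#' @param zonal_index Numeric vector of indices in `[1, 5]`.
#' @param gene_id Optional character vector of gene names used in error
#'   messages when an index is missing or out of range.
#' @return Integer vector of zones in `1:5`.
#' @examples
#' bin_zone(c(2.4, 1.0, 3.5))
#' @export
bin_zone <- function(zonal_index, gene_id = NULL) {
  bad <- is.na(zonal_index) | zonal_index < 1 | zonal_index > 5
  if (any(bad)) {
    offender <- if (!is.null(gene_id)) {
      paste(gene_id[bad], collapse = ", ")
    } else {
      paste(which(bad), collapse = ", ")
    }
    abort(sprintf(
      "zonal_index must be in [1, 5] and non-missing; offending gene(s): %s",
      offender
    ))
  }
  as.integer(floor(zonal_index + 0.5))
}

#' Read an OR annotation table
#'
#' Expects a TSV with header columns `gene_id, chrom, start, end, strand,
#' class, zonal_index, cluster_id`. Coordinates are 0-based half-open.
#' Class II genes with a zonal index get an integer `zone` via [bin_zone()];
#' class I genes and genes with missing indices keep `zone = NA`.
#'
#' @param path Path to the TSV file.
#' @return A tibble of OR genes with columns `gene_id, chrom, start, end,
#'   strand, or_class, zonal_index, zone, cluster_id`.
#' @export
read_or_annotation <- function(path) {
  genes <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(genes, c(
    "gene_id", "chrom", "start", "end", "strand",
    "class", "zonal_index", "cluster_id"
  ), "annotation table")
  genes <- genes |>
    rename(or_class = "class") |>
    mutate(
      start = as.integer(.data$start),
      end = as.integer(.data$end),
      zonal_index = as.numeric(.data$zonal_index)
    )
  validate_or_genes(genes)
  idx <- !is.na(genes$zonal_index)
  genes$zone <- NA_integer_
  genes$zone[idx] <- bin_zone(genes$zonal_index[idx], genes$gene_id[idx])
  dplyr::relocate(genes, "zone", .after = "zonal_index")
}

#' Write an OR annotation table (TSV) or BED6 export
#'
#' @param genes OR gene tibble as returned by [read_or_annotation()] or
#'   [build_genome()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_or_annotation <- function(genes, path) {
  out <- genes |>
    select(
      "gene_id", "chrom", "start", "end", "strand",
      class = "or_class", "zonal_index", "cluster_id"
    )
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_or_annotation
#' @export
write_or_bed <- function(genes, path) {
  bed <- genes |>
    mutate(score = ifelse(is.na(.data$zone), 0L, .data$zone)) |>
    select("chrom", "start", "end", name = "gene_id", "score", "strand")
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

validate_or_genes <- function(genes) {
  if (nrow(genes) == 0) {
    return(invisible(genes))
  }
  if (any(genes$start >= genes$end)) {
    abort("OR gene coordinates must satisfy start < end (0-based half-open)")
  }
  if (anyDuplicated(genes$gene_id) > 0) {
    abort("gene_id values must be unique")
  }
  if (!all(genes$or_class %in% c("I", "II"))) {
    abort("class must be 'I' or 'II'")
  }
  invisible(genes)
}

#' Census of the OR repertoire
#'
#' Counts the repertoire by category: total genes, class I genes, class II
#' genes per integer zone, and class II genes without a zonal annotation.
#' Class I ORs are counted as their own category and never against a numeric
#' zone, even though they are expressed within zone 1.
#'
#' @param genes OR gene tibble with `or_class` and `zone` columns.
#' @return A tibble with columns `category` (`total`, `class_I`, `zone_1` ...
#'   `zone_5`, `unannotated`) and `n`.
#' @export
zone_census <- function(genes) {
  zone_n <- function(z) {
    if (nrow(genes) == 0) {
      return(0L)
    }
    sum(genes$or_class == "II" & !is.na(genes$zone) & genes$zone == z)
  }
  tibble(
    category = c("total", "class_I", paste0("zone_", 1:5), "unannotated"),
    n = c(
      nrow(genes),
      if (nrow(genes) == 0) 0L else sum(genes$or_class == "I"),
      vapply(1:5, zone_n, integer(1)),
      if (nrow(genes) == 0) 0L else {
        sum(genes$or_class == "II" & is.na(genes$zone))
      }
    )
  )
}

# Zone label of a gene: "I" for class I, otherwise the integer zone as
# character. NA for class II genes without zone.
gene_zone_label <- function(genes) {
  ifelse(genes$or_class == "I", "I", as.character(genes$zone))
}

#' Annotate genomic bins by the zonal identity of residing ORs
#'
#' Tiles each chromosome into fixed-width bins and labels every bin that
#' overlaps at least one OR gene with the set of zonal identities of the
#' overlapping genes (class I ORs contribute the label `"I"`). The primary
#' zone of a bin is the most frequent label; ties are broken to the more
#' dorsal (numerically lower) zone, with class I outranked by numeric zones
#' on tied counts.
#'
#' @param genes OR gene tibble; class II genes must carry a `zone`.
#' @param resolution Bin width in bp (e.g. `50000`).
#' @return A tibble with one row per OR-overlapping bin: `chrom, start,
#'   resolution, zone_labels` (list-column of sorted label sets),
#'   `primary_zone`, and `n_or` (number of residing genes).
#' @export
annotate_bins <- function(genes, resolution) {
  stopifnot(resolution > 0)
  if (nrow(genes) == 0) {
    return(tibble(
      chrom = character(), start = integer(), resolution = integer(),
      zone_labels = list(), primary_zone = character(), n_or = integer()
    ))
  }
  label <- gene_zone_label(genes)
  if (anyNA(label)) {
    abort("annotate_bins() requires a zone for every class II gene")
  }
  # every bin overlapped by [start, end): bins floor(start/res) .. floor((end-1)/res)
  per_gene <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    b <- seq.int(
      genes$start[i] %/% resolution,
      (genes$end[i] - 1L) %/% resolution
    )
    tibble(chrom = genes$chrom[i], bin = b, label = label[i])
  })
  priority <- c(as.character(1:5), "I")
  per_gene |>
    group_by(.data$chrom, .data$bin) |>
    summarise(
      zone_labels = list(sort(unique(.data$label))),
      primary_zone = {
        counts <- table(.data$label)
        cand <- names(counts)[counts == max(counts)]
        cand[order(match(cand, priority))][1]
      },
      n_or = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(
      start = as.integer(.data$bin * resolution),
      resolution = as.integer(resolution)
    ) |>
    select(
      "chrom", "start", "resolution", "zone_labels", "primary_zone", "n_or"
    ) |>
    arrange(.data$chrom, .data$start)
}
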