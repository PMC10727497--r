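#' Construct a binned contact matrix
#'
#' Sparse upper-triangle storage of binned genomic contacts: a bin table
#' (`bin_id, chrom, start`) at fixed resolution and a pixel table
#' (`bin1, bin2, count`) with `bin1 <= bin2`; absent pixels are zeros.
#'
#' @param bins Tibble with `chrom, start` (bin starts, multiples of the
#'   resolution); a `bin_id` column is added if missing.
#' @param pixels Tibble with `bin1, bin2, count` (bin ids).
#' @param resolution Bin width in bp.
#' @param normalization `"raw"` or `"counts_per_billion"`.
#' @param total_raw Total raw contact count (with symmetric weighting);
#'   computed from the pixels when `NULL` and raw.
#' @return A `contact_matrix` object.
#' @export
contact_matrix <- function(bins, pixels, resolution,
                           normalization = "raw", total_raw = NULL) {
  assert_columns(bins, c("chrom", "start"), "bin table")
  assert_columns(pixels, c("bin1", "bin2", "count"), "pixel table")
  if (!"bin_id" %in% names(bins)) {
    bins$bin_id <- seq_len(nrow(bins))
  }
  if (any(pixels$count < 0)) abort("pixel counts must be non-negative")
  flip <- pixels$bin1 > pixels$bin2
  if (any(flip)) {
    tmp <- pixels$bin1[flip]
    pixels$bin1[flip] <- pixels$bin2[flip]
    pixels$bin2[flip] <- tmp
  }
  pixels <- pixels |>
    group_by(.data$bin1, .data$bin2) |>
    summarise(count = sum(.data$count), .groups = "drop")
  if (is.null(total_raw)) {
    total_raw <- sum(pixels$count * ifelse(pixels$bin1 == pixels$bin2, 1, 2))
  }
  structure(
    list(
      bins = as_tibble(bins) |>
        select("bin_id", "chrom", "start") |>
        arrange(.data$bin_id),
      pixels = as_tibble(pixels),
      resolution = as.integer(resolution),
      normalization = normalization,
      total_raw = as.numeric(total_raw)
    ),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf(
    "<contact_matrix> %d bins @ %d bp, %d pixels (%s; total raw %.4g)\n",
    nrow(x$bins), x$resolution, nrow(x$pixels), x$normalization, x$total_raw
  ))
  invisible(x)
}

#' Normalize a contact matrix to counts per billion
#'
#' Scales every pixel by `1e9 / total_raw`, where the total counts each
#' off-diagonal pixel twice (symmetric semantics), so that the symmetric sum
#' of normalized pixels equals 1e9.
#'
#' @param matrix A raw `contact_matrix`.
#' @return The normalized matrix.
#' @export
normalize_cpb <- function(matrix) {
  stopifnot(inherits(matrix, "contact_matrix"))
  if (matrix$normalization != "raw") {
    abort("contact matrix is already normalized (counts per billion)")
  }
  if (matrix$total_raw == 0) {
    abort("cannot normalize a contact matrix with zero total counts")
  }
  matrix$pixels$count <- matrix$pixels$count * 1e9 / matrix$total_raw
  matrix$normalization <- "counts_per_billion"
  matrix
}

#' Extract a dense cis contact block between two regions
#'
#' Aggregates pixels into a dense block at a requested (coarser) resolution
#' by summing the finer bins; the display copy is capped at `cap` for color
#' scaling while the raw block is returned untouched.
#'
#' @param matrix A normalized `contact_matrix`.
#' @param region_a,region_b Lists or one-row data frames with
#'   `chrom, start, end` on the same chromosome, non-overlapping.
#' @param resolution Target resolution (multiple of the matrix resolution).
#' @param cap Display cap (contacts per target bin).
#' @return List with `block` (raw dense matrix, rows = region A bins),
#'   `display` (capped copy), and the row/column bin starts.
#' @export
extract_cis_block <- function(matrix, region_a, region_b,
                              resolution = 100000, cap = 150) {
  stopifnot(inherits(matrix, "contact_matrix"))
  if (matrix$normalization == "raw") {
    abort("normalize the contact matrix before extracting blocks")
  }
  region_a <- as.list(region_a)
  region_b <- as.list(region_b)
  if (region_a$chrom != region_b$chrom) {
    abort("cis block regions must be on the same chromosome")
  }
  if (region_a$start < region_b$end && region_b$start < region_a$end) {
    abort("cis block regions must not overlap")
  }
  if (resolution %% matrix$resolution != 0) {
    abort("target resolution must be a multiple of the matrix resolution")
  }
  starts_of <- function(region) {
    seq.int(
      (region$start %/% resolution) * resolution,
      ((region$end - 1) %/% resolution) * resolution,
      by = resolution
    )
  }
  ra <- starts_of(region_a)
  rb <- starts_of(region_b)
  block <- matrix(0, length(ra), length(rb),
                  dimnames = list(ra, rb))
  bins <- matrix$bins |> filter(.data$chrom == region_a$chrom)
  coarse <- stats::setNames((bins$start %/% resolution) * resolution,
                            bins$bin_id)
  px <- matrix$pixels |>
    filter(.data$bin1 %in% bins$bin_id, .data$bin2 %in% bins$bin_id)
  if (nrow(px) > 0) {
    c1 <- coarse[as.character(px$bin1)]
    c2 <- coarse[as.character(px$bin2)]
    for (k in seq_len(nrow(px))) {
      pairs <- rbind(c(c1[k], c2[k]), c(c2[k], c1[k]))
      for (r in 1:2) {
        i <- match(pairs[r, 1], ra)
        j <- match(pairs[r, 2], rb)
        if (!is.na(i) && !is.na(j)) {
          block[i, j] <- block[i, j] + px$count[k]
          if (pairs[1, 1] == pairs[1, 2]) break # diagonal: add once
        }
      }
    }
  }
  list(
    block = block,
    display = pmin(block, cap),
    row_starts = ra,
    col_starts = rb,
    cap = cap
  )
}

#' Zone-pair aggregation of trans contacts between OR bins
#'
#' For every pair of class II zones (p, q), averages the contact counts over
#' all interchromosomal bin pairs in which one bin carries label p and the
#' other label q. Bins with mixed zonal constitution contribute to every
#' zone they carry (set `mode = "primary"` to count each bin only under its
#' primary zone); unobserved pixels count as zeros; class I labels are
#' excluded by default.
#'
#' @param matrix A normalized `contact_matrix`.
#' @param bins Zone-annotated bins from [annotate_bins()] at the matrix
#'   resolution.
#' @param exclude_class_i Drop the class I label from the aggregation.
#' @param mode `"all_labels"` (default) or `"primary"`.
#' @return A `zone_pair_map`: list with the 5x5 `map` (NA where no eligible
#'   pairs), `n_pairs`, and the aggregation settings.
#' @export
zone_pair_trans_map <- function(matrix, bins, exclude_class_i = TRUE,
                                mode = c("all_labels", "primary")) {
  stopifnot(inherits(matrix, "contact_matrix"))
  mode <- match.arg(mode)
  if (matrix$normalization == "raw") {
    abort("normalize the contact matrix before zone-pair aggregation")
  }
  if (any(bins$resolution != matrix$resolution)) {
    abort("annotated bins must match the contact matrix resolution")
  }
  zlabels <- zone_levels(include_class_i = !exclude_class_i)
  binkey <- matrix$bins |>
    mutate(key = paste(.data$chrom, .data$start))
  bins <- bins |>
    mutate(
      key = paste(.data$chrom, .data$start),
      bin_id = binkey$bin_id[match(.data$key, binkey$key)]
    )
  if (anyNA(bins$bin_id)) {
    abort("annotated bins not present in the contact matrix bin table")
  }
  # membership matrix over OR bins
  n_or <- nrow(bins)
  Z <- matrix(0, n_or, length(zlabels), dimnames = list(NULL, zlabels))
  for (i in seq_len(n_or)) {
    labs <- if (mode == "primary") {
      bins$primary_zone[i]
    } else {
      bins$zone_labels[[i]]
    }
    labs <- intersect(labs, zlabels)
    Z[i, labs] <- 1
  }
  # dense symmetric pixel matrix over OR bins (absent pixels are zeros)
  id2row <- stats::setNames(seq_len(n_or), bins$bin_id)
  px <- matrix$pixels |>
    filter(.data$bin1 %in% bins$bin_id, .data$bin2 %in% bins$bin_id)
  D <- matrix(0, n_or, n_or)
  if (nrow(px) > 0) {
    i <- id2row[as.character(px$bin1)]
    j <- id2row[as.character(px$bin2)]
    D[cbind(i, j)] <- px$count
    D[cbind(j, i)] <- px$count
  }
  trans <- outer(bins$chrom, bins$chrom, "!=") * 1
  num <- t(Z) %*% (D * trans) %*% Z
  cnt <- t(Z) %*% trans %*% Z
  if (all(cnt == 0)) {
    abort("no interchromosomal OR bin pairs available for aggregation")
  }
  map <- num / cnt
  map <- (map + t(map)) / 2 # exact symmetry regardless of summation order
  map[cnt == 0] <- NA_real_
  dimnames(map) <- dimnames(cnt) <- list(zlabels, zlabels)
  structure(
    list(
      map = map, n_pairs = cnt, mode = mode,
      exclude_class_i = exclude_class_i,
      resolution = matrix$resolution
    ),
    class = "zone_pair_map"
  )
}

#' @export
print.zone_pair_map <- function(x, ...) {
  cat(sprintf("<zone_pair_map> mean trans contacts by zone pair (@%d bp, %s)\n",
              x$resolution, x$mode))
  print(round(x$map, 3))
  invisible(x)
}

#' Write / read a contact matrix as bins + pixels TSV
#'
#' @param matrix A `contact_matrix`.
#' @param bins_path,pixels_path TSV paths.
#' @param resolution,normalization,total_raw Metadata for reading.
#' @return Paths (write) or a `contact_matrix` (read).
#' @export
write_contacts <- function(matrix, bins_path, pixels_path) {
  stopifnot(inherits(matrix, "contact_matrix"))
  readr::write_tsv(matrix$bins, bins_path)
  readr::write_tsv(matrix$pixels, pixels_path)
  invisible(c(bins_path, pixels_path))
}

#' @rdname write_contacts
#' @export
read_contacts <- function(bins_path, pixels_path, resolution,
                          normalization = "raw", total_raw = NULL) {
  bins <- readr::read_tsv(bins_path, show_col_types = FALSE)
  pixels <- readr::read_tsv(pixels_path, show_col_types = FALSE)
  contact_matrix(bins, pixels, resolution, normalization, total_raw)
}
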