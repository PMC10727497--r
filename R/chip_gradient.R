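#' Construct a coverage track
#'
#' A stepwise per-base coverage signal stored as non-overlapping runs
#' (`chrom, start, end, depth`, 0-based half-open); positions not covered by
#' a run have depth 0. Tracks are normalized to a library size of 10^7 reads
#' before densities are computed.
#'
#' @param runs Tibble with columns `chrom, start, end, depth`.
#' @param library_size Total reads of the underlying library.
#' @param normalized Has the 10^7/library_size factor been applied?
#' @return A `coverage_track` object.
#' @export
coverage_track <- function(runs, library_size, normalized = FALSE) {
  assert_columns(runs, c("chrom", "start", "end", "depth"), "coverage runs")
  if (any(runs$depth < 0)) abort("coverage depths must be non-negative")
  if (any(runs$start >= runs$end)) abort("runs must satisfy start < end")
  structure(
    list(
      runs = as_tibble(runs) |> arrange(.data$chrom, .data$start),
      library_size = as.numeric(library_size),
      normalized = isTRUE(normalized)
    ),
    class = "coverage_track"
  )
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "<coverage_track> %d runs on %d chromosome(s); library %g reads%s\n",
    nrow(x$runs), length(unique(x$runs$chrom)), x$library_size,
    if (x$normalized) " (normalized to 1e7)" else " (raw)"
  ))
  invisible(x)
}

#' Normalize a track to a library size of 10 million reads
#'
#' @param track A `coverage_track`.
#' @return The track with depths scaled by `1e7 / library_size`.
#' @export
normalize_track <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  if (track$normalized) abort("track is already normalized")
  track$runs$depth <- track$runs$depth * 1e7 / track$library_size
  track$normalized <- TRUE
  track
}

#' Read / write bedGraph coverage
#'
#' @param path bedGraph file (chrom, start, end, depth; no header).
#' @param library_size Library size to attach (bedGraph does not carry one).
#' @param normalized Whether the file already holds normalized depths.
#' @param track A `coverage_track` (for writing).
#' @return A `coverage_track` (read) or `path` (write).
#' @export
read_bedgraph <- function(path, library_size = 1e7, normalized = TRUE) {
  runs <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "depth"),
    show_col_types = FALSE
  )
  coverage_track(runs, library_size, normalized)
}

#' @rdname read_bedgraph
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  readr::write_tsv(track$runs, path, col_names = FALSE)
  invisible(path)
}

# Exact integral of the step function over [from, to) per chromosome.
# Vectorized over query intervals.
track_interval_sums <- function(track, chrom, from, to) {
  out <- numeric(length(chrom))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    runs <- track$runs[track$runs$chrom == ch, ]
    if (nrow(runs) == 0) next
    # cumulative integral at run breakpoints
    breaks <- c(runs$start[1], runs$end)
    widths <- runs$end - runs$start
    cum <- c(0, cumsum(widths * runs$depth))
    integral_at <- function(pos) {
      # integral of depth over [breaks[1], pos), clamped outside runs
      p <- pmin(pmax(pos, runs$start[1]), runs$end[nrow(runs)])
      k <- findInterval(p, c(runs$start[1], runs$end), left.open = FALSE)
      k <- pmin(pmax(k, 1L), nrow(runs) + 1L)
      base <- cum[k]
      inside <- k <= nrow(runs)
      extra <- numeric(length(p))
      # gap-aware partial run contribution
      within <- inside & p > runs$start[pmin(k, nrow(runs))]
      kk <- pmin(k, nrow(runs))
      extra[within] <- (pmin(p[within], runs$end[kk[within]]) -
                          runs$start[kk[within]]) * runs$depth[kk[within]]
      base + extra
    }
    out[idx] <- integral_at(to[idx]) - integral_at(from[idx])
  }
  out
}

#' Gene-body signal density
#'
#' Sum of normalized depth over the gene body `[start, end)` divided by gene
#' length, i.e. normalized reads per bp.
#'
#' @param track A normalized `coverage_track`.
#' @param genes OR gene tibble (any tibble with `gene_id, chrom, start, end`).
#' @return The input genes with a `density` column.
#' @export
gene_body_density <- function(track, genes) {
  stopifnot(inherits(track, "coverage_track"))
  if (!track$normalized) {
    abort("track must be normalized to 1e7 reads (see normalize_track())")
  }
  covered <- track$runs |>
    group_by(.data$chrom) |>
    summarise(lo = min(.data$start), hi = max(.data$end), .groups = "drop")
  chk <- genes |> left_join(covered, by = "chrom")
  outside <- is.na(chk$lo) | chk$start < chk$lo | chk$end > chk$hi
  if (any(outside)) {
    abort(sprintf(
      "gene(s) outside the track extent: %s",
      paste(genes$gene_id[outside], collapse = ", ")
    ))
  }
  genes |>
    mutate(density = track_interval_sums(
      track, .data$chrom, .data$start, .data$end
    ) / (.data$end - .data$start))
}

#' Scaled metagene matrix over gene bodies with unscaled flanks
#'
#' Each gene body is rescaled to `body_len` bp, `flank` bp are appended
#' unscaled on both sides, minus-strand genes are reversed, and the profile
#' is averaged into `n_bins` equal-width columns. Rows are ordered by
#' (zone label, gene id).
#'
#' @param track A normalized `coverage_track`.
#' @param genes Gene tibble with `gene_id, chrom, start, end, strand` (and
#'   optionally `zone`/`or_class` for row ordering).
#' @param body_len Target body length in bp.
#' @param flank Flank length in bp on each side.
#' @param n_bins Number of matrix columns.
#' @return A numeric matrix (genes x bins) with bin-offset column names and a
#'   `bin_breaks` attribute; class `metagene_matrix`.
#' @export
scaled_metagene_matrix <- function(track, genes, body_len = 6000,
                                   flank = 2000, n_bins = 100) {
  stopifnot(inherits(track, "coverage_track"))
  if (!track$normalized) {
    abort("track must be normalized to 1e7 reads (see normalize_track())")
  }
  assert_columns(genes, c("gene_id", "chrom", "start", "end", "strand"))
  total <- body_len + 2 * flank
  breaks <- seq(0, total, length.out = n_bins + 1) - flank
  if (all(c("or_class", "zone") %in% names(genes))) {
    genes <- genes |>
      arrange(match(gene_zone_label(genes), zone_levels()), .data$gene_id)
  } else {
    genes <- genes |> arrange(.data$gene_id)
  }
  mat <- matrix(0, nrow(genes), n_bins,
                dimnames = list(genes$gene_id, sprintf("%.0f", utils::head(
                  breaks, -1
                ) + diff(breaks) / 2)))
  for (i in seq_len(nrow(genes))) {
    glen <- genes$end[i] - genes$start[i]
    if (glen < 2 * total / n_bins) {
      warn(sprintf("gene %s body is shorter than two bins; interpolating",
                   genes$gene_id[i]))
    }
    # map metagene coordinate (relative to 5' end, body scaled to body_len)
    # back to genomic coordinates
    to_genomic <- function(u) {
      # u in [-flank, body_len + flank]
      g <- ifelse(
        u < 0, u,
        ifelse(u <= body_len, u * glen / body_len,
               glen + (u - body_len))
      )
      if (genes$strand[i] == "+") genes$start[i] + g else genes$end[i] - g
    }
    b <- to_genomic(breaks)
    lo <- pmin(utils::head(b, -1), b[-1])
    hi <- pmax(utils::head(b, -1), b[-1])
    sums <- track_interval_sums(
      track, rep(genes$chrom[i], n_bins), lo, hi
    )
    mat[i, ] <- sums / pmax(hi - lo, 1e-9)
  }
  attr(mat, "bin_breaks") <- breaks
  attr(mat, "body_len") <- body_len
  attr(mat, "flank") <- flank
  class(mat) <- c("metagene_matrix", class(mat))
  mat
}

#' Write a metagene matrix as TSV with a header of bin offsets
#'
#' @param mat A `metagene_matrix`.
#' @param path Output path.
#' @export
write_metagene_tsv <- function(mat, path) {
  df <- as_tibble(as.data.frame(unclass(mat)), .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble(gene_id = rownames(mat)), df)
  readr::write_tsv(df, path)
  invisible(path)
}

#' Dorsoventral gradient statistic for gene-body densities
#'
#' Quantifies the monotone trend of class II OR gene-body density across
#' zones 1-5 by rank correlation (Spearman by default), with a permutation
#' null obtained by shuffling zone labels. Class I ORs are excluded (their
#' densities form a separate near-zero category).
#'
#' @param table Density table with `gene_id, zone, or_class, density` (as
#'   from [gene_body_density()] on an annotated gene set).
#' @param n_perm Number of label permutations for the p-value.
#' @param method Rank-correlation flavour: `"spearman"` or `"kendall"`.
#' @param seed Seed for the permutation stream.
#' @return A `zonal_trend` object: list with `trend`, `p_value`, per-zone
#'   summaries, the statistic used and the permutation count.
#' @export
zonal_gradient_stat <- function(table, n_perm = 10000,
                                method = c("spearman", "kendall"),
                                seed = 1L) {
  method <- match.arg(method)
  assert_columns(table, c("zone", "density"))
  if ("or_class" %in% names(table)) {
    table <- table |> filter(.data$or_class == "II")
  }
  table <- table |> filter(!is.na(.data$zone))
  zones <- unique(table$zone)
  if (length(zones) < 2) {
    abort("zonal_gradient_stat() needs densities from at least 2 zones")
  }
  x <- as.numeric(table$zone)
  y <- table$density
  # constant densities have no rank trend: treat the undefined correlation
  # (zero variance) as 0 rather than warning
  safe_cor <- function(a, b) {
    r <- suppressWarnings(stats::cor(a, b, method = method))
    if (is.na(r)) 0 else r
  }
  trend <- safe_cor(x, y)
  perm <- with_substream(rz_seed(seed, "trend-perm"), {
    vapply(seq_len(n_perm), function(i) {
      safe_cor(x, y[sample.int(length(y))])
    }, numeric(1))
  })
  p <- (1 + sum(abs(perm) >= abs(trend))) / (n_perm + 1)
  summaries <- table |>
    group_by(.data$zone) |>
    summarise(
      n = dplyr::n(),
      mean_density = mean(.data$density),
      median_density = stats::median(.data$density),
      .groups = "drop"
    )
  structure(
    list(
      trend = trend, p_value = p, per_zone = summaries,
      method = method, n_perm = n_perm, n_genes = nrow(table)
    ),
    class = "zonal_trend"
  )
}

#' @export
print.zonal_trend <- function(x, ...) {
  cat(sprintf(
    "<zonal_trend> %s rank correlation = %.3f (permutation p = %.2g, %d genes)\n",
    x$method, x$trend, x$p_value, x$n_genes
  ))
  invisible(x)
}

#' Recover silencing-gradient parameters from emitted ChIP densities
#'
#' Fits the silencing model to per-gene class II densities pooled across
#' tissues of several zones by nonlinear least squares on the log scale
#' (the emission noise is multiplicative lognormal, so log residuals are
#' homoskedastic):
#' `density = gain * p_t(z_o) * sigma(d) * escape(z_o) + background`, with
#' `sigma(d) = sil_own + (1 - sil_own)(1 - exp(-sil_shape * d))`,
#' `d = z_cell - z_gene >= 0`. Transcription probabilities and the escape
#' term are computed from the known transcription parameters; `sil_own`,
#' `sil_shape` and the gain are estimated.
#'
#' @param densities Table with columns `gene_id, zone, or_class, density,
#'   tissue_zone` — per-gene densities from [emit_chip_coverage()] over
#'   tissues of at least 3 zones, with `tissue_zone` identifying the tissue.
#' @param params The [rheostat_params()] holding the transcription model
#'   (`base_rate`, `promoter_strength`, `escape_scale`, `chip_background`).
#' @return A `silencing_fit` object with elements `estimates` (tibble of
#'   `term, estimate, truth` when available) and the `nls` fit.
#' @export
fit_silencing_gradient <- function(densities, params) {
  assert_columns(densities, c("zone", "or_class", "density", "tissue_zone"))
  df <- densities |>
    filter(.data$or_class == "II", !is.na(.data$zone),
           .data$zone <= .data$tissue_zone) |>
    mutate(
      d = .data$tissue_zone - .data$zone,
      p_t = 1 - exp(-params$base_rate *
                      params$promoter_strength[.data$zone]),
      esc = exp(-params$base_rate * params$promoter_strength[.data$zone] /
                  params$escape_scale)
    )
  if (length(unique(df$tissue_zone)) < 3) {
    abort("fit_silencing_gradient() needs tissues from at least 3 zones")
  }
  bg <- params$chip_background
  df$log_density <- log(pmax(df$density, 1e-12))
  start <- list(
    gain = max(df$density) / max(df$p_t),
    sil_own = 0.5,
    sil_shape = 1
  )
  fit <- minpack.lm::nlsLM(
    log_density ~ log(gain * p_t *
      (sil_own + (1 - sil_own) * (1 - exp(-sil_shape * d))) * esc + bg),
    data = df,
    start = start,
    lower = c(gain = 1e-8, sil_own = 0, sil_shape = 1e-6),
    upper = c(gain = Inf, sil_own = 1, sil_shape = 50),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- stats::coef(fit)
  structure(
    list(
      estimates = tibble(
        term = names(est),
        estimate = as.numeric(est)
      ),
      fit = fit,
      n = nrow(df)
    ),
    class = "silencing_fit"
  )
}

#' @export
print.silencing_fit <- function(x, ...) {
  cat("<silencing_fit>\n")
  print(x$estimates)
  invisible(x)
}
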