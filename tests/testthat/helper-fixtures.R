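# Small repertoire for fast unit tests; full defaults are exercised in the
# acceptance suite.
small_params <- function(seed = 1L, ...) {
  rheostat_params(
    n_class_i = 6L,
    n_per_zone = c(12L, 12L, 10L, 8L, 6L),
    n_clusters = 4L,
    n_chromosomes = 2L,
    base_rate = 0.4, # keeps progenitor repertoire breadth at the small scale
    hk_genes = 60L,
    hk_total = 600,
    mito_genes = 5L,
    seed = seed,
    ...
  )
}

# Hand-built or_counts with explicit OR/mito flags.
toy_counts <- function(counts, or_flags, mito_flags = rep(FALSE, nrow(counts)),
                       origin = NULL) {
  genes <- tibble::tibble(
    gene_id = rownames(counts),
    is_or = or_flags,
    is_mito = mito_flags
  )
  cells <- tibble::tibble(cell_id = colnames(counts))
  if (!is.null(origin)) cells$origin <- origin
  or_counts(counts, genes, cells)
}

# Brute-force interval-overlap bin annotation (oracle for annotate_bins).
brute_annotate_bins <- function(genes, resolution) {
  label <- ifelse(genes$or_class == "I", "I", as.character(genes$zone))
  out <- list()
  for (ch in unique(genes$chrom)) {
    idx <- which(genes$chrom == ch)
    max_end <- max(genes$end[idx])
    for (b in 0:(max_end %/% resolution)) {
      lo <- b * resolution
      hi <- lo + resolution
      res <- which(genes$chrom == ch & genes$start < hi & genes$end > lo)
      if (length(res) == 0) next
      out[[length(out) + 1L]] <- tibble::tibble(
        chrom = ch, start = as.integer(lo),
        labels = list(sort(unique(label[res]))),
        n_or = length(res)
      )
    }
  }
  dplyr::bind_rows(out) |> dplyr::arrange(chrom, start)
}

# Brute-force connected components over a proximity graph (oracle for
# or_aggregates), on arbitrary bead coordinates.
brute_components <- function(xyz, ids, chroms, radius, include_cis = FALSE) {
  n <- nrow(xyz)
  adj <- as.matrix(stats::dist(xyz)) <= radius
  diag(adj) <- FALSE
  if (!include_cis) adj[outer(chroms, chroms, "==")] <- FALSE
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      nb <- which(adj[i, ])
      if (length(nb) > 0 && any(comp[nb] != comp[i])) {
        newc <- min(comp[c(i, nb)])
        comp[c(i, nb)] <- newc
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(ids, comp)
}

# Brute-force zone-pair trans aggregation (oracle for zone_pair_trans_map).
brute_zone_pair_map <- function(matrix, bins) {
  key <- paste(matrix$bins$chrom, matrix$bins$start)
  bins$bin_id <- matrix$bins$bin_id[match(paste(bins$chrom, bins$start), key)]
  px_key <- paste(matrix$pixels$bin1, matrix$pixels$bin2)
  lookup <- function(i, j) {
    v <- matrix$pixels$count[match(paste(min(i, j), max(i, j)), px_key)]
    if (is.na(v)) 0 else v
  }
  map <- num <- cnt <- matrix(0, 5, 5, dimnames = list(1:5, 1:5))
  for (a in seq_len(nrow(bins))) {
    for (b in seq_len(nrow(bins))) {
      if (bins$chrom[a] == bins$chrom[b]) next
      for (p in intersect(bins$zone_labels[[a]], as.character(1:5))) {
        for (q in intersect(bins$zone_labels[[b]], as.character(1:5))) {
          num[p, q] <- num[p, q] + lookup(bins$bin_id[a], bins$bin_id[b])
          cnt[p, q] <- cnt[p, q] + 1
        }
      }
    }
  }
  map <- num / cnt
  map[cnt == 0] <- NA_real_
  map
}

# Per-base track integral (oracle for gene_body_density / metagene), on a
# fine grid to handle fractional boundaries.
brute_interval_mean <- function(track, chrom, from, to, step = 0.05) {
  grid <- seq(from + step / 2, to - step / 2, by = step)
  depth <- vapply(grid, function(pos) {
    r <- track$runs[track$runs$chrom == chrom &
                      track$runs$start <= pos & track$runs$end > pos, ]
    if (nrow(r) == 0) 0 else r$depth[1]
  }, numeric(1))
  mean(depth)
}
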