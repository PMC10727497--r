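#' Build a synthetic OR genome
#'
#' Places the parameterized OR repertoire (class I genes plus class II genes
#' of zones 1-5) into contiguous genomic clusters distributed across at least
#' two synthetic chromosomes. Gene identities are dealt randomly into
#' clusters, so clusters have mixed zonal constitution (at least two zonal
#' categories each, enforced); class II genes receive a continuous zonal
#' index drawn within their zone's rounding interval, and the integer zone is
#' recomputed from it with [bin_zone()].
#'
#' @param params A [rheostat_params()] object.
#' @param seed Seed for the genome substream (default: derived from
#'   `params$seed`). The census is a function of `params` only; coordinates
#'   and indices change with the seed.
#' @return A tibble of OR genes (`gene_id, chrom, start, end, strand,
#'   or_class, zonal_index, zone, cluster_id`) with a `chrom_sizes` attribute
#'   (named integer vector of synthetic chromosome lengths).
#' @export
build_genome <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "rheostat_params"))
  n_total <- params$n_class_i + sum(params$n_per_zone)
  if (n_total == 0) {
    abort("the parameterized repertoire contains zero OR genes")
  }
  n_clusters <- max(1L, min(params$n_clusters, n_total %/% 2L))
  with_substream(rz_seed(seed, "genome"), {
    zone_of <- c(
      rep(NA_integer_, params$n_class_i),
      rep(1:5, times = params$n_per_zone)
    )
    class_of <- c(
      rep("I", params$n_class_i),
      rep("II", sum(params$n_per_zone))
    )
    ord <- sample.int(n_total)
    zone_of <- zone_of[ord]
    class_of <- class_of[ord]
    category <- ifelse(class_of == "I", "I", as.character(zone_of))
    cluster <- rep_len(seq_len(n_clusters), n_total)

    # every cluster must mix at least two zonal categories: swap genes of
    # differing category between a uniform cluster and another cluster,
    # repeating until no cluster is uniform
    if (n_clusters > 1 && length(unique(category)) > 1) {
      for (pass in 1:100) {
        uniform <- which(vapply(
          seq_len(n_clusters),
          function(cl) length(unique(category[cluster == cl])) < 2,
          logical(1)
        ))
        if (length(uniform) == 0) break
        cl <- uniform[1]
        give <- which(cluster == cl)[1]
        take <- which(cluster != cl & category != category[give])[1]
        tmp <- cluster[give]
        cluster[give] <- cluster[take]
        cluster[take] <- tmp
      }
    }

    # genomic layout: clusters dealt round-robin onto chromosomes, laid out
    # left to right with multi-megabase gaps between clusters
    chrom_of_cluster <- rep_len(seq_len(params$n_chromosomes), n_clusters)
    genes <- vector("list", n_clusters)
    chrom_cursor <- rep(1e6, params$n_chromosomes) # leading gap
    for (cl in seq_len(n_clusters)) {
      idx <- which(cluster == cl)
      idx <- idx[sample.int(length(idx))]
      chrom <- chrom_of_cluster[cl]
      pos <- chrom_cursor[chrom]
      len <- round(stats::runif(length(idx), 1000, 8000))
      gap <- round(stats::runif(length(idx), 5000, 40000))
      start <- pos + cumsum(gap) - gap + c(0, cumsum(len))[seq_along(idx)]
      end <- start + len
      genes[[cl]] <- tibble(
        idx = idx,
        chrom = paste0("chrS", chrom),
        start = as.integer(start),
        end = as.integer(end),
        strand = sample(c("+", "-"), length(idx), replace = TRUE),
        cluster_id = sprintf("cl%02d", cl)
      )
      chrom_cursor[chrom] <- max(end) + round(stats::runif(1, 2e6, 8e6))
    }
    genes <- bind_rows(genes) |> arrange(.data$idx)
    genes$or_class <- class_of
    lo <- pmax(1, zone_of - 0.5)
    hi <- pmin(5, zone_of + 0.5)
    genes$zonal_index <- NA_real_
    has_zone <- !is.na(zone_of)
    genes$zonal_index[has_zone] <-
      stats::runif(sum(has_zone), lo[has_zone], hi[has_zone])
    genes$zone <- NA_integer_
    ok <- !is.na(genes$zonal_index)
    genes$zone[ok] <- bin_zone(genes$zonal_index[ok])
    genes$gene_id <- sprintf(
      "Or%s-%04d", ifelse(class_of == "I", "1", "2"), seq_len(n_total)
    )
    genes <- genes |>
      select(
        "gene_id", "chrom", "start", "end", "strand",
        "or_class", "zonal_index", "zone", "cluster_id"
      )
    sizes <- genes |>
      group_by(.data$chrom) |>
      summarise(size = max(.data$end) + 1e6, .groups = "drop")
    all_chroms <- paste0("chrS", seq_len(params$n_chromosomes))
    chrom_sizes <- stats::setNames(rep(2e6, length(all_chroms)), all_chroms)
    chrom_sizes[sizes$chrom] <- sizes$size
    attr(genes, "chrom_sizes") <- chrom_sizes
    genes
  })
}

#' Chromosome sizes of a synthetic genome
#'
#' @param genome A genome tibble from [build_genome()].
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
chrom_sizes <- function(genome) {
  sizes <- attr(genome, "chrom_sizes")
  if (is.null(sizes)) {
    sizes <- genome |>
      group_by(.data$chrom) |>
      summarise(size = max(.data$end) + 1e6, .groups = "drop")
    sizes <- stats::setNames(sizes$size, sizes$chrom)
  }
  sizes
}
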