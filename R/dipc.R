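#' Construct a haplotype-resolved 3D genome structure
#'
#' Bead coordinates of a single-cell 3D genome model: one bead every
#' `bead_bp` bp per haplotype-chromosome (named like `chrS1(mat)`), with
#' coordinates in particle-radius units.
#'
#' @param beads Tibble with `chrom_hap, pos, x, y, z`.
#' @param cell_id Optional cell identifier.
#' @return A `structure_3d` object.
#' @export
structure_3d <- function(beads, cell_id = NA_character_) {
  assert_columns(beads, c("chrom_hap", "pos", "x", "y", "z"), "bead table")
  if (anyDuplicated(beads[, c("chrom_hap", "pos")]) > 0) {
    abort("duplicate (chrom_hap, pos) bead keys")
  }
  if (!all(is.finite(beads$x) & is.finite(beads$y) & is.finite(beads$z))) {
    abort("bead coordinates must be finite")
  }
  structure(
    list(beads = as_tibble(beads), cell_id = cell_id),
    class = "structure_3d"
  )
}

#' @export
print.structure_3d <- function(x, ...) {
  cat(sprintf(
    "<structure_3d> %s: %d beads on %d haplotype-chromosomes\n",
    x$cell_id %||% "?", nrow(x$beads), length(unique(x$beads$chrom_hap))
  ))
  invisible(x)
}

#' Read / write .3dg structure files
#'
#' Whitespace-delimited text: haplotype-chromosome, genomic position, x, y, z.
#'
#' @param path File path.
#' @param structure A `structure_3d` (for writing).
#' @param cell_id Cell id to attach on read.
#' @return A `structure_3d` (read) or `path` (write).
#' @export
read_3dg <- function(path, cell_id = NA_character_) {
  beads <- utils::read.table(
    path,
    col.names = c("chrom_hap", "pos", "x", "y", "z"),
    colClasses = c("character", "integer", "numeric", "numeric", "numeric")
  )
  structure_3d(as_tibble(beads), cell_id)
}

#' @rdname read_3dg
#' @export
write_3dg <- function(structure, path) {
  stopifnot(inherits(structure, "structure_3d"))
  utils::write.table(
    structure$beads, path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

# Resolve loci (gene midpoints) to the nearest bead on each haplotype of
# their chromosome. Returns a tibble with one row per (locus, haplotype).
resolve_loci <- function(structure, loci) {
  assert_columns(loci, c("gene_id", "chrom"), "locus table")
  if (!"pos" %in% names(loci)) {
    loci$pos <- (loci$start + loci$end) / 2
  }
  beads <- structure$beads |>
    mutate(base_chrom = sub("\\(.*\\)$", "", .data$chrom_hap))
  resolved <- character(0)
  out <- list()
  for (hap in split(beads, beads$chrom_hap)) {
    idx <- which(loci$chrom == hap$base_chrom[1])
    if (length(idx) == 0) next
    ord <- order(hap$pos)
    hap <- hap[ord, ]
    # nearest bead by position: boundary between bead k and k+1 is their mid
    mid <- (utils::head(hap$pos, -1) + hap$pos[-1]) / 2
    k <- findInterval(loci$pos[idx], mid) + 1L
    out[[length(out) + 1L]] <- tibble(
      gene_id = loci$gene_id[idx],
      chrom_hap = hap$chrom_hap[1],
      bead_id = paste0(loci$gene_id[idx], "|", hap$chrom_hap[1]),
      x = hap$x[k], y = hap$y[k], z = hap$z[k]
    )
    resolved <- c(resolved, loci$gene_id[idx])
  }
  missing <- setdiff(loci$gene_id, resolved)
  if (length(missing) > 0) {
    abort(sprintf(
      "locus/loci not on any structure chromosome: %s",
      paste(missing, collapse = ", ")
    ))
  }
  out <- bind_rows(out) |> arrange(.data$gene_id, .data$chrom_hap)
  out
}

#' Pairwise Euclidean distances between OR loci in a 3D structure
#'
#' Loci are resolved to the nearest bead by genomic position on each
#' haplotype of their chromosome, so a locus present on two haplotypes
#' yields two rows with suffixed identifiers.
#'
#' @param structure A `structure_3d`.
#' @param loci Tibble with `gene_id, chrom` and either `pos` or
#'   `start`/`end` (midpoint used); a genome tibble works directly.
#' @return A symmetric distance matrix (zero diagonal) with
#'   `gene|haplotype-chromosome` dimnames.
#' @export
pairwise_distances <- function(structure, loci) {
  stopifnot(inherits(structure, "structure_3d"))
  res <- resolve_loci(structure, loci)
  xyz <- as.matrix(res[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  dimnames(d) <- list(res$bead_id, res$bead_id)
  d
}

#' Call OR aggregates (compartments) in a single-cell structure
#'
#' Builds a proximity graph over OR loci (edge iff Euclidean distance is at
#' most `radius` particle radii) and returns its connected components of at
#' least `min_size` loci. By default only interchromosomal edges are used,
#' since OR compartments are multi-chromosomal and backbone neighbors are
#' trivially proximal; `include_cis = TRUE` admits same-chromosome edges.
#'
#' @param structure A `structure_3d`.
#' @param or_loci OR locus table (e.g. the genome tibble); `zone`/`or_class`
#'   columns, when present, drive the per-zone composition summary.
#' @param radius Proximity radius in particle radii.
#' @param min_size Minimum component size to call an aggregate.
#' @param include_cis Allow same-chromosome proximity edges.
#' @return An `aggregate_set`: list with `components` (list of bead-id
#'   vectors), `sizes`, `n_chromosomes` per aggregate, `membership` (tibble
#'   of all resolved loci with their aggregate), `zone_fraction` (per zonal
#'   category, fraction of loci inside any aggregate), and the call settings.
#' @export
or_aggregates <- function(structure, or_loci, radius = 10, min_size = 2,
                          include_cis = FALSE) {
  stopifnot(inherits(structure, "structure_3d"), radius > 0)
  res <- resolve_loci(structure, or_loci)
  n <- nrow(res)
  d <- as.matrix(stats::dist(as.matrix(res[, c("x", "y", "z")])))
  adj <- d <= radius
  diag(adj) <- FALSE
  if (!include_cis) {
    same <- outer(res$chrom_hap, res$chrom_hap, "==")
    adj[same] <- FALSE
  }
  # connected components by breadth-first search
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  sizes_all <- tabulate(comp)
  keep <- which(sizes_all >= min_size)
  components <- lapply(keep, function(k) res$bead_id[comp == k])
  membership <- res |>
    mutate(
      aggregate = match(comp, keep),
      in_aggregate = !is.na(.data$aggregate)
    )
  zone_fraction <- NULL
  if (all(c("zone", "or_class") %in% names(or_loci))) {
    lab <- tibble(
      gene_id = or_loci$gene_id,
      zone_label = ifelse(or_loci$or_class == "I", "I",
                          as.character(or_loci$zone))
    )
    zone_fraction <- membership |>
      left_join(lab, by = "gene_id") |>
      group_by(.data$zone_label) |>
      summarise(
        n_loci = dplyr::n(),
        fraction_in_aggregate = mean(.data$in_aggregate),
        .groups = "drop"
      )
  }
  structure(
    list(
      components = components,
      sizes = lengths(components),
      n_chromosomes = vapply(
        components,
        function(ids) length(unique(sub("^.*\\|", "", ids))),
        integer(1)
      ),
      membership = membership,
      zone_fraction = zone_fraction,
      radius = radius,
      min_size = min_size,
      include_cis = include_cis,
      cell_id = structure$cell_id
    ),
    class = "aggregate_set"
  )
}

#' @export
print.aggregate_set <- function(x, ...) {
  cat(sprintf(
    "<aggregate_set> %s: %d aggregate(s) at radius %g (sizes: %s)\n",
    x$cell_id %||% "?", length(x$components), x$radius,
    if (length(x$sizes)) paste(sort(x$sizes, decreasing = TRUE),
                               collapse = ", ") else "-"
  ))
  invisible(x)
}

#' Single-cell OR contact density
#'
#' Fraction of eligible haplotype-resolved locus pairs supported by at least
#' the observed contacts: the number of contacts whose two ends both fall
#' within `neighborhood` bp of a group locus (on the matching chromosome,
#' haplotypes matched when the contact is haplotype-resolved), normalized by
#' the number of distinct locus pairs.
#'
#' @param cell_contacts Tibble of contacts: `chrom_a, pos_a, chrom_b, pos_b`
#'   (chromosome names may carry `(mat)`/`(pat)` haplotype suffixes).
#' @param group_loci Locus table with `gene_id, chrom` and `pos` (or
#'   `start`/`end`).
#' @param neighborhood Window around each locus in bp.
#' @param haplotypes Haplotype suffixes assumed when expanding loci.
#' @return Contact density (contacts per eligible locus pair).
#' @export
contact_density <- function(cell_contacts, group_loci, neighborhood = 20000,
                            haplotypes = c("(mat)", "(pat)")) {
  assert_columns(cell_contacts, c("chrom_a", "pos_a", "chrom_b", "pos_b"))
  if (!"pos" %in% names(group_loci)) {
    group_loci$pos <- (group_loci$start + group_loci$end) / 2
  }
  loci <- purrr::map_dfr(haplotypes, function(h) {
    tibble(
      chrom_hap = paste0(group_loci$chrom, h),
      pos = group_loci$pos
    )
  })
  n_loci <- nrow(loci)
  n_pairs <- n_loci * (n_loci - 1) / 2
  if (n_pairs == 0) {
    warn("fewer than two group loci; density is 0")
    return(0)
  }
  if (nrow(cell_contacts) == 0) {
    warn("empty contact list; density is 0")
    return(0)
  }
  near_locus <- function(chrom, pos) {
    out <- logical(length(chrom))
    for (ch in unique(chrom)) {
      lp <- sort(loci$pos[loci$chrom_hap == ch])
      idx <- which(chrom == ch)
      if (length(lp) == 0) next
      k <- findInterval(pos[idx], lp)
      lo <- pmax(k, 1L)
      hi <- pmin(k + 1L, length(lp))
      out[idx] <- (abs(pos[idx] - lp[lo]) <= neighborhood) |
        (abs(pos[idx] - lp[hi]) <= neighborhood)
    }
    out
  }
  hits <- near_locus(cell_contacts$chrom_a, cell_contacts$pos_a) &
    near_locus(cell_contacts$chrom_b, cell_contacts$pos_b)
  sum(hits) / n_pairs
}

#' Quality filter on single-cell contact counts
#'
#' @param contact_lists Named list of per-cell contact tibbles.
#' @param min_contacts Minimum contacts per cell.
#' @return The retained list, with a message on removals.
#' @export
filter_cells_by_contacts <- function(contact_lists, min_contacts = 20000) {
  n <- vapply(contact_lists, nrow, integer(1))
  keep <- n >= min_contacts
  if (any(!keep)) {
    message(sprintf("removed %d cell(s) with < %d contacts",
                    sum(!keep), min_contacts))
  }
  contact_lists[keep]
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Exact two-sided p by full enumeration when the smaller group has at most
#' 8 observations and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction. U is reported for the
#' first group.
#'
#' @param group_a,group_b Numeric vectors.
#' @return A `rank_sum` object: list with `U`, `p_value`, `method`.
#' @export
rank_sum_test <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be non-empty")
  }
  na <- length(group_a)
  nb <- length(group_b)
  pooled <- c(group_a, group_b)
  if (length(unique(pooled)) == 1) {
    return(structure(
      list(U = na * nb / 2, p_value = 1, method = "degenerate"),
      class = "rank_sum"
    ))
  }
  r <- rank(pooled)
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- any(duplicated(pooled))
  if (min(na, nb) <= 8 && !ties) {
    combos <- utils::combn(na + nb, na)
    u_all <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    mid <- na * nb / 2
    p <- mean(abs(u_all - mid) >= abs(u_a - mid))
    method <- "exact enumeration"
  } else {
    n <- na + nb
    tie_tab <- table(pooled)
    mu <- na * nb / 2
    sigma2 <- na * nb / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    z <- (u_a - mu - sign(u_a - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation (tie + continuity corrected)"
  }
  structure(
    list(U = u_a, p_value = p, method = method, n_a = na, n_b = nb),
    class = "rank_sum"
  )
}

#' @export
print.rank_sum <- function(x, ...) {
  cat(sprintf(
    "<rank_sum> U = %g, two-sided p = %.4g (%s; n = %d + %d)\n",
    x$U, x$p_value, x$method, x$n_a, x$n_b
  ))
  invisible(x)
}
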