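#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a zone-pair trans-contact map into long format
#'
#' @param x A `zone_pair_map`.
#' @param ... Unused.
#' @return Tibble `zone_a, zone_b, mean_contacts, n_pairs`.
#' @method tidy zone_pair_map
#' @export
tidy.zone_pair_map <- function(x, ...) {
  tidyr::expand_grid(
    zone_a = rownames(x$map),
    zone_b = colnames(x$map)
  ) |>
    mutate(
      mean_contacts = as.numeric(t(x$map))[dplyr::row_number()],
      n_pairs = as.numeric(t(x$n_pairs))[dplyr::row_number()]
    )
}

#' @rdname tidy.zone_pair_map
#' @method glance zone_pair_map
#' @export
glance.zone_pair_map <- function(x, ...) {
  d <- diag(x$map)
  tibble(
    resolution = x$resolution,
    mode = x$mode,
    max_pair = max(x$map, na.rm = TRUE),
    diag_dorsal = d["1"],
    diag_ventral = d["5"]
  )
}

#' Tidy / glance methods for the zonal gradient statistic
#'
#' @param x A `zonal_trend`.
#' @param ... Unused.
#' @return `tidy()`: per-zone density summaries; `glance()`: one row with
#'   the trend, permutation p and settings.
#' @method tidy zonal_trend
#' @export
tidy.zonal_trend <- function(x, ...) {
  x$per_zone
}

#' @rdname tidy.zonal_trend
#' @method glance zonal_trend
#' @export
glance.zonal_trend <- function(x, ...) {
  tibble(
    trend = x$trend,
    p_value = x$p_value,
    method = x$method,
    n_perm = x$n_perm,
    n_genes = x$n_genes
  )
}

#' Tidy / glance methods for the rank-sum test
#'
#' @param x A `rank_sum` result.
#' @param ... Unused.
#' @method tidy rank_sum
#' @export
tidy.rank_sum <- function(x, ...) {
  tibble(U = x$U, p_value = x$p_value, method = x$method)
}

#' @rdname tidy.rank_sum
#' @method glance rank_sum
#' @export
glance.rank_sum <- function(x, ...) {
  tibble(
    U = x$U, p_value = x$p_value, n_a = x$n_a, n_b = x$n_b,
    method = x$method
  )
}

#' Tidy / glance methods for the silencing-gradient fit
#'
#' @param x A `silencing_fit`.
#' @param ... Unused.
#' @method tidy silencing_fit
#' @export
tidy.silencing_fit <- function(x, ...) {
  x$estimates
}

#' @rdname tidy.silencing_fit
#' @method glance silencing_fit
#' @export
glance.silencing_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    sigma = s$sigma,
    n = x$n,
    converged = x$fit$convInfo$isConv %||% TRUE
  )
}

#' Tidy an aggregate set
#'
#' @param x An `aggregate_set`.
#' @param ... Unused.
#' @return One row per aggregate: `aggregate, size, n_chromosomes`.
#' @method tidy aggregate_set
#' @export
tidy.aggregate_set <- function(x, ...) {
  tibble(
    aggregate = seq_along(x$components),
    size = x$sizes,
    n_chromosomes = x$n_chromosomes
  )
}

#' @rdname tidy.aggregate_set
#' @method glance aggregate_set
#' @export
glance.aggregate_set <- function(x, ...) {
  tibble(
    cell_id = x$cell_id,
    n_aggregates = length(x$components),
    n_or_in_aggregates = sum(x$sizes),
    mean_size = if (length(x$sizes)) mean(x$sizes) else 0,
    max_size = if (length(x$sizes)) max(x$sizes) else 0,
    radius = x$radius
  )
}
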