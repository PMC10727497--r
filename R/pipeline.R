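#' Configuration for the end-to-end demonstration pipeline
#'
#' Bundles the model parameters with pipeline-scale settings. The defaults
#' give a small, fast demonstration; pass a full-size [rheostat_params()] for
#' study-scale runs.
#'
#' @param out_dir Output directory for the run.
#' @param params A [rheostat_params()] object.
#' @param n_cells_per_zone Mature neurons per zone for the demo tissue.
#' @param n_inp_per_zone Progenitors per zone for the single-cell stage.
#' @param hic_zone,chip_zones Zones used by the contact / coverage stages.
#' @param resolution Hi-C bin width (bp).
#' @param n_structures Cells per group for the 3D-structure stage.
#' @param grid_shape Spatial grid (rows, cols).
#' @param seed Seed governing the whole run.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            params = rheostat_params(
                              n_class_i = 12L,
                              n_per_zone = c(26L, 28L, 16L, 14L, 8L),
                              n_clusters = 6L,
                              seed = 1L
                            ),
                            n_cells_per_zone = 60L,
                            n_inp_per_zone = 40L,
                            hic_zone = 5L,
                            chip_zones = c(1L, 3L, 5L),
                            resolution = 50000L,
                            n_structures = 4L,
                            grid_shape = c(10L, 6L),
                            seed = params$seed) {
  structure(
    list(
      out_dir = out_dir,
      params = params,
      n_cells_per_zone = as.integer(n_cells_per_zone),
      n_inp_per_zone = as.integer(n_inp_per_zone),
      hic_zone = as.integer(hic_zone),
      chip_zones = as.integer(chip_zones),
      resolution = as.integer(resolution),
      n_structures = as.integer(n_structures),
      grid_shape = as.integer(grid_shape),
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror [pipeline_config()] arguments; the `params` key
#' holds [rheostat_params()] fields.
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals$out_dir) && is.null(out_dir)) {
    abort("config is missing the required field: out_dir")
  }
  params <- if (is.null(vals$params)) {
    rheostat_params()
  } else {
    do.call(rheostat_params, vals$params)
  }
  vals$params <- params
  if (!is.null(out_dir)) vals$out_dir <- out_dir
  do.call(pipeline_config, vals)
}

run_stage <- function(name, expr) {
  tryCatch(
    force(expr),
    error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    }
  )
}

#' Run the end-to-end demonstration pipeline
#'
#' Simulates a tissue and drives every analysis stage over its emissions:
#' annotate (genome table, census, zone-annotated bins), sc-profile (counts,
#' QC, polygenic profiles), chip-gradient (densities, bedGraph, trend),
#' hic-zonemap (bins/pixels, normalization, zone-pair map),
#' dipc-aggregates (.3dg structures, aggregate report), and spatial-assign
#' (spots, assignment, dorsalization vs an NFI-knockout emission). Every
#' output is written through the package's own writers, and a manifest JSON
#' records parameters, seed and file hashes; a rerun with the same config is
#' hash-identical.
#'
#' @param config A `pipeline_config` (or path to a YAML config).
#' @return The manifest, invisibly (list with `files` md5 table).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  params <- config$params
  seed <- config$seed

  message("stage: simulate")
  tissue <- run_stage("simulate", simulate_tissue(
    params,
    n_cells_per_zone = config$n_cells_per_zone,
    stage_mix = "mOSN", seed = seed
  ))
  inp <- run_stage("simulate", simulate_tissue(
    params,
    genome = tissue$genome,
    n_cells_per_zone = config$n_inp_per_zone,
    stage_mix = "INP", seed = seed
  ))

  message("stage: annotate")
  run_stage("annotate", {
    write_or_annotation(tissue$genome, file.path(out, "or_annotation.tsv"))
    write_or_bed(tissue$genome, file.path(out, "or_annotation.bed"))
    readr::write_tsv(zone_census(tissue$genome),
                     file.path(out, "zone_census.tsv"))
    bins <- annotate_bins(tissue$genome, config$resolution)
    readr::write_tsv(
      bins |> mutate(zone_labels = purrr::map_chr(
        .data$zone_labels, paste, collapse = ","
      )),
      file.path(out, "or_bins.tsv")
    )
  })

  message("stage: sc-profile")
  profile_summary <- run_stage("sc-profile", {
    counts <- emit_sc_counts(inp, seed = seed)
    write_counts_mtx(counts, file.path(out, "sc_counts"))
    prof <- polygenic_zone_profile(counts, tissue$genome)
    readr::write_tsv(
      prof$profiles |> select(-"zone_composition"),
      file.path(out, "polygenic_profiles.tsv")
    )
    readr::write_tsv(prof$summary, file.path(out, "polygenic_summary.tsv"))
    prof$summary
  })

  message("stage: chip-gradient")
  trend <- run_stage("chip-gradient", {
    dens <- emit_chip_gradient(tissue, zones = config$chip_zones, seed = seed)
    readr::write_tsv(dens, file.path(out, "chip_densities.tsv"))
    ventral <- dens |> filter(.data$tissue_zone == max(config$chip_zones))
    emission <- emit_chip_coverage(tissue, max(config$chip_zones),
                                   seed = seed)
    write_bedgraph(emission$track, file.path(out, "chip_ventral.bedGraph"))
    tr <- zonal_gradient_stat(ventral, n_perm = 1000, seed = seed)
    jsonlite::write_json(
      glance(tr), file.path(out, "chip_trend.json"),
      auto_unbox = TRUE, digits = NA
    )
    tr
  })

  message("stage: hic-zonemap")
  zmap <- run_stage("hic-zonemap", {
    cm <- emit_hic_contacts(tissue, config$hic_zone,
                            resolution = config$resolution, seed = seed)
    write_contacts(cm, file.path(out, "hic_bins.tsv"),
                   file.path(out, "hic_pixels.tsv"))
    cm <- normalize_cpb(cm)
    bins <- annotate_bins(tissue$genome, config$resolution)
    zm <- zone_pair_trans_map(cm, bins)
    readr::write_tsv(tidy(zm), file.path(out, "zone_pair_map.tsv"))
    zm
  })

  message("stage: dipc-aggregates")
  agg_report <- run_stage("dipc-aggregates", {
    cells <- tissue$cells |>
      filter(.data$stage == "mOSN", .data$dv_zone %in% c(1L, 5L)) |>
      group_by(.data$dv_zone) |>
      slice(seq_len(config$n_structures)) |>
      ungroup()
    reports <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
      st <- emit_structure(tissue, cells$cell_id[i], seed = seed)
      write_3dg(st, file.path(
        out, sprintf("structure_%s.3dg", cells$cell_id[i])
      ))
      glance(or_aggregates(st, tissue$genome,
                           radius = params$contact_radius)) |>
        mutate(dv_zone = cells$dv_zone[i])
    })
    readr::write_tsv(reports, file.path(out, "aggregates.tsv"))
    reports
  })

  message("stage: spatial-assign")
  spatial <- run_stage("spatial-assign", {
    spots <- emit_spatial(tissue, grid_shape = config$grid_shape,
                          sample = "control", seed = seed)
    readr::write_tsv(spots$spots, file.path(out, "spots.tsv"))
    write_counts_mtx(
      or_counts(spots$counts, spots$genes,
                spots$spots |> rename(cell_id = "barcode")),
      file.path(out, "spot_counts")
    )
    ko_tissue <- simulate_tissue(
      apply_nfi_knockout(params),
      genome = tissue$genome,
      n_cells_per_zone = config$n_cells_per_zone,
      stage_mix = "mOSN", seed = seed
    )
    ko_spots <- emit_spatial(ko_tissue, grid_shape = config$grid_shape,
                             sample = "perturbed", seed = seed)
    ac <- assign_spot_zone(normalize_spots(spots))
    ak <- assign_spot_zone(normalize_spots(ko_spots))
    readr::write_tsv(ac, file.path(out, "spot_assignment_control.tsv"))
    readr::write_tsv(ak, file.path(out, "spot_assignment_perturbed.tsv"))
    di <- dorsalization_index(ac, ak)
    readr::write_tsv(di$shift, file.path(out, "assignment_shift.tsv"))
    di
  })

  files <- sort(list.files(out, recursive = TRUE))
  files <- setdiff(files, "manifest.json")
  hashes <- tools::md5sum(file.path(out, files))
  manifest <- list(
    package = "orzone",
    version = as.character(utils::packageVersion("orzone")),
    seed = seed,
    params = unclass(params),
    config = list(
      n_cells_per_zone = config$n_cells_per_zone,
      n_inp_per_zone = config$n_inp_per_zone,
      hic_zone = config$hic_zone,
      chip_zones = config$chip_zones,
      resolution = config$resolution,
      n_structures = config$n_structures,
      grid_shape = config$grid_shape
    ),
    results = list(
      chip_trend = trend$trend,
      dorsalization_index = spatial$index
    ),
    files = as.list(stats::setNames(unname(hashes), files))
  )
  jsonlite::write_json(
    manifest, file.path(out, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(manifest)
}
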