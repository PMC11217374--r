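# YAML-configured pipeline: simulate or load inputs, segment, count,
# quantify, report. Every run embeds a provenance block (config hash,
# seed, tool version) in the report.

# FNV-1a 32-bit hash of a character string, as 8 hex digits.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  for (b in bytes) {
    # xor touches only the low byte; arithmetic stays exact in doubles
    h <- h - (h %% 256) + bitwXor(h %% 256, b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Read a pipeline configuration from YAML
#'
#' Fills unspecified sections with defaults: in-plane Gaussian sigma of 1
#' pixel (none along z), 26-connectivity, low-face exclusion planes, the
#' standard shrinkage factors and the 3 um shaft-length filter.
#'
#' @param path YAML file, or a list already parsed.
#' @return Config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    region = "region",
    seed = 1L,
    segmentation = list(sigma_xy = 1, sigma_z = 0, gray_threshold = 100,
                        min_voxels = 20L, connectivity = 26L),
    frame = list(margin_um = c(0.05, 0.05, 0.05),
                 exclusion_faces = c("x-", "y-", "z-")),
    shrinkage = list(volume = 0.87, surface = 0.91, linear = 0.96),
    metrics = list(min_shaft_um = 3))
  modifyList(defaults, cfg)
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    abort(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e))))
}

#' Run the full quantification pipeline
#'
#' Executes simulate/load, segment, count, quantify and report stages as
#' configured, writing `junctions.csv` (+ voxel sidecar), `records.csv`,
#' `skeletons.json` and `report.json` into `out_dir`. Deterministic per
#' seed: rerunning the same config yields byte-identical reports.
#'
#' @param config Config list or YAML path (see [read_pipeline_config()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides the config seed when given.
#' @return The `region_report`, invisibly.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- read_pipeline_config(config)
  seed <- seed %||% cfg$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  factors <- shrinkage_factors(cfg$shrinkage$volume, cfg$shrinkage$surface,
                               cfg$shrinkage$linear)
  cfg_hash <- fnv1a(as.character(jsonlite::toJSON(cfg, auto_unbox = TRUE)))

  grid <- junctions <- frame <- NULL
  if (!is.null(cfg$simulate$stack)) {
    sim <- pipeline_stage("simulate-stack", {
      spec <- do.call(phantom_spec, cfg$simulate$stack)
      generate_phantom_stack(spec, seed)
    })
    grid <- sim$grid
  } else if (!is.null(cfg$inputs$stack)) {
    grid <- pipeline_stage("read-stack", read_stack(
      cfg$inputs$stack,
      voxel_size = cfg$inputs$voxel_size %||% c(5, 5, 20)))
  }
  if (!is.null(grid)) {
    junctions <- pipeline_stage("segment", {
      sm <- gaussian_preprocess(grid, cfg$segmentation$sigma_xy,
                                cfg$segmentation$sigma_z)
      segment_junctions(sm, cfg$segmentation$gray_threshold,
                        cfg$segmentation$min_voxels,
                        cfg$segmentation$connectivity)
    })
    frame <- pipeline_stage("count", frame_from_grid(
      grid, cfg$frame$margin_um, cfg$frame$exclusion_faces))
    write_junctions(junctions, file.path(out_dir, "junctions.csv"),
                    file.path(out_dir, "junction_voxels.json"))
  }

  if (!is.null(cfg$simulate$network)) {
    net <- pipeline_stage("simulate-network", {
      args <- cfg$simulate$network
      args$factors <- factors
      spec <- do.call(network_spec, args)
      generate_fiber_network(spec, seed + 1L)
    })
    network <- net$network; synapses <- net$synapses
    volume_um3 <- cfg$simulate$network$volume_um3 %||% 500
  } else if (!is.null(cfg$inputs$skeletons)) {
    sk <- pipeline_stage("read-skeletons", read_skeletons(
      cfg$inputs$skeletons))
    network <- sk$network; synapses <- sk$synapses
    volume_um3 <- cfg$volume_um3 %||%
      (if (!is.null(frame)) corrected_volume(frame_volume(frame), factors)
       else abort("config needs `volume_um3` when no frame is available"))
  } else {
    network <- fiber_network(
      tibble::tibble(fiber_id = integer(), fiber_class = character(),
                     myelinated = logical()),
      tibble::tibble(fiber_id = integer(), node_id = integer(),
                     parent_id = integer(), x_um = numeric(),
                     y_um = numeric(), z_um = numeric(), role = character()))
    synapses <- empty_synapse_table()
    volume_um3 <- cfg$volume_um3 %||%
      (if (!is.null(frame)) corrected_volume(frame_volume(frame), factors)
       else abort("config needs a network, a stack, or `volume_um3`"))
  }

  report <- pipeline_stage("quantify", build_region_report(
    region = cfg$region, network = network, synapses = synapses,
    junctions = if (!is.null(junctions) && nrow(junctions)) junctions
                else NULL,
    frame = frame, volume_um3 = volume_um3, factors = factors,
    voxel_size = if (!is.null(grid)) grid$voxel_size else c(5, 5, 20),
    min_shaft_um = cfg$metrics$min_shaft_um))

  pipeline_stage("report", {
    recs <- as.data.frame(report$records)
    tmp <- file.path(out_dir, "records.csv.tmp")
    utils::write.csv(recs, tmp, row.names = FALSE)
    file.rename(tmp, file.path(out_dir, "records.csv"))
    write_skeletons(network, file.path(out_dir, "skeletons.json"), synapses)
    write_region_report(report, file.path(out_dir, "report.json"),
                        provenance = list(config_hash = cfg_hash,
                                          seed = seed))
  })
  invisible(report)
}
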