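# Assembly of all per-region summary quantities into a single report
# object with deterministic JSON serialization.

#' Assemble a full region report
#'
#' Composes every summary quantity for one tissue region: shrinkage-
#' corrected volumetric synapse densities by type (counted in an unbiased
#' frame when one is given), fiber counts and proportions by class, linear
#' synapse density records and per-class means, the synapse target
#' distribution, multi-contact and bouton-shape statistics, fiber-class
#' length densities in m/mm^3, the spine/shaft density correlation, and
#' advisory within-region comparisons. Deterministic given inputs.
#'
#' @param region Region label (e.g. `"SR"`).
#' @param network A [fiber_network()]; may have zero fibers.
#' @param synapses Junction tibble (`synapse_id`, `syn_type`, centroids).
#' @param junctions Optional segmented junction tibble with voxel sets,
#'   used for frame counting when `frame` is given (defaults to
#'   `synapses`).
#' @param frame Optional [counting_frame()]; when given, synapse counts and
#'   the reference volume come from the frame.
#' @param volume_um3 Corrected reference volume in um^3 (required when no
#'   frame is given).
#' @param factors A [shrinkage_factors()].
#' @param voxel_size,origin Geometry for voxel-backed junctions.
#' @param min_shaft_um Inclusion threshold for linear densities.
#' @param bounds Volume extent for bouton censoring (see
#'   [bouton_shape_summary()]).
#' @return A `region_report` object.
#' @export
build_region_report <- function(region, network, synapses, junctions = NULL,
                                frame = NULL, volume_um3 = NULL,
                                factors = shrinkage_factors(),
                                voxel_size = c(5, 5, 20), origin = c(0, 0, 0),
                                min_shaft_um = 3, bounds = NULL) {
  junctions <- junctions %||% synapses
  if (is.null(volume_um3)) {
    if (is.null(frame)) abort("give either `frame` or `volume_um3`")
    volume_um3 <- corrected_volume(frame_volume(frame), factors)
  }
  # synapse counts and volumetric densities
  if (!is.null(frame)) {
    by_type <- lapply(c(AS = "AS", SS = "SS"), function(ty)
      count_in_frame(junctions[!is.na(junctions$syn_type) &
                                 junctions$syn_type == ty, , drop = FALSE],
                     frame, voxel_size, origin))
  } else {
    by_type <- list(AS = sum(junctions$syn_type == "AS", na.rm = TRUE),
                    SS = sum(junctions$syn_type == "SS", na.rm = TRUE))
  }
  n_as <- by_type$AS; n_ss <- by_type$SS
  n_tot <- n_as + n_ss
  density <- tibble::tibble(
    syn_type = c("AS", "SS", "all"),
    n = c(n_as, n_ss, n_tot),
    density_per_um3 = volumetric_density(c(n_as, n_ss, n_tot), volume_um3),
    pct = if (n_tot > 0) 100 * c(n_as, n_ss, n_tot) / n_tot
          else c(NA, NA, NA))

  empty <- nrow(network$fibers) == 0L
  comp <- network$fibers |>
    dplyr::count(fiber_class = factor(.data$fiber_class,
                                      levels = FIBER_CLASSES),
                 .drop = FALSE, name = "n") |>
    dplyr::mutate(fiber_class = as.character(.data$fiber_class),
                  pct = if (sum(n) > 0) 100 * .data$n / sum(.data$n)
                        else rep(NA_real_, dplyr::n()))
  nd <- sum(comp$n[comp$fiber_class %in% DENDRITE_CLASSES])
  na_ <- sum(comp$n[comp$fiber_class %in% AXON_CLASSES])
  composition_shares <- tibble::tibble(
    share = c("spiny_of_dendrites", "excitatory_of_axons"),
    pct = c(if (nd > 0) 100 * comp$n[comp$fiber_class == "spiny_dendrite"] / nd
            else NA_real_,
            if (na_ > 0) 100 * comp$n[comp$fiber_class == "excitatory_axon"] / na_
            else NA_real_))

  if (!empty) {
    records <- linear_synapse_density(network, synapses, factors, min_shaft_um)
    density_by_class <- records |>
      dplyr::filter(.data$included) |>
      dplyr::group_by(.data$fiber_class) |>
      dplyr::summarise(
        n_fibers = dplyr::n(),
        mean_density_total = mean(.data$density_total),
        sem_density_total = sd(.data$density_total) / sqrt(dplyr::n()),
        mean_density_spines = mean(.data$density_spines),
        mean_density_shaft = mean(.data$density_shaft),
        .groups = "drop")
    targets <- if (nrow(synapses)) synapse_target_distribution(synapses, network)
               else NULL
    multi <- multi_contact_summary(network, synapses)
    bouton <- bouton_shape_summary(network, synapses, bounds = bounds)
    lengths <- length_report(network, volume_um3, factors)
    n_spiny_inc <- sum(records$fiber_class == "spiny_dendrite" &
                         records$included)
    ss_corr <- if (n_spiny_inc >= 3L) spine_shaft_correlation(records)
               else tibble::tibble(r_squared = NA_real_,
                                   n_dendrites = n_spiny_inc)
    adv <- advisory_tests(records)
  } else {
    records <- linear_synapse_density(network, synapses, factors, min_shaft_um)
    density_by_class <- records[0, c("fiber_class", "included")]
    targets <- NULL; multi <- multi_contact_summary(network, synapses)
    bouton <- bouton_shape_summary(network, synapses)
    lengths <- length_report_from_densities(
      tibble::tibble(fiber_class = FIBER_CLASSES,
                     length_m_per_mm3 = 0))
    ss_corr <- tibble::tibble(r_squared = NA_real_, n_dendrites = 0L)
    adv <- tibble::tibble(comparison = character(), statistic = numeric(),
                          p_value = numeric())
  }
  structure(list(region = region, volume_um3 = volume_um3,
                 factors = factors, density = density,
                 composition = comp, composition_shares = composition_shares,
                 records = records, density_by_class = density_by_class,
                 targets = targets, multi_contact = multi, bouton = bouton,
                 lengths = lengths, spine_shaft = ss_corr,
                 tests = adv, empty = empty),
            class = "region_report")
}

# Advisory within-region comparisons (the nonparametric path is always
# taken for between-region comparisons; these are descriptive).
advisory_tests <- function(records) {
  out <- list()
  sp <- records[records$fiber_class == "spiny_dendrite" & records$included, ]
  if (nrow(sp) >= 2L && (sd(sp$density_spines) > 0 ||
                         sd(sp$density_shaft) > 0)) {
    mw <- mann_whitney(sp$density_spines, sp$density_shaft)
    out$spines_vs_shaft <- tibble::tibble(
      comparison = "spiny: density on spines vs on shaft",
      statistic = mw$u, p_value = mw$p_value)
  }
  sm <- records[records$fiber_class == "smooth_dendrite" & records$included, ]
  if (nrow(sp) >= 2L && nrow(sm) >= 2L) {
    mw <- mann_whitney(sp$density_total, sm$density_total)
    out$spiny_vs_smooth <- tibble::tibble(
      comparison = "total density: spiny vs smooth dendrites",
      statistic = mw$u, p_value = mw$p_value)
  }
  if (length(out)) dplyr::bind_rows(out)
  else tibble::tibble(comparison = character(), statistic = numeric(),
                      p_value = numeric())
}

#' @export
print.region_report <- function(x, ...) {
  cat(sprintf("<region_report> %s, %.2f um^3 (corrected)\n", x$region,
              x$volume_um3))
  d <- x$density
  cat(sprintf("  synapses: %d (%.2f /um^3); AS %.2f%%, SS %.2f%%\n",
              d$n[3], d$density_per_um3[3], d$pct[1], d$pct[2]))
  cat(sprintf("  fibers: %d; total length %.2f m/mm^3\n",
              sum(x$composition$n), x$lengths$total_m_per_mm3))
  invisible(x)
}

#' @rdname build_region_report
#' @param x A `region_report`.
#' @param component One of `"density"`, `"composition"`, `"records"`,
#'   `"density_by_class"`, `"lengths"`, `"tests"`.
#' @param ... Unused.
#' @export
tidy.region_report <- function(x, component = "records", ...) {
  comp <- match.arg(component, c("density", "composition", "records",
                                 "density_by_class", "lengths", "tests"))
  if (comp == "lengths") return(tidy(x$lengths))
  x[[comp]]
}

#' @rdname build_region_report
#' @export
glance.region_report <- function(x, ...) {
  tibble::tibble(
    region = x$region,
    volume_um3 = x$volume_um3,
    n_synapses = x$density$n[3],
    synapse_density_per_um3 = x$density$density_per_um3[3],
    ss_pct = x$density$pct[2],
    n_fibers = sum(x$composition$n),
    total_length_m_per_mm3 = x$lengths$total_m_per_mm3,
    spine_shaft_r_squared = x$spine_shaft$r_squared)
}

#' @export
tidy.length_report <- function(x, ...) x$by_class

#' @export
glance.length_report <- function(x, ...) {
  ns <- x$by_class
  tibble::tibble(
    total_m_per_mm3 = x$total_m_per_mm3,
    synaptic_total_m_per_mm3 = x$synaptic_total_m_per_mm3,
    nonsynaptic_pct = ns$pct[ns$fiber_class == "non_synaptic"])
}

# round for report output: densities and percentages at 2 decimals
r2 <- function(x) ifelse(is.na(x), NA, round(as.numeric(x), 2))

df_json <- function(df, round_cols) {
  df <- as.data.frame(df)
  for (cc in intersect(round_cols, names(df))) df[[cc]] <- r2(df[[cc]])
  df
}

#' Serialize a region report to deterministic JSON
#'
#' Fixed key order and fixed rounding (densities and percentages at two
#' decimals), so identical inputs yield byte-identical files. The write is
#' atomic (temporary file + rename). A provenance block (tool version plus
#' any entries in `provenance`) is embedded.
#'
#' @param report A `region_report`.
#' @param path Output path.
#' @param provenance Named list added to the provenance block (e.g. config
#'   hash and seed).
#' @return `path`, invisibly.
#' @export
write_region_report <- function(report, path, provenance = list()) {
  rc <- c("density_per_um3", "pct", "mean_density_total",
          "sem_density_total", "mean_density_spines", "mean_density_shaft",
          "length_m_per_mm3", "pct_en_passant", "pct_terminal",
          "pct_axons_multihit_same_dendrite",
          "pct_dendrites_with_repeated_partner", "density_total",
          "density_spines", "density_shaft", "shaft_length_um")
  body <- list(
    schema = "synaptometry/region_report",
    schema_version = 1L,
    provenance = c(list(tool = "synaptometry",
                        version = as.character(utils::packageVersion(
                          "synaptometry"))),
                   provenance),
    region = report$region,
    volume_um3 = r2(report$volume_um3),
    synapse_density = df_json(report$density, rc),
    fiber_composition = df_json(report$composition, rc),
    composition_shares = df_json(report$composition_shares, rc),
    linear_density_by_class = df_json(report$density_by_class, rc),
    target_distribution = if (is.null(report$targets)) NULL else list(
      fourway = df_json(report$targets$fourway, rc),
      by_dendrite_type = df_json(report$targets$by_dendrite_type, rc),
      ss_spine_head_neck = df_json(report$targets$ss_spine_head_neck, rc)),
    multi_contact = df_json(report$multi_contact$summary, rc),
    bouton_shape = df_json(report$bouton, rc),
    length_densities = df_json(report$lengths$by_class, rc),
    length_total_m_per_mm3 = r2(report$lengths$total_m_per_mm3),
    length_synaptic_m_per_mm3 = r2(report$lengths$synaptic_total_m_per_mm3),
    spine_shaft_r_squared = round(report$spine_shaft$r_squared, 4),
    advisory_tests = df_json(report$tests, character()),
    empty = report$empty)
  json <- jsonlite::toJSON(body, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, null = "null", na = "null",
                           pretty = TRUE)
  write_atomic(as.character(json), path)
  invisible(path)
}

#' Compare linear-density records across regions
#'
#' Kruskal-Wallis with Bonferroni-corrected pairwise Mann-Whitney tests on
#' a per-fiber linear-density measure, across named regions.
#'
#' @param records_by_region Named list of [linear_synapse_density()]
#'   tibbles.
#' @param fiber_class Class to compare.
#' @param measure Column to compare (e.g. `"density_total"`).
#' @param ... Passed to [kruskal_wallis_bonferroni()].
#' @return A `kw_test` (or the [mann_whitney()] tibble for two regions).
#' @export
compare_region_densities <- function(records_by_region,
                                     fiber_class = "spiny_dendrite",
                                     measure = "density_total", ...) {
  groups <- lapply(records_by_region, function(r)
    r[[measure]][r$fiber_class == fiber_class & r$included])
  groups <- groups[lengths(groups) > 0]
  if (length(groups) < 2L) abort("need records from at least 2 regions")
  if (length(groups) == 2L) return(mann_whitney(groups[[1]], groups[[2]]))
  kruskal_wallis_bonferroni(groups, ...)
}

#' Chi-square comparison of count compositions across regions
#'
#' @param counts_by_region Named list of equally-named count vectors (e.g.
#'   AS/SS counts per region).
#' @return One-row tibble from [chi_square_independence()].
#' @export
compare_region_counts <- function(counts_by_region) {
  tab <- do.call(rbind, counts_by_region)
  chi_square_independence(tab)
}
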