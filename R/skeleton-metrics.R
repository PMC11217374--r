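# Per-fiber and per-population metrics computed from skeletons and their
# attached synapses: 3D lengths, linear synapse densities, fiber
# classification, length densities in m/mm^3, target distributions,
# multi-contact and bouton-shape statistics.

#' Length of a 3D polyline
#'
#' Sum of Euclidean distances between consecutive nodes; a single node has
#' length zero. Fiber lengths are measured in 3D along the skeleton, never
#' from 2D projections.
#'
#' @param xyz Numeric matrix with columns x, y, z (um), one row per node in
#'   order.
#' @return Length in um.
#' @examples
#' polyline_length(rbind(c(0, 0, 0), c(3, 4, 0)))  # 5
#' @export
polyline_length <- function(xyz) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  if (nrow(xyz) < 1L) abort("polyline needs at least one node")
  if (nrow(xyz) == 1L) return(0)
  d <- diff(xyz)
  sum(sqrt(rowSums(d^2)))
}

# Edge table of a network: one row per non-root node with its segment
# length and the role of the edge (= role of the child node).
fiber_edge_table <- function(network) {
  nodes <- spine_branches(network)
  nodes[!is.na(nodes$parent_row),
        c("fiber_id", "node_id", "role", "seg_len_um", "branch_id")]
}

#' Shrinkage-corrected shaft length per fiber
#'
#' Sums edge lengths over shaft edges only (spine branches excluded, since
#' linear densities are expressed per micron of dendritic shaft) and
#' divides by the linear shrinkage factor.
#'
#' @param network A [fiber_network()].
#' @param factors A [shrinkage_factors()]; use [no_shrinkage()] to disable
#'   correction.
#' @return Tibble `fiber_id`, `shaft_length_um` (corrected),
#'   `spine_length_um` (corrected total spine-branch length).
#' @export
shaft_length <- function(network, factors = shrinkage_factors()) {
  edges <- fiber_edge_table(network)
  base <- tibble::tibble(fiber_id = network$fibers$fiber_id)
  agg <- edges |>
    dplyr::group_by(.data$fiber_id) |>
    dplyr::summarise(
      shaft_length_um = sum(.data$seg_len_um[.data$role == "shaft"]),
      spine_length_um = sum(.data$seg_len_um[.data$role == "spine"]),
      .groups = "drop")
  base |>
    dplyr::left_join(agg, by = "fiber_id") |>
    dplyr::mutate(
      shaft_length_um = dplyr::coalesce(.data$shaft_length_um, 0) /
        factors$linear,
      spine_length_um = dplyr::coalesce(.data$spine_length_um, 0) /
        factors$linear)
}

#' Classify fibers from their synaptic attachments
#'
#' A fiber postsynaptic to at least one junction is a dendrite (spiny when
#' it has at least one spine branch, smooth otherwise); a presynaptic fiber
#' is an axon (myelinated when flagged, else excitatory if all its
#' junctions are AS, inhibitory if all SS); a fiber with no attachments is
#' non-synaptic. A fiber that is both pre- and postsynaptic, or an axon
#' attaching both AS and SS junctions, is a classification conflict and is
#' surfaced, never silently resolved.
#'
#' @param network A [fiber_network()].
#' @param synapses Junction tibble with `synapse_id`, `syn_type`.
#' @param on_conflict `"error"` (default) stops; `"flag"` returns
#'   `fiber_class = NA` with the conflict described.
#' @return Tibble `fiber_id`, `fiber_class`, `conflict` (NA when clean).
#' @export
classify_fibers <- function(network, synapses,
                            on_conflict = c("error", "flag")) {
  on_conflict <- match.arg(on_conflict)
  nodes <- spine_branches(network)
  has_spine <- tapply(!is.na(nodes$branch_id), nodes$fiber_id, any)
  att <- network$attachments
  res <- lapply(seq_len(nrow(network$fibers)), function(i) {
    fid <- network$fibers$fiber_id[i]
    a <- att[att$fiber_id == fid, , drop = FALSE]
    spiny <- isTRUE(has_spine[[as.character(fid)]])
    conflict <- NA_character_
    if (nrow(a) == 0L) cls <- "non_synaptic"
    else if (all(c("pre", "post") %in% a$side)) {
      cls <- NA_character_
      conflict <- "fiber is both pre- and postsynaptic"
    } else if (all(a$side == "post")) {
      cls <- if (spiny) "spiny_dendrite" else "smooth_dendrite"
    } else {
      if (isTRUE(network$fibers$myelinated[i])) cls <- "myelinated_axon"
      else {
        types <- unique(synapses$syn_type[match(a$synapse_id,
                                                synapses$synapse_id)])
        types <- types[!is.na(types)]
        if (length(types) == 1L && types == "AS") cls <- "excitatory_axon"
        else if (length(types) == 1L && types == "SS") cls <- "inhibitory_axon"
        else {
          cls <- NA_character_
          conflict <- if (length(types) > 1L)
            "axon attaches both AS and SS junctions"
          else "junction types unknown"
        }
      }
    }
    tibble::tibble(fiber_id = fid, fiber_class = cls, conflict = conflict)
  }) |> dplyr::bind_rows()
  if (on_conflict == "error" && any(!is.na(res$conflict)))
    abort(sprintf("classification conflict for fiber(s) %s: %s",
                  paste(res$fiber_id[!is.na(res$conflict)], collapse = ", "),
                  res$conflict[!is.na(res$conflict)][1]))
  res
}

#' Linear synapse densities per fiber
#'
#' The linear density is the number of synapses per micron of shaft,
#' measured along the 3D skeleton with shrinkage-corrected lengths. For
#' dendrites the count is split into synapses on spines and on the shaft
#' (by the role of the postsynaptic attachment node); for axons all
#' presynaptic attachments count toward the total regardless of their
#' postsynaptic target. Fibers whose corrected shaft is shorter than
#' `min_shaft_um` are retained with `included = FALSE` and `NA` densities,
#' mirroring the >= 3 micron inclusion rule.
#'
#' @param network A [fiber_network()].
#' @param synapses Junction tibble (`synapse_id`, `syn_type`).
#' @param factors A [shrinkage_factors()].
#' @param min_shaft_um Minimum corrected shaft length for inclusion.
#' @return Tibble with one record per fiber: `fiber_id`, `fiber_class`,
#'   `shaft_length_um`, `n_syn_total`, `n_syn_spines`, `n_syn_shaft`,
#'   `density_total`, `density_spines`, `density_shaft`, `included`.
#' @export
linear_synapse_density <- function(network, synapses,
                                   factors = shrinkage_factors(),
                                   min_shaft_um = 3) {
  lens <- shaft_length(network, factors)
  nodes <- network$nodes
  role_of <- setNames(nodes$role, paste(nodes$fiber_id, nodes$node_id))
  att <- network$attachments
  att$att_role <- role_of[paste(att$fiber_id, att$node_id)]
  cls <- network$fibers$fiber_class
  names(cls) <- as.character(network$fibers$fiber_id)
  counts <- att |>
    dplyr::group_by(.data$fiber_id) |>
    dplyr::summarise(
      n_syn_total = dplyr::n(),
      n_syn_spines = sum(.data$att_role == "spine"),
      n_syn_shaft = sum(.data$att_role == "shaft"),
      .groups = "drop")
  rec <- lens |>
    dplyr::left_join(counts, by = "fiber_id") |>
    dplyr::mutate(
      fiber_class = unname(cls[as.character(.data$fiber_id)]),
      dplyr::across(dplyr::starts_with("n_syn"),
                    ~ dplyr::coalesce(.x, 0L)),
      included = .data$shaft_length_um >= min_shaft_um,
      density_total = ifelse(.data$included,
                             .data$n_syn_total / .data$shaft_length_um, NA),
      density_spines = ifelse(.data$included &
                                .data$fiber_class %in% DENDRITE_CLASSES,
                              .data$n_syn_spines / .data$shaft_length_um, NA),
      density_shaft = ifelse(.data$included &
                               .data$fiber_class %in% DENDRITE_CLASSES,
                             .data$n_syn_shaft / .data$shaft_length_um, NA))
  rec[, c("fiber_id", "fiber_class", "shaft_length_um", "n_syn_total",
          "n_syn_spines", "n_syn_shaft", "density_total", "density_spines",
          "density_shaft", "included")]
}

#' Fiber-class length densities in meters per cubic millimeter
#'
#' Sums the shrinkage-corrected skeleton length of every fiber class,
#' divides by the corrected tissue volume and converts um/um^3 to m/mm^3
#' (factor 1000). By default only shaft length is accounted, mirroring the
#' per-micron-of-shaft convention of the linear densities; set
#' `include_spines = TRUE` to add spine-branch length (clearly a different
#' accounting, reported as such).
#'
#' @param network A [fiber_network()] with classified fibers.
#' @param volume_um3 Shrinkage-corrected reference volume in um^3.
#' @param factors A [shrinkage_factors()].
#' @param include_spines Include spine-branch length in the totals.
#' @return A `length_report` object; see [tidy()] / [glance()] methods.
#' @export
length_report <- function(network, volume_um3,
                          factors = shrinkage_factors(),
                          include_spines = FALSE) {
  if (!is.finite(volume_um3) || volume_um3 <= 0)
    abort("`volume_um3` must be > 0")
  lens <- shaft_length(network, factors) |>
    dplyr::left_join(network$fibers[, c("fiber_id", "fiber_class")],
                     by = "fiber_id") |>
    dplyr::mutate(len = .data$shaft_length_um +
                    if (include_spines) .data$spine_length_um else 0)
  by_class <- lens |>
    dplyr::group_by(fiber_class = factor(.data$fiber_class,
                                         levels = FIBER_CLASSES)) |>
    dplyr::summarise(length_um = sum(.data$len), .groups = "drop") |>
    tidyr::complete(.data$fiber_class, fill = list(length_um = 0)) |>
    dplyr::mutate(fiber_class = as.character(.data$fiber_class),
                  length_m_per_mm3 = .data$length_um / volume_um3 * 1000) |>
    dplyr::select("fiber_class", "length_m_per_mm3")
  out <- length_report_from_densities(by_class)
  out$volume_um3 <- volume_um3
  out$include_spines <- include_spines
  out
}

#' Length-density accounting from per-class densities
#'
#' The arithmetic half of [length_report()]: given per-class length
#' densities (m/mm^3), computes each class's percentage of the grand total
#' and the synaptic-fiber total (all classes except non-synaptic fibers).
#' Useful to re-derive the percentage accounting of a published length
#' table.
#'
#' @param by_class Tibble with `fiber_class` and `length_m_per_mm3`.
#' @return A `length_report` object.
#' @export
length_report_from_densities <- function(by_class) {
  by_class <- tibble::as_tibble(by_class)
  stopifnot(all(c("fiber_class", "length_m_per_mm3") %in% names(by_class)))
  total <- sum(by_class$length_m_per_mm3)
  by_class$pct <- if (total > 0) 100 * by_class$length_m_per_mm3 / total
                  else rep(0, nrow(by_class))
  synaptic <- sum(by_class$length_m_per_mm3[by_class$fiber_class !=
                                              "non_synaptic"])
  structure(list(by_class = by_class,
                 total_m_per_mm3 = total,
                 synaptic_total_m_per_mm3 = synaptic),
            class = "length_report")
}

#' @export
print.length_report <- function(x, ...) {
  cat("<length_report>\n")
  df <- x$by_class
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-16s %10.2f m/mm^3  %6.2f%%\n", df$fiber_class[i],
                df$length_m_per_mm3[i], df$pct[i]))
  cat(sprintf("  %-16s %10.2f m/mm^3\n", "total", x$total_m_per_mm3))
  cat(sprintf("  %-16s %10.2f m/mm^3\n", "synaptic only",
              x$synaptic_total_m_per_mm3))
  invisible(x)
}

#' Resolve the postsynaptic target of each synapse
#'
#' Assigns every synapse its postsynaptic dendrite, dendrite class, target
#' location (`shaft`, `spine_head` or `spine_neck`) and presynaptic axon.
#' A spine-branch attachment counts as the head when its arc-length
#' position along the branch exceeds `head_threshold` of the branch length
#' from the shaft, otherwise as the neck.
#'
#' @param synapses Junction tibble with `synapse_id`, `syn_type`.
#' @param network A [fiber_network()].
#' @param head_threshold Fraction of branch length separating neck from
#'   head.
#' @return `synapses` with columns `dendrite_id`, `dendrite_class`,
#'   `axon_id`, `target`.
#' @export
assign_targets <- function(synapses, network, head_threshold = 0.5) {
  nodes <- spine_branches(network)
  key <- paste(nodes$fiber_id, nodes$node_id)
  branch_len <- tapply(nodes$arc_um, nodes$branch_id, max)
  att <- network$attachments
  post <- att[att$side == "post", , drop = FALSE]
  pre <- att[att$side == "pre", , drop = FALSE]
  cls <- setNames(network$fibers$fiber_class,
                  as.character(network$fibers$fiber_id))
  i <- match(synapses$synapse_id, post$synapse_id)
  synapses$dendrite_id <- post$fiber_id[i]
  synapses$dendrite_class <- unname(cls[as.character(synapses$dendrite_id)])
  synapses$axon_id <- pre$fiber_id[match(synapses$synapse_id, pre$synapse_id)]
  node_row <- match(paste(synapses$dendrite_id, post$node_id[i]), key)
  target <- rep(NA_character_, nrow(synapses))
  ok <- !is.na(node_row)
  role <- nodes$role[node_row[ok]]
  tgt <- ifelse(role == "shaft", "shaft", NA)
  sp <- which(role == "spine")
  if (length(sp)) {
    br <- nodes$branch_id[node_row[ok][sp]]
    frac <- nodes$arc_um[node_row[ok][sp]] / unname(branch_len[as.character(br)])
    tgt[sp] <- ifelse(frac > head_threshold, "spine_head", "spine_neck")
  }
  target[ok] <- tgt
  synapses$target <- target
  synapses
}

#' Distribution of synapses over postsynaptic targets
#'
#' Computes (i) the four-way AS/SS x spine/shaft percentages, (ii) the
#' split of synapses over spines, shafts of spiny dendrites and smooth
#' dendrites, and (iii) the head/neck split of SS on spines. Each partition
#' sums to 100.
#'
#' @param synapses Junction tibble carrying `syn_type`, `target` and
#'   `dendrite_class` columns; if `network` is given these are (re)derived
#'   with [assign_targets()].
#' @param network Optional [fiber_network()].
#' @return A `target_distribution` object with tibbles `fourway`,
#'   `by_dendrite_type` and `ss_spine_head_neck` (`category`, `n`, `pct`).
#' @export
synapse_target_distribution <- function(synapses, network = NULL) {
  if (!is.null(network)) synapses <- assign_targets(synapses, network)
  if (nrow(synapses) == 0L) abort("empty synapse set")
  need <- c("syn_type", "target", "dendrite_class")
  if (!all(need %in% names(synapses)))
    abort("synapses lack target columns; pass `network` to derive them")
  s <- synapses[!is.na(synapses$target), , drop = FALSE]
  loc <- ifelse(s$target == "shaft", "shaft", "spine")
  pct_table <- function(cat, levels) {
    n <- table(factor(cat, levels = levels))
    tibble::tibble(category = levels, n = as.integer(n),
                   pct = if (sum(n) > 0) 100 * as.integer(n) / sum(n)
                         else rep(0, length(n)))
  }
  fourway <- pct_table(paste(s$syn_type, loc, sep = "_on_"),
                       c("AS_on_spine", "AS_on_shaft", "SS_on_shaft",
                         "SS_on_spine"))
  dend_cat <- ifelse(loc == "spine", "spines",
                     ifelse(s$dendrite_class == "smooth_dendrite",
                            "smooth_dendrite_shaft", "spiny_dendrite_shaft"))
  by_dend <- pct_table(dend_cat, c("spines", "spiny_dendrite_shaft",
                                   "smooth_dendrite_shaft"))
  ss_sp <- s[s$syn_type == "SS" & loc == "spine", , drop = FALSE]
  head_neck <- pct_table(ifelse(ss_sp$target == "spine_head", "head", "neck"),
                         c("head", "neck"))
  structure(list(fourway = fourway, by_dendrite_type = by_dend,
                 ss_spine_head_neck = head_neck, n_synapses = nrow(s)),
            class = "target_distribution")
}

#' @export
print.target_distribution <- function(x, ...) {
  cat("<target_distribution>", x$n_synapses, "synapses\n")
  for (nm in c("fourway", "by_dendrite_type", "ss_spine_head_neck")) {
    cat(" ", nm, "\n")
    df <- x[[nm]]
    for (i in seq_len(nrow(df)))
      cat(sprintf("    %-22s %6d  %6.2f%%\n", df$category[i], df$n[i],
                  df$pct[i]))
  }
  invisible(x)
}

#' Multi-contact statistics of the axon-dendrite graph
#'
#' Among axons establishing at least two synapses, the proportion that
#' establish two or more with the *same* dendrite; and among all dendrites,
#' the proportion receiving repeated contacts from at least one axon,
#' together with each dendrite's number of distinct multi-contact partner
#' axons.
#'
#' @param network A [fiber_network()].
#' @param synapses Junction tibble.
#' @return List with `summary` (one row: `n_axons`, `n_axons_ge2`,
#'   `n_axons_multihit`, `pct_axons_multihit_same_dendrite`, `n_dendrites`,
#'   `n_dendrites_with_repeated_partner`,
#'   `pct_dendrites_with_repeated_partner`), `per_axon` and `per_dendrite`
#'   tibbles. Empty inputs give zero counts and `NA` percentages.
#' @export
multi_contact_summary <- function(network, synapses) {
  syn <- assign_targets(synapses, network)
  pairs <- syn[!is.na(syn$axon_id) & !is.na(syn$dendrite_id),
               c("synapse_id", "axon_id", "dendrite_id")]
  cls <- setNames(network$fibers$fiber_class,
                  as.character(network$fibers$fiber_id))
  per_axon <- if (nrow(pairs)) {
    pairs |>
      dplyr::group_by(.data$axon_id) |>
      dplyr::summarise(
        n_synapses = dplyr::n(),
        n_partner_dendrites = dplyr::n_distinct(.data$dendrite_id),
        multihit = max(table(.data$dendrite_id)) >= 2L,
        .groups = "drop") |>
      dplyr::mutate(fiber_class = unname(cls[as.character(.data$axon_id)]))
  } else {
    tibble::tibble(axon_id = integer(), n_synapses = integer(),
                   n_partner_dendrites = integer(), multihit = logical(),
                   fiber_class = character())
  }
  ax2 <- per_axon[per_axon$n_synapses >= 2L, , drop = FALSE]
  dend_ids <- unique(network$attachments$fiber_id[
    network$attachments$side == "post"])
  per_dend <- pairs |>
    dplyr::group_by(.data$dendrite_id, .data$axon_id) |>
    dplyr::summarise(k = dplyr::n(), .groups = "drop_last") |>
    dplyr::summarise(n_multi_contact_partners = sum(.data$k >= 2L),
                     .groups = "drop")
  per_dend <- tibble::tibble(dendrite_id = dend_ids) |>
    dplyr::left_join(per_dend, by = "dendrite_id") |>
    dplyr::mutate(n_multi_contact_partners =
                    dplyr::coalesce(.data$n_multi_contact_partners, 0L))
  n_rep <- sum(per_dend$n_multi_contact_partners >= 1L)
  summary <- tibble::tibble(
    n_axons = nrow(per_axon),
    n_axons_ge2 = nrow(ax2),
    n_axons_multihit = sum(ax2$multihit),
    pct_axons_multihit_same_dendrite =
      if (nrow(ax2)) 100 * sum(ax2$multihit) / nrow(ax2) else NA_real_,
    n_dendrites = nrow(per_dend),
    n_dendrites_with_repeated_partner = n_rep,
    pct_dendrites_with_repeated_partner =
      if (nrow(per_dend)) 100 * n_rep / nrow(per_dend) else NA_real_)
  list(summary = summary, per_axon = per_axon, per_dendrite = per_dend)
}

#' En passant versus terminal bouton percentages per axon class
#'
#' A synapse is attributed to a terminal bouton when its presynaptic
#' attachment node is an endpoint (degree <= 1) of the axon skeleton;
#' otherwise it is en passant. Apparent endpoints at the faces of the
#' imaged volume are truncation artifacts, so when `bounds` is supplied,
#' attachments at endpoints within `censor_margin_um` of a face are flagged
#' censored and excluded from the percentages.
#'
#' @param network A [fiber_network()].
#' @param synapses Junction tibble.
#' @param bounds Optional list with `lo` and `hi` (um) or a
#'   [counting_frame()]/[voxel_grid()] giving the volume extent.
#' @param censor_margin_um Censoring distance from a face.
#' @return Tibble per axon class: counts and percentages of en passant and
#'   terminal synapses (`pct` over uncensored synapses).
#' @export
bouton_shape_summary <- function(network, synapses, bounds = NULL,
                                 censor_margin_um = 0.5) {
  if (inherits(bounds, "voxel_grid")) bounds <- grid_extent_um(bounds)
  if (inherits(bounds, "counting_frame"))
    bounds <- list(lo = bounds$lo, hi = bounds$hi)
  nodes <- network$nodes
  key <- paste(nodes$fiber_id, nodes$node_id)
  parent_key <- paste(nodes$fiber_id, nodes$parent_id)
  n_children <- as.integer(table(factor(parent_key, levels = key)))
  degree <- n_children + as.integer(!is.na(nodes$parent_id))
  is_leaf <- degree <= 1L
  near_face <- rep(FALSE, nrow(nodes))
  if (!is.null(bounds)) {
    p <- as.matrix(nodes[, c("x_um", "y_um", "z_um")])
    d <- pmin(p[, 1] - bounds$lo[1], bounds$hi[1] - p[, 1],
              p[, 2] - bounds$lo[2], bounds$hi[2] - p[, 2],
              p[, 3] - bounds$lo[3], bounds$hi[3] - p[, 3])
    near_face <- d <= censor_margin_um
  }
  att <- network$attachments
  pre <- att[att$side == "pre", , drop = FALSE]
  row <- match(paste(pre$fiber_id, pre$node_id), key)
  cls <- setNames(network$fibers$fiber_class,
                  as.character(network$fibers$fiber_id))
  tibble::tibble(
    fiber_class = unname(cls[as.character(pre$fiber_id)]),
    terminal = is_leaf[row],
    censored = is_leaf[row] & near_face[row]) |>
    dplyr::group_by(.data$fiber_class) |>
    dplyr::summarise(
      n_en_passant = sum(!.data$terminal),
      n_terminal = sum(.data$terminal & !.data$censored),
      n_censored = sum(.data$censored),
      .groups = "drop") |>
    dplyr::mutate(
      n_used = .data$n_en_passant + .data$n_terminal,
      pct_en_passant = ifelse(.data$n_used > 0,
                              100 * .data$n_en_passant / .data$n_used, NA),
      pct_terminal = ifelse(.data$n_used > 0,
                            100 * .data$n_terminal / .data$n_used, NA))
}

#' Correlation between spine and shaft synapse densities
#'
#' Squared Pearson correlation between the per-dendrite linear density of
#' synapses on spines and on the shaft, over included spiny dendrites.
#' Dendritic spines behave as compartments whose synapse numbers are
#' regulated independently of the shaft, so this is typically near zero.
#'
#' @param records Output of [linear_synapse_density()].
#' @return Tibble `r_squared` (NA when either density is constant),
#'   `n_dendrites`.
#' @export
spine_shaft_correlation <- function(records) {
  r <- records[records$fiber_class == "spiny_dendrite" & records$included, ,
               drop = FALSE]
  if (nrow(r) < 3L) abort("need at least 3 included spiny dendrites")
  if (sd(r$density_spines) == 0 || sd(r$density_shaft) == 0)
    return(tibble::tibble(r_squared = NA_real_, n_dendrites = nrow(r)))
  tibble::tibble(r_squared = cor(r$density_spines, r$density_shaft)^2,
                 n_dendrites = nrow(r))
}
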