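#' Label connected components
#'
#' Assigns each segment a dense component label: two segments share a label
#' iff their endpoints are joined by a path of segments. Labels are 0-based
#' and ordered by descending component vascular (cylinder) volume, so the
#' largest component is always component 0.
#'
#' @param net A [vessel_network()].
#' @return The network with `segments$component` filled in.
#' @export
label_components <- function(net) {
  if (nrow(net$segments) == 0) return(net)
  g <- as_igraph(net)
  memb <- igraph::components(g)$membership
  seg_comp <- memb[as.character(net$segments$node_a)]
  vol <- tapply(segment_volume(net$segments$radius, net$segments$length),
                seg_comp, sum)
  ord <- order(-vol)  # ranks igraph component ids by descending volume
  rank_of <- integer(length(vol))
  rank_of[as.integer(names(vol))[ord]] <- seq_along(ord) - 1L
  net$segments$component <- as.integer(rank_of[seg_comp])
  net
}

#' Vascular-density fractions per component
#' @param net A network with labelled components.
#' @return Tibble with `component`, `volume`, `fraction` (fractions sum to 1).
#' @export
component_density <- function(net) {
  sg <- net$segments
  if (nrow(sg) == 0 || anyNA(sg$component)) {
    net <- label_components(net)
    sg <- net$segments
  }
  out <- sg |>
    dplyr::mutate(vol = segment_volume(.data$radius, .data$length)) |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(volume = sum(.data$vol), .groups = "drop") |>
    dplyr::arrange(.data$component)
  out$fraction <- out$volume / sum(out$volume)
  out
}

# Extract one labelled component as a subnetwork (coordinate bbox domain).
extract_component <- function(net, comp) {
  sg <- net$segments[net$segments$component == comp, , drop = FALSE]
  keep <- unique(c(sg$node_a, sg$node_b))
  nd <- net$nodes[net$nodes$id %in% keep, , drop = FALSE]
  vol <- sum(segment_volume(sg$radius, sg$length))
  sub <- structure(
    list(nodes = nd, segments = sg, box = net$box, face_tol = net$face_tol,
         provenance = net$provenance,
         component_id = as.integer(comp),
         origin = c(x = 0, y = 0, z = 0), extent = net$box,
         parent_box = net$box,
         volume_initial = vol, volume_pruned = vol),
    class = c("vessel_subnetwork", "vessel_network")
  )
  update_bbox(sub)
}

#' Retain subnetworks above a vascular-density threshold
#'
#' Connected subnetworks representing at least `threshold` of the complete
#' vascular density (cylinder-volume fraction) are retained; the rest are
#' dropped from downstream simulation. The threshold comparison is inclusive.
#'
#' @param net A [vessel_network()]; components are labelled if needed.
#' @param threshold Minimum density fraction, default 0.15.
#' @return A list of `vessel_subnetwork` objects, each with `volume_initial`
#'   set to its retained vascular volume; empty list for an empty network.
#' @export
filter_by_density <- function(net, threshold = 0.15) {
  if (nrow(net$segments) == 0) return(list())
  if (anyNA(net$segments$component)) net <- label_components(net)
  dens <- component_density(net)
  keep <- dens$component[dens$fraction >= threshold - 1e-12]
  lapply(sort(keep), function(cc) extract_component(net, cc))
}

#' Elongate near-border end branches onto the domain border
#'
#' Degree-1 nodes whose perpendicular distance to a face of the parent domain
#' box is at most `epsilon` are translated onto that face along the face
#' normal; the incident segment's length grows by the displacement and the
#' node acquires the face tag. When a node is within `epsilon` of several
#' faces it snaps to the nearest; ties break toward the lower axis index
#' (x before y before z), low face before high face.
#'
#' @param sub A `vessel_subnetwork` (or network, coerced).
#' @param epsilon Capture distance, μm (default 5).
#' @return The modified subnetwork; the elongation count is in
#'   `attr(, "n_elongated")`.
#' @export
elongate_border_ends <- function(sub, epsilon = 5.0) {
  sub <- as_subnetwork(sub)
  box <- sub$parent_box
  deg <- node_degrees(sub)
  nd <- sub$nodes
  n_moved <- 0L
  for (i in which(deg == 1)) {
    pos <- c(nd$x[i], nd$y[i], nd$z[i])
    # candidate faces: (axis, side) with distances
    d <- c(pos[1], box[1] - pos[1], pos[2], box[2] - pos[2], pos[3], box[3] - pos[3])
    j <- which.min(d)  # ties resolve to lowest index: x_lo,x_hi,y_lo,y_hi,z_lo,z_hi
    if (d[j] > epsilon) next
    if (d[j] <= 0) next  # already on (or beyond within tol of) the face
    axis <- c(1L, 1L, 2L, 2L, 3L, 3L)[j]
    target <- if (j %% 2 == 1) 0 else box[axis]
    ax <- c("x", "y", "z")[axis]
    nd[[ax]][i] <- target
    # extend the single incident segment by the displacement
    sid <- which(sub$segments$node_a == nd$id[i] | sub$segments$node_b == nd$id[i])
    sub$segments$length[sid] <- sub$segments$length[sid] + d[j]
    n_moved <- n_moved + 1L
  }
  sub$nodes <- nd
  sub <- tag_faces(sub)
  # border nodes sit on the parent box; tags must reflect the parent box faces
  sub$nodes <- tag_parent_faces(sub)$nodes
  sub <- update_bbox(sub)
  attr(sub, "n_elongated") <- n_moved
  sub
}

# Tag faces against the parent box (subnetworks keep net$box == parent box).
tag_parent_faces <- function(sub) {
  net <- sub
  net$box <- sub$parent_box
  tag_faces(net)
}

#' Prune blind ends
#'
#' Iteratively removes segments incident to interior (untagged) degree-1
#' nodes until none remain: such branches connect to only one branch and do
#' not touch the volume borders, so they are treated as sprouts or imaging
#' artifacts that would not contribute to the permeability tensor. Border
#' (face-tagged) degree-1 nodes are never pruned. The operation is
#' idempotent. Afterwards `volume_pruned` and the bounding box are
#' recomputed.
#'
#' @param sub A `vessel_subnetwork` (elongation should run first so that
#'   near-border ends are not lost).
#' @return The pruned subnetwork; per-iteration pruned-segment counts are in
#'   `attr(, "pruned_per_iteration")`. A fully pruned subnetwork has zero
#'   segments and is flagged via `attr(, "empty")`.
#' @export
prune_blind_ends <- function(sub) {
  sub <- as_subnetwork(sub)
  sub$nodes <- tag_parent_faces(sub)$nodes
  pruned <- integer()
  repeat {
    deg <- node_degrees(sub)
    interior_end <- sub$nodes$id[deg == 1 & !has_face(sub$nodes$faces)]
    if (length(interior_end) == 0) break
    drop <- sub$segments$node_a %in% interior_end |
            sub$segments$node_b %in% interior_end
    pruned <- c(pruned, sum(drop))
    sub$segments <- sub$segments[!drop, , drop = FALSE]
    keep <- unique(c(sub$segments$node_a, sub$segments$node_b))
    sub$nodes <- sub$nodes[sub$nodes$id %in% keep, , drop = FALSE]
    if (nrow(sub$segments) == 0) break
  }
  sub$volume_pruned <- network_volume(sub)
  sub <- update_bbox(sub)
  attr(sub, "pruned_per_iteration") <- pruned
  attr(sub, "empty") <- nrow(sub$segments) == 0
  sub
}

#' Representative-elementary-volume gate
#'
#' A subnetwork qualifies for tensor computation only when its post-pruning
#' bounding box measures at least `cutoff` along both x and y (inclusive).
#' The z direction is not gated: sample thickness is well below the cutoff.
#'
#' @param sub A pruned `vessel_subnetwork`.
#' @param cutoff Minimum x and y side length, μm (default 170).
#' @return `TRUE` when the subnetwork passes.
#' @export
rev_gate <- function(sub, cutoff = 170) {
  sub <- as_subnetwork(sub)
  all(sub$extent[c("x", "y")] >= cutoff - 1e-9)
}

#' Full preprocessing pipeline
#'
#' Runs, in order: component labelling, density filtering, border-end
#' elongation, blind-end pruning, and the representative-elementary-volume
#' gate. Returns the surviving subnetworks together with a per-component
#' report.
#'
#' @param net A [vessel_network()].
#' @param density_threshold Minimum vascular-density fraction (default 0.15).
#' @param epsilon Border-elongation capture distance, μm (default 5).
#' @param rev_cutoff REV side-length cutoff along x and y, μm (default 170).
#' @return A list with `subnetworks` (REV-passing, non-empty subnetworks) and
#'   `report` (tibble: one row per component with density fraction, retention,
#'   elongation/pruning counts, volumes and REV status).
#' @export
preprocess_network <- function(net, density_threshold = 0.15, epsilon = 5.0,
                               rev_cutoff = 170) {
  net <- label_components(net)
  dens <- component_density(net)
  subs <- filter_by_density(net, density_threshold)
  rows <- list()
  kept <- list()
  for (sub in subs) {
    el <- elongate_border_ends(sub, epsilon)
    pr <- prune_blind_ends(el)
    empty <- isTRUE(attr(pr, "empty"))
    pass <- !empty && rev_gate(pr, rev_cutoff)
    rows[[length(rows) + 1]] <- tibble::tibble(
      component = sub$component_id,
      density_fraction = dens$fraction[dens$component == sub$component_id],
      retained = TRUE,
      n_elongated = attr(el, "n_elongated"),
      n_pruned_segments = sum(attr(pr, "pruned_per_iteration")),
      volume_initial = pr$volume_initial,
      volume_pruned = pr$volume_pruned,
      extent_x = unname(pr$extent["x"]),
      extent_y = unname(pr$extent["y"]),
      extent_z = unname(pr$extent["z"]),
      empty = empty,
      rev_pass = pass
    )
    if (pass) kept[[length(kept) + 1]] <- pr
  }
  dropped <- dens[!(dens$component %in% vapply(subs, `[[`, 0L, "component_id")), ]
  if (nrow(dropped) > 0) {
    rows[[length(rows) + 1]] <- tibble::tibble(
      component = dropped$component,
      density_fraction = dropped$fraction,
      retained = FALSE, n_elongated = NA_integer_,
      n_pruned_segments = NA_integer_,
      volume_initial = dropped$volume, volume_pruned = NA_real_,
      extent_x = NA_real_, extent_y = NA_real_, extent_z = NA_real_,
      empty = NA, rev_pass = FALSE
    )
  }
  report <- dplyr::arrange(dplyr::bind_rows(rows), .data$component)
  list(subnetworks = kept, report = report)
}
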