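#' Construct a vessel network
#'
#' A `vessel_network` is the geometric-graph representation of a microvascular
#' bed: a node table (3D positions in micrometers), a segment table (edges
#' carrying a radius and a geodesic length), and the rectangular domain box the
#' network lives in. All lengths are micrometers, pressures are Pascal
#' internally, viscosities mPa·s, flows μm³/s.
#'
#' @param nodes Data frame with columns `id` (integer), `x`, `y`, `z`
#'   (positions, μm). A `faces` column (comma-separated face tags among
#'   `x_lo, x_hi, y_lo, y_hi, z_lo, z_hi`) is recomputed from geometry.
#' @param segments Data frame with columns `id`, `node_a`, `node_b`,
#'   `radius` (μm) and optionally `length` (μm; filled with the Euclidean
#'   endpoint distance when missing) and `component`.
#' @param box Numeric length-3 vector of per-axis domain extents (μm).
#' @param provenance Free-text metadata string.
#' @param face_tol Tolerance (μm) for tagging nodes as lying on a domain face.
#' @param validate Run [validate_network()] on the result.
#'
#' @return An object of class `vessel_network`: a list with tibbles `nodes`
#'   and `segments`, the `box`, `face_tol` and `provenance`.
#' @export
#' @examples
#' net <- make_single_tube()
#' net
vessel_network <- function(nodes, segments, box, provenance = "",
                           face_tol = 1.0, validate = TRUE) {
  nodes <- tibble::as_tibble(nodes)
  segments <- tibble::as_tibble(segments)
  stopifnot(all(c("id", "x", "y", "z") %in% names(nodes)))
  stopifnot(all(c("id", "node_a", "node_b", "radius") %in% names(segments)))
  nodes$id <- as.integer(nodes$id)
  segments$id <- as.integer(segments$id)
  segments$node_a <- as.integer(segments$node_a)
  segments$node_b <- as.integer(segments$node_b)
  if (!"component" %in% names(segments)) segments$component <- NA_integer_
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stop("`box` must be 3 positive finite extents (μm)", call. = FALSE)
  }
  names(box) <- c("x", "y", "z")

  if (!"length" %in% names(segments)) segments$length <- NA_real_
  if (nrow(segments) > 0 && anyNA(segments$length)) {
    eu <- euclidean_lengths(nodes, segments)
    segments$length <- ifelse(is.na(segments$length), eu, segments$length)
  }
  segments <- segments[, c("id", "node_a", "node_b", "radius", "length", "component")]

  net <- structure(
    list(nodes = nodes, segments = segments, box = box,
         face_tol = face_tol, provenance = provenance),
    class = "vessel_network"
  )
  net$nodes <- tag_faces(net)$nodes
  if (validate) validate_network(net)
  net
}

euclidean_lengths <- function(nodes, segments) {
  ia <- match(segments$node_a, nodes$id)
  ib <- match(segments$node_b, nodes$id)
  sqrt((nodes$x[ia] - nodes$x[ib])^2 +
       (nodes$y[ia] - nodes$y[ib])^2 +
       (nodes$z[ia] - nodes$z[ib])^2)
}

#' Assign domain-face tags to nodes
#'
#' Face tags are a pure function of node position, the domain box and the
#' tolerance: a node is tagged `x_lo` when its x coordinate is within
#' `face_tol` of 0, `x_hi` when within `face_tol` of the box extent, and so on.
#' Re-tagging is idempotent.
#'
#' @param net A [vessel_network()].
#' @param face_tol Tolerance in μm; defaults to the network's own.
#' @return The network with its `nodes$faces` column recomputed.
#' @export
tag_faces <- function(net, face_tol = net$face_tol) {
  nd <- net$nodes
  tags <- character(nrow(nd))
  for (ax in c("x", "y", "z")) {
    lo <- abs(nd[[ax]]) <= face_tol
    hi <- abs(nd[[ax]] - net$box[[ax]]) <= face_tol
    tags <- paste0(tags, ifelse(lo, paste0(",", ax, "_lo"), ""),
                   ifelse(hi, paste0(",", ax, "_hi"), ""))
  }
  nd$faces <- sub("^,", "", tags)
  net$nodes <- nd
  net
}

has_face <- function(faces) !is.na(faces) & faces != ""

#' Validate a vessel network
#'
#' Checks the structural invariants: segment endpoints resolve to existing
#' node ids, no duplicate node or segment ids, radii strictly positive, no
#' self-loops, lengths at least the Euclidean endpoint distance (within
#' tolerance), and all node positions inside the domain box (inclusive, with
#' the face tolerance).
#'
#' @param net A [vessel_network()].
#' @param length_tol Allowed shortfall (μm) of recorded length below the
#'   Euclidean endpoint distance.
#' @return `net`, invisibly; errors describe the offending entity.
#' @export
validate_network <- function(net, length_tol = 1e-6) {
  nd <- net$nodes
  sg <- net$segments
  if (anyDuplicated(nd$id)) stop("duplicate node ids", call. = FALSE)
  if (anyDuplicated(sg$id)) stop("duplicate segment ids", call. = FALSE)
  for (ax in c("x", "y", "z")) {
    bad <- which(nd[[ax]] < -net$face_tol | nd[[ax]] > net$box[[ax]] + net$face_tol)
    if (length(bad)) {
      stop(sprintf("node id %d outside box along %s (%.3f not in [0, %.3f])",
                   nd$id[bad[1]], ax, nd[[ax]][bad[1]], net$box[[ax]]),
           call. = FALSE)
    }
  }
  if (nrow(sg) > 0) {
    if (!all(sg$node_a %in% nd$id) || !all(sg$node_b %in% nd$id)) {
      missing <- setdiff(c(sg$node_a, sg$node_b), nd$id)
      stop("segment endpoint refers to unknown node id ", missing[1], call. = FALSE)
    }
    if (any(sg$radius <= 0)) {
      stop("segment id ", sg$id[which(sg$radius <= 0)[1]],
           " has non-positive radius", call. = FALSE)
    }
    if (any(sg$node_a == sg$node_b)) {
      stop("segment id ", sg$id[which(sg$node_a == sg$node_b)[1]],
           " is a self-loop", call. = FALSE)
    }
    if (any(sg$length <= 0)) {
      stop("segment id ", sg$id[which(sg$length <= 0)[1]],
           " has non-positive length", call. = FALSE)
    }
    eu <- euclidean_lengths(nd, sg)
    short <- which(sg$length < eu - pmax(length_tol, 1e-9 * eu))
    if (length(short)) {
      stop(sprintf("segment id %d length %.6f below endpoint distance %.6f",
                   sg$id[short[1]], sg$length[short[1]], eu[short[1]]),
           call. = FALSE)
    }
  }
  invisible(net)
}

#' Cylinder volume of segments
#'
#' Vascular volume of a segment treated as a circular cylinder, π r² l.
#'
#' @param radius Segment radius, μm (vectorized).
#' @param length Segment length, μm.
#' @return Volume in μm³.
#' @export
#' @examples
#' segment_volume(1, 1) # pi
segment_volume <- function(radius, length) {
  pi * radius^2 * length
}

#' Total vascular (cylinder) volume of a network
#' @param net A [vessel_network()].
#' @return Total μm³ of all segments.
#' @export
network_volume <- function(net) {
  sum(segment_volume(net$segments$radius, net$segments$length))
}

#' Node degrees
#' @param net A [vessel_network()].
#' @return Integer vector of segment-incidence counts, aligned with `net$nodes`.
#' @export
node_degrees <- function(net) {
  cnt <- table(factor(c(net$segments$node_a, net$segments$node_b),
                      levels = net$nodes$id))
  as.integer(cnt)
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("<vessel_network> %d nodes, %d segments, box %.4g x %.4g x %.4g μm\n",
              nrow(x$nodes), nrow(x$segments), x$box[1], x$box[2], x$box[3]))
  ncomp <- length(unique(stats::na.omit(x$segments$component)))
  if (ncomp > 0) cat(sprintf("  components labelled: %d\n", ncomp))
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Coerce a network to a subnetwork
#'
#' A `vessel_subnetwork` is a connected piece of a network together with the
#' rectangular domain used for mirroring and tensor normalization: an `origin`
#' and per-axis `extent`, plus the vascular volumes before (`volume_initial`)
#' and after (`volume_pruned`) blind-end elimination. Coercing a whole network
#' uses the network's own box as the domain.
#'
#' @param net A [vessel_network()].
#' @param component_id Component label carried along (default 0).
#' @return A `vessel_subnetwork`.
#' @export
as_subnetwork <- function(net, component_id = 0L) {
  if (inherits(net, "vessel_subnetwork")) return(net)
  v <- network_volume(net)
  structure(
    c(unclass(net),
      list(component_id = as.integer(component_id),
           origin = c(x = 0, y = 0, z = 0),
           extent = net$box,
           parent_box = net$box,
           volume_initial = v,
           volume_pruned = v)),
    class = c("vessel_subnetwork", "vessel_network")
  )
}

#' @export
print.vessel_subnetwork <- function(x, ...) {
  cat(sprintf("<vessel_subnetwork> component %d: %d nodes, %d segments\n",
              x$component_id, nrow(x$nodes), nrow(x$segments)))
  cat(sprintf("  domain extent %.4g x %.4g x %.4g μm at origin (%.4g, %.4g, %.4g)\n",
              x$extent[1], x$extent[2], x$extent[3],
              x$origin[1], x$origin[2], x$origin[3]))
  cat(sprintf("  vascular volume: %.4g μm³ initial, %.4g μm³ after pruning\n",
              x$volume_initial, x$volume_pruned))
  invisible(x)
}

# Recompute origin/extent from current node coordinates. An axis whose
# coordinate range collapses (a straight or planar component) falls back to
# the full parent-box extent along that axis: the component still occupies
# the slab, and a zero-thickness domain has no face area to normalize by.
update_bbox <- function(sub) {
  if (nrow(sub$nodes) == 0) {
    sub$origin <- c(x = 0, y = 0, z = 0)
    sub$extent <- c(x = 0, y = 0, z = 0)
    return(sub)
  }
  lo <- c(x = min(sub$nodes$x), y = min(sub$nodes$y), z = min(sub$nodes$z))
  hi <- c(x = max(sub$nodes$x), y = max(sub$nodes$y), z = max(sub$nodes$z))
  ext <- hi - lo
  if (!is.null(sub$parent_box)) {
    degen <- ext <= 2 * sub$face_tol
    lo[degen] <- 0
    ext[degen] <- sub$parent_box[degen]
  }
  sub$origin <- lo
  sub$extent <- ext
  sub
}

#' Ratio of pruned to initial vascular volume
#'
#' The fraction of a subnetwork's vascular volume that survives blind-end
#' elimination; its reciprocal is the tensor rescaling factor used during
#' fusion.
#'
#' @param sub A `vessel_subnetwork` with both volumes set.
#' @return A number in (0, 1].
#' @export
volume_ratio <- function(sub) {
  if (!inherits(sub, "vessel_subnetwork")) sub <- as_subnetwork(sub)
  if (sub$volume_initial <= 0) stop("volume_initial is zero", call. = FALSE)
  sub$volume_pruned / sub$volume_initial
}
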