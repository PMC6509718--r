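#' Single axial tube fixture
#'
#' One segment spanning the x faces at the box center: the canonical
#' closed-form fixture with k11 = πr⁴/(8 μ L²) and all other tensor entries
#' zero.
#'
#' @param box Domain extents, μm (default 100³).
#' @param radius Tube radius, μm (default 4); must be below half the
#'   smallest box side.
#' @return A [vessel_network()].
#' @export
make_single_tube <- function(box = c(100, 100, 100), radius = 4) {
  box <- as.numeric(box)
  if (radius >= min(box) / 2) {
    stop("radius must be below half the smallest box side", call. = FALSE)
  }
  nodes <- tibble::tibble(id = 1:2, x = c(0, box[1]),
                          y = box[2] / 2, z = box[3] / 2)
  segments <- tibble::tibble(id = 1L, node_a = 1L, node_b = 2L, radius = radius)
  vessel_network(nodes, segments, box, provenance = "synthetic single tube")
}

#' Parallel axial tubes fixture
#'
#' `n` straight tubes along x, evenly spaced in y at mid-depth z; tensor
#' conductivities add in parallel.
#'
#' @param box Domain extents, μm.
#' @param radii Radius per tube (recycled to `n`), μm.
#' @param n Number of tubes.
#' @return A [vessel_network()].
#' @export
make_parallel_tubes <- function(box = c(100, 100, 100), radii = 4, n = 2) {
  box <- as.numeric(box)
  radii <- rep_len(radii, n)
  ys <- box[2] * seq_len(n) / (n + 1)
  nodes <- tibble::tibble(
    id = seq_len(2 * n),
    x = rep(c(0, box[1]), n),
    y = rep(ys, each = 2),
    z = box[3] / 2
  )
  segments <- tibble::tibble(id = seq_len(n), node_a = 2 * seq_len(n) - 1L,
                             node_b = 2 * seq_len(n), radius = radii)
  vessel_network(nodes, segments, box, provenance = "synthetic parallel tubes")
}

#' Cubic lattice fixture
#'
#' Full 3D grid of equal-radius segments along all three axes with unit-cell
#' closed-form diagonal πr⁴/(8 μ s²).
#'
#' Two constructions are available. The plain grid (`staggered = FALSE`)
#' places node planes on the domain faces; its lines on lateral faces are
#' then shared between periodic images after mirroring, which biases the
#' diagonal upward by the finite-size factor ((2n−1)/(2n−2))² for n node
#' planes per side. The staggered grid (default) offsets every line half a
#' spacing from the lateral faces and reaches the domain faces through
#' perpendicular stubs, so each line carries exactly one s×s unit cell:
#' the closed form is then exact (to solver precision) and mirroring leaves
#' the tensor invariant.
#'
#' @param box Domain extents, μm; `spacing` must divide each extent.
#' @param spacing Lattice spacing s, μm.
#' @param radius Segment radius, μm.
#' @param staggered Use the half-offset construction (default TRUE).
#' @return A [vessel_network()].
#' @export
make_cubic_lattice <- function(box = c(200, 200, 200), spacing = 50, radius = 4,
                               staggered = TRUE) {
  box <- as.numeric(box)
  nper <- box / spacing
  if (any(abs(nper - round(nper)) > 1e-9)) {
    stop("spacing must divide every box extent", call. = FALSE)
  }
  if (staggered) {
    return(make_staggered_lattice(box, spacing, radius))
  }
  nper <- as.integer(round(nper)) + 1L
  grid <- expand.grid(ix = seq_len(nper[1]) - 1L, iy = seq_len(nper[2]) - 1L,
                      iz = seq_len(nper[3]) - 1L)
  nodes <- tibble::tibble(id = seq_len(nrow(grid)),
                          x = grid$ix * spacing, y = grid$iy * spacing,
                          z = grid$iz * spacing)
  idx <- function(ix, iy, iz) 1L + ix + nper[1] * (iy + nper[2] * iz)
  segs <- list()
  for (ax in 1:3) {
    lim <- nper
    lim[ax] <- lim[ax] - 1L
    g <- expand.grid(ix = seq_len(lim[1]) - 1L, iy = seq_len(lim[2]) - 1L,
                     iz = seq_len(lim[3]) - 1L)
    shift <- c(0L, 0L, 0L)
    shift[ax] <- 1L
    segs[[ax]] <- tibble::tibble(
      node_a = idx(g$ix, g$iy, g$iz),
      node_b = idx(g$ix + shift[1], g$iy + shift[2], g$iz + shift[3])
    )
  }
  segments <- dplyr::bind_rows(segs)
  segments$id <- seq_len(nrow(segments))
  segments$radius <- radius
  vessel_network(nodes, segments, box, provenance = "synthetic cubic lattice")
}

# half-offset lattice: core nodes at ((i+1/2)s, (j+1/2)s, (k+1/2)s), each
# boundary-most core node joined to the domain face by a perpendicular stub
make_staggered_lattice <- function(box, spacing, radius) {
  n <- as.integer(round(box / spacing))
  off <- function(ax) (seq_len(n[ax]) - 0.5) * spacing
  core <- expand.grid(ix = seq_len(n[1]), iy = seq_len(n[2]), iz = seq_len(n[3]))
  core_id <- function(ix, iy, iz) ix + n[1] * ((iy - 1L) + n[2] * (iz - 1L))
  nodes <- tibble::tibble(
    id = core_id(core$ix, core$iy, core$iz),
    x = (core$ix - 0.5) * spacing,
    y = (core$iy - 0.5) * spacing,
    z = (core$iz - 0.5) * spacing
  )
  segs <- list()
  for (ax in 1:3) {
    lim <- n
    lim[ax] <- lim[ax] - 1L
    if (lim[ax] >= 1L) {
      g <- expand.grid(ix = seq_len(lim[1]), iy = seq_len(lim[2]),
                       iz = seq_len(lim[3]))
      shift <- c(0L, 0L, 0L)
      shift[ax] <- 1L
      segs[[length(segs) + 1]] <- tibble::tibble(
        node_a = core_id(g$ix, g$iy, g$iz),
        node_b = core_id(g$ix + shift[1], g$iy + shift[2], g$iz + shift[3])
      )
    }
  }
  # stubs to the six faces
  next_id <- nrow(nodes)
  ax_names <- c("x", "y", "z")
  for (ax in 1:3) {
    others <- setdiff(1:3, ax)
    g <- expand.grid(a = seq_len(n[others[1]]), b = seq_len(n[others[2]]))
    for (side in c(0L, 1L)) {
      ijk <- matrix(0L, nrow(g), 3)
      ijk[, others[1]] <- g$a
      ijk[, others[2]] <- g$b
      ijk[, ax] <- if (side == 0L) 1L else n[ax]
      cid <- core_id(ijk[, 1], ijk[, 2], ijk[, 3])
      pos <- cbind((ijk[, 1] - 0.5), (ijk[, 2] - 0.5), (ijk[, 3] - 0.5)) * spacing
      pos[, ax] <- if (side == 0L) 0 else box[ax]
      fid <- next_id + seq_len(nrow(g))
      next_id <- next_id + nrow(g)
      nodes <- dplyr::bind_rows(nodes, tibble::tibble(
        id = fid, x = pos[, 1], y = pos[, 2], z = pos[, 3]))
      segs[[length(segs) + 1]] <- tibble::tibble(node_a = cid, node_b = fid)
    }
  }
  segments <- dplyr::bind_rows(segs)
  segments$id <- seq_len(nrow(segments))
  segments$radius <- radius
  vessel_network(nodes, segments, box,
                 provenance = "synthetic staggered cubic lattice")
}

#' Seeded random capillary bed
#'
#' Emulates thin-slab anatomical capillary networks: a cubic lattice with
#' jittered interior node positions, log-normal radii, a deleted segment
#' fraction that creates blind ends, and an optional detached secondary
#' component mimicking pathology-related disconnections. Boundary nodes keep
#' their face coordinate so the network still spans the domain. Generation
#' is reproducible by seed; if the deletions break x-face-to-face
#' connectivity the network is regenerated (new sub-seed) up to 10 times.
#'
#' @param box Domain extents, μm (default 320 × 320 × 80, a thin myocardial
#'   slab).
#' @param spacing Base lattice spacing, μm (default 40, of the order of
#'   intercapillary distance).
#' @param radius_meanlog,radius_sdlog Log-normal radius parameters (defaults
#'   log(4) and 0.3: median 4 μm capillaries).
#' @param jitter Maximal uniform positional jitter per coordinate, μm.
#' @param blind_end_fraction Fraction of segments deleted at random.
#' @param disconnect_fraction Approximate fraction of segments detached into
#'   a secondary component (0 disables).
#' @param seed Integer seed.
#' @return A [vessel_network()].
#' @export
make_random_capillary <- function(box = c(320, 320, 80), spacing = 40,
                                  radius_meanlog = log(4), radius_sdlog = 0.3,
                                  jitter = 8, blind_end_fraction = 0.1,
                                  disconnect_fraction = 0.05, seed = 1L) {
  for (attempt in 0:9) {
    net <- withr::with_seed(seed + attempt * 1000L, {
      gen_random_capillary(box, spacing, radius_meanlog, radius_sdlog,
                           jitter, blind_end_fraction, disconnect_fraction)
    })
    if (spans_x(net)) {
      net$provenance <- sprintf("synthetic capillary bed seed=%d", seed)
      if (attempt > 0) {
        warning("regenerated ", attempt, " time(s) to obtain a spanning component",
                call. = FALSE)
      }
      return(net)
    }
  }
  stop("no spanning component after 10 attempts; lower blind_end_fraction",
       call. = FALSE)
}

gen_random_capillary <- function(box, spacing, radius_meanlog, radius_sdlog,
                                 jitter, blind_end_fraction,
                                 disconnect_fraction) {
  net <- make_cubic_lattice(box, spacing, radius = 4)
  nd <- net$nodes
  for (ax in c("x", "y", "z")) {
    j <- stats::runif(nrow(nd), -jitter, jitter)
    interior <- nd[[ax]] > 0 & nd[[ax]] < box[[match(ax, c("x", "y", "z"))]]
    nd[[ax]] <- ifelse(interior,
                       pmin(pmax(nd[[ax]] + j, 2), net$box[[ax]] - 2),
                       nd[[ax]])
  }
  sg <- net$segments
  sg$radius <- stats::rlnorm(nrow(sg), radius_meanlog, radius_sdlog)
  # carve blind ends: at randomly chosen interior nodes, delete all but one
  # incident segment, until the requested segment fraction is removed
  ndel <- floor(blind_end_fraction * nrow(sg))
  face_ids <- nd$id[has_face(tag_faces(net)$nodes$faces)]
  deleted <- 0L
  guard <- 0L
  while (deleted < ndel && guard < 10L * ndel + 100L) {
    guard <- guard + 1L
    deg <- table(c(sg$node_a, sg$node_b))
    cand <- setdiff(as.integer(names(deg)[deg >= 2]), face_ids)
    if (length(cand) == 0) break
    v <- cand[sample.int(length(cand), 1)]
    inc <- which(sg$node_a == v | sg$node_b == v)
    kill <- inc[-sample.int(length(inc), 1)]
    kill <- kill[seq_len(min(length(kill), ndel - deleted))]
    if (length(kill) == 0) next
    sg <- sg[-kill, , drop = FALSE]
    deleted <- deleted + length(kill)
  }
  # retract some border ends a few micrometers inside the volume, emulating
  # branches that stop just short of the section border
  end_ids <- intersect(face_ids, names(which(table(c(sg$node_a, sg$node_b)) == 1)))
  for (v in as.integer(end_ids)) {
    if (stats::runif(1) > 0.5) next
    i <- which(nd$id == v)
    pull <- stats::runif(1, 0.5, 3)
    for (axn in 1:3) {
      ax <- c("x", "y", "z")[axn]
      if (abs(nd[[ax]][i]) < 1e-9) nd[[ax]][i] <- pull
      else if (abs(nd[[ax]][i] - box[axn]) < 1e-9) nd[[ax]][i] <- box[axn] - pull
    }
  }
  net2 <- vessel_network(nd, sg[, c("id", "node_a", "node_b", "radius")],
                         box = box, validate = FALSE)
  if (disconnect_fraction > 0) net2 <- detach_component(net2, disconnect_fraction)
  keep <- unique(c(net2$segments$node_a, net2$segments$node_b))
  net2$nodes <- net2$nodes[net2$nodes$id %in% keep, , drop = FALSE]
  validate_network(net2)
  net2
}

# cut the segments joining a grown region to the rest, detaching a secondary
# connected component of roughly the requested segment fraction
detach_component <- function(net, fraction) {
  g <- as_igraph(net)
  target <- max(2, round(fraction * nrow(net$segments)))
  seed_v <- sample(igraph::V(g), 1)
  dist <- igraph::distances(g, v = seed_v)[1, ]
  ord <- order(dist)
  inside <- character(0)
  for (n_v in seq_along(ord)) {
    inside <- names(dist)[ord[seq_len(n_v)]]
    n_inside <- sum(net$segments$node_a %in% as.integer(inside) &
                    net$segments$node_b %in% as.integer(inside))
    if (n_inside >= target) break
  }
  inside <- as.integer(inside)
  boundary <- xor(net$segments$node_a %in% inside, net$segments$node_b %in% inside)
  net$segments <- net$segments[!boundary, , drop = FALSE]
  net
}

spans_x <- function(net, slack = 5) {
  if (nrow(net$segments) == 0) return(FALSE)
  net <- label_components(net)
  nd <- net$nodes
  lo <- nd$id[nd$x <= slack]
  hi <- nd$id[nd$x >= net$box[["x"]] - slack]
  for (cc in unique(net$segments$component)) {
    sg <- net$segments[net$segments$component == cc, ]
    ids <- unique(c(sg$node_a, sg$node_b))
    if (any(lo %in% ids) && any(hi %in% ids)) return(TRUE)
  }
  FALSE
}

#' Infarct-like perturbation of a network
#'
#' Emulates the late post-infarction phenotype — presence of larger vessels
#' and loss of capillaries — by enlarging a seeded random fraction of radii
#' and deleting a seeded random fraction of the small-radius (below-median)
#' segments.
#'
#' @param net A [vessel_network()].
#' @param enlarge_fraction Fraction of segments whose radius is multiplied.
#' @param enlarge_factor Radius multiplier for enlarged segments.
#' @param disconnect_fraction Fraction of below-median-radius segments
#'   deleted.
#' @param seed Integer seed.
#' @return The perturbed network.
#' @export
perturb_mi_like <- function(net, enlarge_fraction = 0.2, enlarge_factor = 1.3,
                            disconnect_fraction = 0.1, seed = 1L) {
  withr::with_seed(seed, {
    sg <- net$segments
    n <- nrow(sg)
    if (enlarge_fraction > 0 && n > 0) {
      k <- round(enlarge_fraction * n)
      if (k > 0) {
        pick <- sample.int(n, k)
        sg$radius[pick] <- sg$radius[pick] * enlarge_factor
      }
    }
    if (disconnect_fraction > 0 && nrow(sg) > 0) {
      small <- which(sg$radius < stats::median(sg$radius))
      k <- round(disconnect_fraction * length(small))
      if (k > 0) sg <- sg[-sample(small, k), , drop = FALSE]
    }
    net$segments <- sg
    keep <- unique(c(sg$node_a, sg$node_b))
    net$nodes <- net$nodes[net$nodes$id %in% keep, , drop = FALSE]
    net$segments$component <- NA_integer_
    net
  })
}
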