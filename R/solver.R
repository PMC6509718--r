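#' Solver configuration
#'
#' @param gradient_pa_per_um Applied pressure gradient, Pa/μm (default 1; the
#'   tensor is invariant to this choice by linearity).
#' @param tol Relative residual tolerance for the nodal-pressure solve.
#' @param min_radius Radius floor (μm) guarding conductances against
#'   numerical underflow; thinner segments are treated as this radius with a
#'   warning.
#' @return A list of class `solver_config`.
#' @export
solver_config <- function(gradient_pa_per_um = 1, tol = 1e-10, min_radius = 0.1) {
  stopifnot(gradient_pa_per_um > 0, tol > 0, min_radius > 0)
  structure(list(gradient_pa_per_um = gradient_pa_per_um, tol = tol,
                 min_radius = min_radius),
            class = "solver_config")
}

#' Mirror a subnetwork into a spatially periodic domain
#'
#' Reflects the subnetwork successively across its upper x, y and z domain
#' faces, producing a domain of doubled extents containing 8 flipped copies.
#' Opposite outer faces of the result are mirror-identical, so every
#' lateral-face node has an exact periodic partner: this converts an
#' arbitrary anatomical network into one on which periodic (Darcy
#' homogenization) boundary conditions are legitimate. Nodes lying on a
#' mirror plane (within the face tolerance) merge with their own image;
#' segments lying entirely in a plane are not duplicated.
#'
#' @param sub A `vessel_subnetwork` (or network, coerced); coordinates are
#'   translated so the domain origin is 0.
#' @param times Number of mirroring passes (2 gives the 4x-extent
#'   double-mirrored domain used to validate mirroring invariance).
#' @return A `mirrored_network` (also a `vessel_network`) whose `box` is the
#'   mirrored extent.
#' @export
mirror_network <- function(sub, times = 1L) {
  sub <- as_subnetwork(sub)
  nd <- sub$nodes
  nd$x <- nd$x - sub$origin[["x"]]
  nd$y <- nd$y - sub$origin[["y"]]
  nd$z <- nd$z - sub$origin[["z"]]
  sg <- sub$segments
  box <- pmax(sub$extent, 0)
  tol <- sub$face_tol
  if (any(box <= 0)) {
    stop("degenerate domain extent; cannot mirror a zero-thickness box",
         call. = FALSE)
  }
  for (pass in seq_len(times)) {
    for (ax in c("x", "y", "z")) {
      e <- box[[ax]]
      on_plane <- abs(nd[[ax]] - e) <= tol
      img <- nd[!on_plane, , drop = FALSE]
      next_id <- max(nd$id) + 1L
      img_ids <- seq.int(next_id, length.out = nrow(img))
      id_map <- nd$id
      names(id_map) <- as.character(nd$id)
      id_map[!on_plane] <- img_ids     # image of each node (itself if on plane)
      img$id <- img_ids
      img[[ax]] <- 2 * e - img[[ax]]
      both_on_plane <- on_plane[match(sg$node_a, nd$id)] &
                       on_plane[match(sg$node_b, nd$id)]
      sgi <- sg[!both_on_plane, , drop = FALSE]
      sgi$node_a <- unname(id_map[as.character(sgi$node_a)])
      sgi$node_b <- unname(id_map[as.character(sgi$node_b)])
      sgi$id <- max(sg$id) + seq_len(nrow(sgi))
      nd <- dplyr::bind_rows(nd, img)
      sg <- dplyr::bind_rows(sg, sgi)
      box[[ax]] <- 2 * e
    }
  }
  net <- structure(
    list(nodes = nd, segments = sg, box = box, face_tol = tol,
         provenance = sub$provenance, mirror_times = times,
         source_extent = sub$extent),
    class = c("mirrored_network", "vessel_network")
  )
  net$nodes <- tag_faces(net)$nodes
  net
}

# face membership helpers on a mirrored network
face_nodes <- function(net, axis, side) {
  coord <- net$nodes[[axis]]
  if (side == "lo") which(abs(coord) <= net$face_tol)
  else which(abs(coord - net$box[[axis]]) <= net$face_tol)
}

# exact-match key of the two in-face coordinates
inface_key <- function(net, idx, axis) {
  others <- setdiff(c("x", "y", "z"), axis)
  paste(sprintf("%.9g", net$nodes[[others[1]]][idx]),
        sprintf("%.9g", net$nodes[[others[2]]][idx]))
}

#' Assemble and solve the nodal-pressure system
#'
#' Imposes a uniform pressure gradient along `direction`: Dirichlet pressures
#' L·∇p on the inflow face and 0 on the outflow face, with each lateral-face
#' periodic pair merged into a single unknown (equal pressure, conserved
#' flow). Interior nodes satisfy Kirchhoff's current law with Poiseuille
#' conductances g = πr⁴/(8μl). The sparse symmetric system is solved by
#' direct factorization. Components with no face-to-face connectivity along
#' `direction` carry zero flow; if no component spans the two faces the
#' all-zero state is returned (a legitimate zero-permeability direction).
#'
#' @param mir A [mirror_network()] result.
#' @param direction `"x"`, `"y"` or `"z"`.
#' @param rheo A [rheology_params()].
#' @param solver A [solver_config()].
#' @param hct Optional per-segment discharge hematocrit (defaults to the
#'   inlet value everywhere); determines viscosity via the in-vitro law.
#' @return A `flow_state` list: per-node `pressure` (Pa, named by node id),
#'   per-segment `flow` (μm³/s, signed node_a→node_b), `dp` (Pa),
#'   `viscosity` (mPa·s), `hct`, `direction`, `gradient`, the periodic
#'   `node_rep` map, and the relative `residual`.
#' @export
assemble_and_solve <- function(mir, direction = c("x", "y", "z"),
                               rheo = rheology_params(),
                               solver = solver_config(), hct = NULL) {
  direction <- match.arg(direction)
  nd <- mir$nodes
  sg <- mir$segments
  n_node <- nrow(nd)
  n_seg <- nrow(sg)
  if (is.null(hct)) hct <- rep(rheo$inlet_hct, n_seg)
  r_eff <- sg$radius
  if (any(r_eff < solver$min_radius)) {
    warning("segments below the ", solver$min_radius,
            " μm radius guard treated at the guard radius", call. = FALSE)
    r_eff <- pmax(r_eff, solver$min_radius)
  }
  visc <- segment_viscosity(r_eff, hct, rheo)            # mPa·s
  g <- pi * r_eff^4 / (8 * visc * 1e-3 * sg$length)      # μm³/(Pa·s)

  L <- mir$box
  grad <- solver$gradient_pa_per_um
  p_in_val <- grad * L[[direction]]

  zero_state <- function() {
    list(pressure = stats::setNames(rep(0, n_node), nd$id),
         flow = rep(0, n_seg), dp = rep(0, n_seg), viscosity = visc,
         hct = hct, direction = direction, gradient = grad,
         node_rep = stats::setNames(nd$id, nd$id), residual = 0)
  }
  if (n_seg == 0) return(zero_state())

  row_in <- face_nodes(mir, direction, "lo")
  row_out <- face_nodes(mir, direction, "hi")
  if (length(row_in) == 0 || length(row_out) == 0) return(zero_state())
  dirichlet <- rep(NA_real_, n_node)
  dirichlet[row_in] <- p_in_val
  dirichlet[row_out] <- 0
  is_dir <- !is.na(dirichlet)

  # union-find over node rows for periodic lateral pairs
  parent <- seq_len(n_node)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (ax in setdiff(c("x", "y", "z"), direction)) {
    lo <- setdiff(face_nodes(mir, ax, "lo"), which(is_dir))
    hi <- setdiff(face_nodes(mir, ax, "hi"), which(is_dir))
    if (length(lo) == 0 || length(hi) == 0) next
    m <- match(inface_key(mir, lo, ax), inface_key(mir, hi, ax))
    if (anyNA(m)) {
      stop("unpaired periodic node on face ", ax, "_lo (node id ",
           nd$id[lo[which(is.na(m))[1]]], ")", call. = FALSE)
    }
    for (k in seq_along(lo)) {
      ra <- find(lo[k]); rb <- find(hi[m[k]])
      if (ra != rb) parent[rb] <- ra
    }
  }
  rep_row <- vapply(seq_len(n_node), find, integer(1))

  ia <- rep_row[match(sg$node_a, nd$id)]
  ib <- rep_row[match(sg$node_b, nd$id)]
  live <- ia != ib
  if (!any(live)) return(zero_state())

  # connectivity: solve only components reachable from Dirichlet nodes,
  # and only if some component contains both faces
  gg <- igraph::graph_from_edgelist(cbind(ia[live], ib[live]), directed = FALSE)
  gg <- igraph::add_vertices(gg, max(0, n_node - igraph::vcount(gg)))
  memb <- igraph::components(gg)$membership
  comp_in <- unique(memb[rep_row[row_in]])
  comp_out <- unique(memb[rep_row[row_out]])
  spanning <- intersect(comp_in, comp_out)
  if (length(spanning) == 0) return(zero_state())

  reps <- sort(unique(rep_row))
  rep_dir <- dirichlet[reps]            # Dirichlet value per representative
  # a representative group inherits any member's Dirichlet value
  grp_dir <- tapply(dirichlet, rep_row, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else v[1]
  })
  rep_dir <- as.numeric(grp_dir[as.character(reps)])
  active_rep <- memb[reps] %in% unique(memb[rep_row[c(row_in, row_out)]])
  unknown <- which(is.na(rep_dir) & active_rep)
  uidx <- rep(NA_integer_, n_node)
  uidx[reps[unknown]] <- seq_along(unknown)

  pressure_rep <- rep(0, n_node)        # indexed by representative row
  pressure_rep[reps] <- ifelse(is.na(rep_dir), 0, rep_dir)

  if (length(unknown) > 0) {
    ea <- ia[live]; eb <- ib[live]; ew <- g[live]
    ua <- uidx[ea]; ub <- uidx[eb]
    nu <- length(unknown)
    # off-diagonal contributions between unknowns
    both <- !is.na(ua) & !is.na(ub)
    trip_i <- c(ua[both], ub[both])
    trip_j <- c(ub[both], ua[both])
    trip_x <- c(-ew[both], -ew[both])
    # diagonal: every live edge incident to an unknown
    diag_i <- c(ua[!is.na(ua)], ub[!is.na(ub)])
    diag_x <- c(ew[!is.na(ua)], ew[!is.na(ub)])
    A <- Matrix::sparseMatrix(i = c(trip_i, diag_i), j = c(trip_j, diag_i),
                              x = c(trip_x, diag_x), dims = c(nu, nu))
    # rhs from Dirichlet neighbours
    b <- rep(0, nu)
    bnd_a <- !is.na(ua) & is.na(ub)
    bnd_b <- is.na(ua) & !is.na(ub)
    if (any(bnd_a)) {
      contrib <- ew[bnd_a] * pressure_rep[eb[bnd_a]]
      b <- b + as.numeric(tapply_add(contrib, ua[bnd_a], nu))
    }
    if (any(bnd_b)) {
      contrib <- ew[bnd_b] * pressure_rep[ea[bnd_b]]
      b <- b + as.numeric(tapply_add(contrib, ub[bnd_b], nu))
    }
    A <- Matrix::forceSymmetric(A)
    p_u <- tryCatch(as.numeric(Matrix::solve(A, b)),
                    error = function(e) stop("singular nodal-pressure system: ",
                                             conditionMessage(e), call. = FALSE))
    res <- sqrt(sum((as.numeric(A %*% p_u) - b)^2))
    nb <- sqrt(sum(b^2))
    residual <- if (nb > 0) res / nb else res
    if (residual > solver$tol * 1e3) {
      warning(sprintf("nodal solve residual %.3g exceeds tolerance", residual),
              call. = FALSE)
    }
    pressure_rep[reps[unknown]] <- p_u
  } else {
    residual <- 0
  }

  pressure <- pressure_rep[rep_row]
  dp <- pressure[match(sg$node_a, nd$id)] - pressure[match(sg$node_b, nd$id)]
  dp[ia == ib] <- 0
  flow <- g * dp
  list(pressure = stats::setNames(pressure, nd$id), flow = flow, dp = dp,
       viscosity = visc, hct = hct, direction = direction, gradient = grad,
       node_rep = stats::setNames(nd$id[rep_row], nd$id), residual = residual)
}

tapply_add <- function(x, idx, n) {
  out <- rep(0, n)
  s <- tapply(x, idx, sum)
  out[as.integer(names(s))] <- as.numeric(s)
  out
}

#' Net flux through a domain face
#'
#' Sum of signed segment flows crossing the upper face along `axis`, oriented
#' outward (+axis). For the gradient direction this is the outflow through
#' the Dirichlet face; for lateral axes it is the cross-flow carried through
#' the periodic face. By conservation the outflow equals the inflow-face
#' influx to solver tolerance.
#'
#' @param mir The mirrored network that was solved.
#' @param state A `flow_state` from [assemble_and_solve()].
#' @param axis Face axis (defaults to the gradient direction).
#' @param side `"hi"` (outflow, default) or `"lo"` (influx, oriented inward).
#' @return Flux in μm³/s.
#' @export
surface_flux <- function(mir, state, axis = state$direction, side = "hi") {
  nd <- mir$nodes
  sg <- mir$segments
  idx <- face_nodes(mir, axis, side)
  if (axis != state$direction) {
    # periodic face: exclude Dirichlet (gradient-face) nodes, whose flux
    # leaves through the pressure boundary instead
    dir_rows <- c(face_nodes(mir, state$direction, "lo"),
                  face_nodes(mir, state$direction, "hi"))
    idx <- setdiff(idx, dir_rows)
  }
  ids <- nd$id[idx]
  into_face <- (sg$node_b %in% ids) - (sg$node_a %in% ids)
  total <- sum(into_face * state$flow)
  if (side == "lo") -total else total
}
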