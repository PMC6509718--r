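AXES <- c("x", "y", "z")
UM2_PER_PAS_TO_MM3S_PER_KG <- 1e-3  # 1 μm²/(Pa·s) = 1e-3 mm³·s/kg

new_permeability_tensor <- function(k, sorted = FALSE, permutation = 1:3,
                                    hct_mode = "constant_hct", meta = list()) {
  dimnames(k) <- list(AXES, AXES)
  structure(list(k = k, sorted = sorted, permutation = permutation,
                 hct_mode = hct_mode, meta = meta),
            class = "permeability_tensor")
}

#' Darcy permeability tensor of a subnetwork
#'
#' Mirrors the subnetwork into a spatially periodic domain, solves the
#' Poiseuille nodal-pressure system for a unit pressure gradient along each
#' axis in turn, and forms the 3×3 tensor \eqn{k_{ij} = M_j / (S_j \nabla
#' p^i)} where \eqn{M_j} is the net flux through the face normal to axis j
#' and \eqn{S_j} the mirrored-domain face area. Diagonal entries are
#' through-flow conductivities; off-diagonals capture cross-flow through the
#' periodic lateral faces. Units are mm³·s/kg.
#'
#' In `phase_separation` mode the solve alternates with a damped hematocrit
#' update (red-cell phase separation at bifurcations, viscosity recomputed
#' each pass) until the hematocrit field reaches its fixed point.
#'
#' @param sub A preprocessed `vessel_subnetwork`, or a whole
#'   [vessel_network()] (its box becomes the domain).
#' @param rheo A [rheology_params()].
#' @param solver A [solver_config()].
#' @param mirror_times Mirroring passes (2 = validation double mirror).
#' @return A `permeability_tensor` (unsorted): 3×3 matrix `k` plus metadata
#'   (surfaces, extents, volume ratio, hematocrit convergence per direction).
#' @export
#' @examples
#' k <- permeability_tensor(make_single_tube(),
#'                          rheo = rheology_params(1, 0))
#' k$k["x", "x"] # ~ pi * 4^4 / (8e-3 * 100^2) * 1e-3
permeability_tensor <- function(sub, rheo = rheology_params(),
                                solver = solver_config(), mirror_times = 1L) {
  sub <- as_subnetwork(sub)
  if (nrow(sub$segments) == 0) {
    return(new_permeability_tensor(matrix(0, 3, 3), hct_mode = rheo$mode,
                                   meta = list(empty = TRUE)))
  }
  mir <- mirror_network(sub, times = mirror_times)
  L <- mir$box
  S <- c(x = L[["y"]] * L[["z"]], y = L[["x"]] * L[["z"]], z = L[["x"]] * L[["y"]])
  k <- matrix(0, 3, 3)
  converged <- rep(TRUE, 3)
  iterations <- rep(0L, 3)
  for (i in seq_along(AXES)) {
    di <- AXES[i]
    if (rheo$mode == "phase_separation") {
      st <- iterate_phase_separation(mir, di, rheo, solver)
      converged[i] <- st$hct_converged
      iterations[i] <- st$hct_iterations
    } else {
      st <- assemble_and_solve(mir, di, rheo, solver)
    }
    for (j in seq_along(AXES)) {
      flux <- surface_flux(mir, st, AXES[j])
      k[i, j] <- flux / (S[[AXES[j]]] * st$gradient) * UM2_PER_PAS_TO_MM3S_PER_KG
    }
  }
  if (!all(converged)) {
    warning("hematocrit iteration did not converge in directions: ",
            paste(AXES[!converged], collapse = ", "), call. = FALSE)
  }
  new_permeability_tensor(
    k, hct_mode = rheo$mode,
    meta = list(surfaces = S, extent = L, mirror_times = mirror_times,
                volume_initial = sub$volume_initial,
                volume_pruned = sub$volume_pruned,
                component_id = sub$component_id,
                hct_converged = converged, hct_iterations = iterations))
}

# Alternate nodal solve and damped hematocrit update to the fixed point.
iterate_phase_separation <- function(mir, direction, rheo, solver) {
  h <- rep(rheo$inlet_hct, nrow(mir$segments))
  st <- NULL
  converged <- FALSE
  it <- 0L
  for (it in seq_len(rheo$max_iter)) {
    st <- assemble_and_solve(mir, direction, rheo, solver, hct = h)
    st2 <- update_hematocrit(mir, st, rheo)
    delta <- max(abs(st2$hct - h))
    h <- st2$hct
    if (delta < rheo$hct_tol) {
      converged <- TRUE
      break
    }
  }
  # final solve with the converged hematocrit field
  st <- assemble_and_solve(mir, direction, rheo, solver, hct = h)
  st$hct_converged <- converged
  st$hct_iterations <- it
  st
}

#' Sort a permeability tensor by descending diagonal
#'
#' Applies the simultaneous row and column permutation that orders the
#' diagonal in descending order, so direction 1 is the direction of maximum
#' flow. Off-diagonal entry (i, j) moves to (σ(i), σ(j)); eigenvalues are
#' preserved. Ties keep the axis order x, y, z.
#'
#' @param t A `permeability_tensor`.
#' @return The sorted tensor with its `permutation` recorded.
#' @export
sort_tensor <- function(t) {
  stopifnot(inherits(t, "permeability_tensor"))
  if (t$sorted) return(t)
  perm <- order(-diag(t$k))  # stable: ties keep x,y,z order
  t$k <- t$k[perm, perm, drop = FALSE]
  dimnames(t$k) <- list(AXES, AXES)
  t$permutation <- perm
  t$sorted <- TRUE
  t
}

# bbox face area of a subnetwork perpendicular to axis j (mirrored extents)
sub_surface <- function(sub, j) {
  e <- 2 * sub$extent
  others <- setdiff(AXES, j)
  e[[others[1]]] * e[[others[2]]]
}

# overlap area of two subnetwork bbox projections perpendicular to axis j
projected_overlap <- function(sub_a, sub_b, j) {
  others <- setdiff(AXES, j)
  prod(vapply(others, function(ax) {
    lo <- max(sub_a$origin[[ax]], sub_b$origin[[ax]])
    hi <- min(sub_a$origin[[ax]] + sub_a$extent[[ax]],
              sub_b$origin[[ax]] + sub_b$extent[[ax]])
    4 * max(0, hi - lo)  # mirrored extents double each in-face side
  }, numeric(1))) / 4   # (2a)(2b) = 4ab; one factor of 4 total
}

#' Fuse per-subnetwork tensors into a volume tensor
#'
#' Weighted-average fusion for independent parallel subnetworks: the volume
#' tensor is \eqn{k_{ij}(I) = \sum_{cc} w_{ij}(cc)\, s(cc)\, k_{ij}(cc)} with
#' surface weights \eqn{w_{ij}(cc) = S_j(cc) / (\sum S_j - \sum_{n<k}
#' S_j(n)\cap S_j(k))}: each subnetwork's outflow-face area divided by the
#' union area covered by all subnetworks (pairwise overlaps of the projected
#' bounding boxes subtracted). The optional scale \eqn{s(cc) =
#' V_{init}/V_{pruned} \ge 1} compensates the vascular volume lost to
#' blind-end elimination; `apply_scale = FALSE` reproduces the unscaled
#' variant.
#'
#' @param subs List of `vessel_subnetwork` objects.
#' @param tensors List of matching unsorted `permeability_tensor` objects.
#' @param apply_scale Apply the volume-ratio rescaling (default TRUE).
#' @return A fused `permeability_tensor`; per-subnetwork surfaces, weights
#'   and scales are recorded in `meta$fusion` (a tibble).
#' @export
fuse_tensors <- function(subs, tensors, apply_scale = TRUE) {
  stopifnot(length(subs) == length(tensors), length(subs) >= 1)
  if (any(vapply(tensors, function(t) t$sorted, logical(1)))) {
    stop("fuse unsorted tensors; sort after fusion", call. = FALSE)
  }
  modes <- unique(vapply(tensors, function(t) t$hct_mode, character(1)))
  if (length(modes) > 1) stop("tensors mix hematocrit modes", call. = FALSE)
  m <- length(subs)
  k <- matrix(0, 3, 3)
  recs <- list()
  for (j_ax in AXES) {
    s_j <- vapply(subs, sub_surface, numeric(1), j = j_ax)
    ov <- 0
    if (m > 1) {
      for (n in seq_len(m - 1)) for (kk in seq.int(n + 1, m)) {
        ov <- ov + projected_overlap(subs[[n]], subs[[kk]], j_ax)
      }
    }
    denom <- sum(s_j) - ov
    if (denom <= 0) stop("degenerate fusion surface along ", j_ax, call. = FALSE)
    w <- s_j / denom
    scale <- if (apply_scale) {
      vapply(subs, function(s) 1 / volume_ratio(s), numeric(1))
    } else rep(1, m)
    jj <- match(j_ax, AXES)
    for (cc in seq_len(m)) {
      k[, jj] <- k[, jj] + w[cc] * scale[cc] * tensors[[cc]]$k[, jj]
    }
    recs[[j_ax]] <- tibble::tibble(
      direction = j_ax, subnetwork = seq_len(m), surface = s_j,
      denominator = denom, weight = w, scale = scale)
  }
  new_permeability_tensor(
    k, hct_mode = modes,
    meta = list(fusion = dplyr::bind_rows(recs), apply_scale = apply_scale,
                n_subnetworks = m))
}

#' Scan tensor dependence on unit size
#'
#' Partitions the domain along x and y into square units of each requested
#' side length (the full z thickness is kept, matching thin-slab data), runs
#' the complete per-unit pipeline (preprocess, mirror, solve, fuse) on each
#' unit, and reports per-unit sorted diagonals plus their median per size.
#' Units whose subnetworks all fail the representative-elementary-volume
#' gate yield no tensor and are flagged.
#'
#' @param net A [vessel_network()].
#' @param unit_sizes Numeric vector of unit side lengths, μm. Units larger
#'   than the domain use a single unit (the whole domain).
#' @param rheo,solver Passed to [permeability_tensor()].
#' @param density_threshold,epsilon,rev_cutoff Passed to
#'   [preprocess_network()]; set `rev_cutoff = 0` to disable gating for
#'   homogeneity scans below the anatomical cutoff.
#' @return A tibble with one row per unit and size: unit origin, `k11`,
#'   `k22`, `k33` (sorted diagonal, mm³·s/kg), `excluded` flag, and
#'   per-size medians in `attr(, "summary")`.
#' @export
rev_scan <- function(net, unit_sizes, rheo = rheology_params(),
                     solver = solver_config(), density_threshold = 0.15,
                     epsilon = 5.0, rev_cutoff = 170) {
  rows <- list()
  for (u in unit_sizes) {
    nx <- max(1L, floor(net$box[["x"]] / u))
    ny <- max(1L, floor(net$box[["y"]] / u))
    ux <- net$box[["x"]] / nx
    uy <- net$box[["y"]] / ny
    for (ix in seq_len(nx) - 1L) for (iy in seq_len(ny) - 1L) {
      lo <- c(ix * ux, iy * uy, 0)
      hi <- c((ix + 1) * ux, (iy + 1) * uy, net$box[["z"]])
      unit <- crop_network(net, lo, hi)
      res <- tibble::tibble(unit_size = u, origin_x = lo[1], origin_y = lo[2],
                            k11 = NA_real_, k22 = NA_real_, k33 = NA_real_,
                            excluded = TRUE, reason = "no retained subnetwork")
      if (nrow(unit$segments) > 0) {
        pp <- preprocess_network(unit, density_threshold, epsilon, rev_cutoff)
        if (length(pp$subnetworks) > 0) {
          tens <- lapply(pp$subnetworks, permeability_tensor,
                         rheo = rheo, solver = solver)
          fused <- sort_tensor(fuse_tensors(pp$subnetworks, tens))
          res$k11 <- fused$k[1, 1]; res$k22 <- fused$k[2, 2]
          res$k33 <- fused$k[3, 3]
          res$excluded <- FALSE; res$reason <- NA_character_
        } else if (any(!pp$report$rev_pass)) {
          res$reason <- "below REV cutoff"
        }
      }
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  summary <- out |>
    dplyr::filter(!.data$excluded) |>
    dplyr::group_by(.data$unit_size) |>
    dplyr::summarise(median_k11 = stats::median(.data$k11),
                     median_k22 = stats::median(.data$k22),
                     median_k33 = stats::median(.data$k33),
                     n_units = dplyr::n(), .groups = "drop")
  attr(out, "summary") <- summary
  out
}

# Crop to the unit box [lo, hi]: nodes inside are kept, segments crossing
# the boundary are clipped at it (a new boundary node is created and the
# length shortened proportionally) exactly as decomposing an image volume
# would cut vessels at subvolume borders; segments fully outside are
# dropped. Coordinates are re-offset to the unit origin.
crop_network <- function(net, lo, hi) {
  nd <- net$nodes
  tol <- net$face_tol
  co <- cbind(nd$x, nd$y, nd$z)
  inside <- co[, 1] >= lo[1] - tol & co[, 1] <= hi[1] + tol &
            co[, 2] >= lo[2] - tol & co[, 2] <= hi[2] + tol &
            co[, 3] >= lo[3] - tol & co[, 3] <= hi[3] + tol
  in_of <- stats::setNames(inside, nd$id)
  sg <- net$segments
  a_in <- unname(in_of[as.character(sg$node_a)])
  b_in <- unname(in_of[as.character(sg$node_b)])
  keep_sg <- sg[a_in & b_in, , drop = FALSE]
  cross <- sg[xor(a_in, b_in), , drop = FALSE]
  cross_a_in <- a_in[xor(a_in, b_in)]
  new_nodes <- list()
  next_id <- if (nrow(nd)) max(nd$id) else 0L
  if (nrow(cross) > 0) {
    pos <- function(ids) co[match(ids, nd$id), , drop = FALSE]
    p_in <- pos(ifelse(cross_a_in, cross$node_a, cross$node_b))
    p_out <- pos(ifelse(cross_a_in, cross$node_b, cross$node_a))
    for (s in seq_len(nrow(cross))) {
      # slab clipping: largest t in (0,1] keeping p_in + t (p_out - p_in)
      # inside the unit box
      t_exit <- 1
      for (ax in 1:3) {
        delta <- p_out[s, ax] - p_in[s, ax]
        if (delta > 0) t_exit <- min(t_exit, (hi[ax] - p_in[s, ax]) / delta)
        if (delta < 0) t_exit <- min(t_exit, (lo[ax] - p_in[s, ax]) / delta)
      }
      if (t_exit <= 1e-6) next    # inside endpoint already on the border
      next_id <- next_id + 1L
      bp <- p_in[s, ] + t_exit * (p_out[s, ] - p_in[s, ])
      new_nodes[[length(new_nodes) + 1]] <- tibble::tibble(
        id = next_id, x = bp[1], y = bp[2], z = bp[3])
      stub <- cross[s, , drop = FALSE]
      if (cross_a_in[s]) stub$node_b <- next_id else stub$node_a <- next_id
      stub$length <- stub$length * t_exit
      keep_sg <- dplyr::bind_rows(keep_sg, stub)
    }
  }
  nd <- dplyr::bind_rows(nd[inside, , drop = FALSE],
                         if (length(new_nodes)) dplyr::bind_rows(new_nodes))
  used <- unique(c(keep_sg$node_a, keep_sg$node_b))
  nd <- nd[nd$id %in% used, , drop = FALSE]
  nd$x <- pmin(pmax(nd$x - lo[1], 0), hi[1] - lo[1])
  nd$y <- pmin(pmax(nd$y - lo[2], 0), hi[2] - lo[2])
  nd$z <- pmin(pmax(nd$z - lo[3], 0), hi[3] - lo[3])
  keep_sg$component <- NA_integer_
  vessel_network(nd, keep_sg, box = hi - lo, provenance = net$provenance,
                 face_tol = tol, validate = FALSE)
}

#' @export
print.permeability_tensor <- function(x, ...) {
  cat(sprintf("<permeability_tensor> (%s%s) mm³·s/kg\n",
              x$hct_mode, if (x$sorted) ", sorted" else ""))
  print(signif(x$k, 4))
  invisible(x)
}

#' Tidy a permeability tensor into a long tibble
#'
#' @param x A `permeability_tensor`.
#' @param ... Unused.
#' @return Tibble with columns `i`, `j`, `element` (e.g. "k11") and
#'   `value` (mm³·s/kg).
#' @export
tidy.permeability_tensor <- function(x, ...) {
  idx <- expand.grid(i = 1:3, j = 1:3)
  tibble::tibble(
    i = idx$i, j = idx$j,
    element = paste0("k", idx$i, idx$j),
    value = x$k[cbind(idx$i, idx$j)]
  ) |> dplyr::arrange(.data$i, .data$j)
}

#' One-row summary of a permeability tensor
#' @param x A `permeability_tensor`.
#' @param ... Unused.
#' @return Tibble with `k11`, `k22`, `k33`, anisotropy ratio `k11/k33`,
#'   `sorted`, `hct_mode`.
#' @export
glance.permeability_tensor <- function(x, ...) {
  d <- unname(diag(x$k))
  tibble::tibble(k11 = d[1], k22 = d[2], k33 = d[3],
                 anisotropy = ifelse(d[3] > 0, d[1] / d[3], NA_real_),
                 sorted = x$sorted, hct_mode = x$hct_mode)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a permeability tensor
#' @param object A `permeability_tensor`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permeability_tensor <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$j), y = factor(.data$i),
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$value, 3)),
                       color = "white") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "flux direction j", y = "gradient direction i",
                  fill = "k (mm³·s/kg)",
                  title = "Darcy permeability tensor") +
    ggplot2::theme_minimal()
}

#' Median tensor diagonal versus unit size
#' @param object A [rev_scan()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_rev_scan <- function(object, ...) {
  s <- attr(object, "summary")
  df <- tidyr::pivot_longer(s, dplyr::starts_with("median_"),
                            names_to = "element", values_to = "k",
                            names_prefix = "median_")
  ggplot2::ggplot(df, ggplot2::aes(.data$unit_size, .data$k,
                                   color = .data$element)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "unit side length (μm)", y = "median k (mm³·s/kg)",
                  title = "Permeability versus representative volume size") +
    ggplot2::theme_minimal()
}
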