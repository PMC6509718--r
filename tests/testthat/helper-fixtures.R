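# Fixtures built in code and independent oracles used across tests.

# Y-fixture: trunk of two r=4 segments spanning x (volume 1600*pi) plus an
# interior blind side branch of volume 100*pi (r=2, l=25).
make_y_fixture <- function() {
  nodes <- tibble::tibble(
    id = 1:4,
    x = c(0, 50, 100, 50),
    y = c(50, 50, 50, 75),
    z = c(50, 50, 50, 50)
  )
  segments <- tibble::tibble(
    id = 1:3,
    node_a = c(1L, 2L, 2L),
    node_b = c(2L, 3L, 4L),
    radius = c(4, 4, 2)
  )
  vessel_network(nodes, segments, box = c(100, 100, 100))
}

# two disjoint axial tubes with controllable radii (different components)
make_two_tube_net <- function(r1 = 4, r2 = 2) {
  nodes <- tibble::tibble(
    id = 1:4,
    x = c(0, 100, 0, 100),
    y = c(30, 30, 70, 70),
    z = c(50, 50, 50, 50)
  )
  segments <- tibble::tibble(id = 1:2, node_a = c(1L, 3L), node_b = c(2L, 4L),
                             radius = c(r1, r2))
  vessel_network(nodes, segments, box = c(100, 100, 100))
}

# closed-form tensor diagonal element for a single axial tube
tube_k11 <- function(radius, box_side = 100, mu_mpas = 1) {
  pi * radius^4 / (8 * mu_mpas * 1e-3 * box_side^2) * 1e-3
}

# Independent dense nodal-pressure oracle on a mirrored network: naive
# coordinate matching for periodic pairs, dense base-R solve.
dense_pressure_oracle <- function(mir, direction, mu_mpas) {
  nd <- mir$nodes
  sg <- mir$segments
  L <- mir$box
  tol <- mir$face_tol
  n <- nrow(nd)
  ax <- c("x", "y", "z")
  co <- cbind(nd$x, nd$y, nd$z)
  d <- match(direction, ax)
  # periodic merging via naive O(n^2) coordinate comparison
  group <- seq_len(n)
  is_dirichlet <- co[, d] <= tol | co[, d] >= L[[d]] - tol
  for (a in setdiff(1:3, d)) {
    lo <- which(co[, a] <= tol & !is_dirichlet)
    hi <- which(co[, a] >= L[[a]] - tol & !is_dirichlet)
    for (i in lo) for (j in hi) {
      oth <- setdiff(1:3, a)
      if (all(abs(co[i, oth] - co[j, oth]) <= tol)) {
        gi <- min(group[group == group[i] | group == group[j]])
        group[group == group[i]] <- gi
        group[group == group[j]] <- gi
      }
    }
  }
  groups <- sort(unique(group))
  gidx <- match(group, groups)
  m <- length(groups)
  A <- matrix(0, m, m)
  g <- pi * pmax(sg$radius, 0.1)^4 / (8 * mu_mpas * 1e-3 * sg$length)
  ia <- gidx[match(sg$node_a, nd$id)]
  ib <- gidx[match(sg$node_b, nd$id)]
  for (s in seq_along(g)) {
    if (ia[s] == ib[s]) next
    A[ia[s], ia[s]] <- A[ia[s], ia[s]] + g[s]
    A[ib[s], ib[s]] <- A[ib[s], ib[s]] + g[s]
    A[ia[s], ib[s]] <- A[ia[s], ib[s]] - g[s]
    A[ib[s], ia[s]] <- A[ib[s], ia[s]] - g[s]
  }
  p_fix <- rep(NA_real_, m)
  for (i in seq_len(n)) {
    if (co[i, d] <= tol) p_fix[gidx[i]] <- L[[d]]         # gradient 1 Pa/μm
    if (co[i, d] >= L[[d]] - tol) p_fix[gidx[i]] <- 0
  }
  free <- which(is.na(p_fix))
  # drop free groups with no path to a fixed group (keep pressure 0)
  reach <- !is.na(p_fix)
  repeat {
    grew <- FALSE
    for (s in seq_along(g)) {
      if (ia[s] != ib[s] && xor(reach[ia[s]], reach[ib[s]])) {
        reach[ia[s]] <- reach[ib[s]] <- TRUE
        grew <- TRUE
      }
    }
    if (!grew) break
  }
  free <- free[reach[free]]
  p <- ifelse(is.na(p_fix), 0, p_fix)
  if (length(free) > 0) {
    rhs <- -A[free, -free, drop = FALSE] %*% p[-free]
    p[free] <- solve(A[free, free, drop = FALSE], rhs)
  }
  stats::setNames(p[gidx], nd$id)
}

# independent scalar evaluation of the bifurcation phase-separation law
phase_sep_oracle <- function(df, d1, d2, fqb, h) {
  x0 <- 0.964 * (1 - h) / df
  if (fqb <= x0) return(0)
  if (fqb >= 1 - x0) return(1)
  a <- -13.29 * ((d1^2 - d2^2) / (d1^2 + d2^2)) * (1 - h) / df
  b <- 1 + 6.98 * (1 - h) / df
  plogis(a + b * qlogis((fqb - x0) / (1 - 2 * x0)))
}

# Kirchhoff residual summary on a solved mirrored state: max absolute net
# flow at interior (non-Dirichlet) representative nodes, relative to the
# mean absolute incident flow.
kirchhoff_residual <- function(mir, state) {
  nd <- mir$nodes
  sg <- mir$segments
  L <- mir$box
  tol <- mir$face_tol
  d <- state$direction
  rep_of <- state$node_rep
  coord <- nd[[d]]
  dir_ids <- nd$id[coord <= tol | coord >= L[[d]] - tol]
  dir_reps <- unique(unname(rep_of[as.character(dir_ids)]))
  ra <- unname(rep_of[as.character(sg$node_a)])
  rb <- unname(rep_of[as.character(sg$node_b)])
  net_flow <- tapply(c(-state$flow, state$flow), c(ra, rb), sum)
  interior <- setdiff(as.integer(names(net_flow)), dir_reps)
  if (length(interior) == 0) return(0)
  scale <- mean(abs(state$flow[state$flow != 0]))
  if (!is.finite(scale) || scale == 0) return(0)
  max(abs(net_flow[as.character(interior)])) / scale
}

# bare tensor object for sorting/fusion arithmetic tests
new_tensor_for_test <- function(m, hct_mode = "constant_hct") {
  dimnames(m) <- list(c("x", "y", "z"), c("x", "y", "z"))
  structure(list(k = m, sorted = FALSE, permutation = 1:3,
                 hct_mode = hct_mode, meta = list()),
            class = "permeability_tensor")
}
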