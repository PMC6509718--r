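#' Rheology parameters
#'
#' Blood rheology configuration for the flow solver. In `constant_hct` mode
#' every segment carries the inlet discharge hematocrit and viscosity follows
#' the in-vitro apparent-viscosity law at that hematocrit; in
#' `phase_separation` mode the per-segment hematocrit is iterated to a fixed
#' point of the red-cell phase-separation (plasma-skimming) law, with
#' viscosity recomputed from the converged hematocrit field.
#'
#' @param plasma_viscosity Plasma viscosity, mPa·s (default 1.2). Setting this
#'   to 1 with `inlet_hct = 0` yields constant unit viscosity, convenient for
#'   closed-form checks.
#' @param inlet_hct Discharge hematocrit at boundary inflows (default 0.4).
#' @param mode `"constant_hct"` or `"phase_separation"`.
#' @param damping Under-relaxation factor for the hematocrit update, in (0, 1].
#' @param max_iter Maximum hematocrit iterations.
#' @param hct_tol Convergence tolerance on max |ΔH|.
#' @return A list of class `rheology_params`.
#' @export
rheology_params <- function(plasma_viscosity = 1.2, inlet_hct = 0.4,
                            mode = c("constant_hct", "phase_separation"),
                            damping = 0.5, max_iter = 100L, hct_tol = 1e-4) {
  mode <- match.arg(mode)
  stopifnot(plasma_viscosity > 0, inlet_hct >= 0, inlet_hct <= 1,
            damping > 0, damping <= 1, max_iter >= 1, hct_tol > 0)
  structure(list(plasma_viscosity = plasma_viscosity, inlet_hct = inlet_hct,
                 mode = mode, damping = damping, max_iter = as.integer(max_iter),
                 hct_tol = hct_tol),
            class = "rheology_params")
}

#' In-vitro relative apparent blood viscosity
#'
#' Empirical in-vitro law for the relative apparent viscosity of blood in a
#' glass tube of diameter d (μm) at discharge hematocrit H, exhibiting the
#' Fåhræus–Lindqvist minimum near 7 μm:
#' \deqn{\mu_{rel} = 1 + (\mu^*_{0.45} - 1)\,
#'   \frac{(1-H)^C - 1}{(1-0.45)^C - 1}}
#' with \eqn{\mu^*_{0.45} = 220 e^{-1.3 d} + 3.2 - 2.44 e^{-0.06 d^{0.645}}}
#' and the shape exponent
#' \eqn{C = (0.8 + e^{-0.075 d})(-1 + 1/(1 + 10^{-11} d^{12})) +
#'   1/(1 + 10^{-11} d^{12})}.
#' At H = 0 the law returns exactly 1 (pure plasma).
#'
#' @param diameter Vessel diameter, μm (vectorized).
#' @param discharge_hct Discharge hematocrit in \[0, 1\] (vectorized).
#' @return Dimensionless relative viscosity; multiply by the plasma viscosity
#'   to obtain the segment's apparent viscosity.
#' @export
#' @examples
#' relative_viscosity_invitro(7, 0.45) < relative_viscosity_invitro(3, 0.45)
relative_viscosity_invitro <- function(diameter, discharge_hct) {
  stopifnot(all(diameter > 0), all(discharge_hct >= 0), all(discharge_hct <= 1))
  d <- diameter
  mu45 <- 220 * exp(-1.3 * d) + 3.2 - 2.44 * exp(-0.06 * d^0.645)
  dd <- 1 / (1 + 1e-11 * d^12)
  cc <- (0.8 + exp(-0.075 * d)) * (-1 + dd) + dd
  hterm <- ((1 - discharge_hct)^cc - 1) / ((1 - 0.45)^cc - 1)
  1 + (mu45 - 1) * hterm
}

# Per-segment apparent viscosity (mPa·s) from diameters and hematocrits.
segment_viscosity <- function(radius, hct, rheo) {
  rheo$plasma_viscosity * relative_viscosity_invitro(2 * radius, hct)
}

#' Red-cell flux fractions at a diverging bifurcation
#'
#' Empirical phase-separation (plasma-skimming) law for a parent vessel
#' splitting into exactly two daughters. With FQB the fractional blood flow
#' entering daughter one, the fractional erythrocyte flux FQE follows
#' \deqn{logit(FQE) = A + B\, logit\!\left(\frac{FQB - X_0}{1 - 2X_0}\right)}
#' where, with parent diameter Df and daughter diameters D1, D2 (μm) and
#' parent discharge hematocrit H:
#' \eqn{A = -13.29\,[(D_1^2 - D_2^2)/(D_1^2 + D_2^2)]\,(1-H)/D_f},
#' \eqn{B = 1 + 6.98\,(1-H)/D_f}, and the zero-flux cutoff
#' \eqn{X_0 = 0.964\,(1-H)/D_f}. A daughter whose blood-flow fraction falls
#' below \eqn{X_0} receives no red cells; above \eqn{1 - X_0} it receives all
#' of them.
#'
#' @param parent_diameter Feeding-vessel diameter, μm.
#' @param daughter_diameters Length-2 vector of daughter diameters, μm.
#' @param flow_fractions Length-2 vector of daughter blood-flow fractions
#'   (must sum to 1).
#' @param parent_hct Parent discharge hematocrit.
#' @return Length-2 vector of erythrocyte flux fractions summing to 1.
#' @export
#' @examples
#' phase_separation_fractions(8, c(6, 6), c(0.5, 0.5), 0.4) # 0.5 0.5
phase_separation_fractions <- function(parent_diameter, daughter_diameters,
                                       flow_fractions, parent_hct) {
  stopifnot(length(daughter_diameters) == 2, length(flow_fractions) == 2,
            abs(sum(flow_fractions) - 1) < 1e-9,
            all(flow_fractions >= 0), parent_diameter > 0)
  fqb <- flow_fractions[1]
  x0 <- 0.964 * (1 - parent_hct) / parent_diameter
  if (x0 >= 0.5) {
    # degenerate ultra-narrow parent: law undefined, split with the flow
    return(flow_fractions)
  }
  if (fqb <= x0) return(c(0, 1))
  if (fqb >= 1 - x0) return(c(1, 0))
  d1 <- daughter_diameters[1]
  d2 <- daughter_diameters[2]
  a <- -13.29 * ((d1^2 - d2^2) / (d1^2 + d2^2)) * (1 - parent_hct) / parent_diameter
  b <- 1 + 6.98 * (1 - parent_hct) / parent_diameter
  logit <- function(p) log(p / (1 - p))
  inv_logit <- function(x) 1 / (1 + exp(-x))
  fqe <- inv_logit(a + b * logit((fqb - x0) / (1 - 2 * x0)))
  c(fqe, 1 - fqe)
}

#' Propagate discharge hematocrit through a solved flow field
#'
#' Given a converged flow solution, traverses segments in topological order of
#' the flow direction (flow follows strictly decreasing pressure, so the
#' orientation is acyclic up to zero-flow ties). Boundary inflows carry the
#' inlet discharge hematocrit; converging nodes mix red-cell flux
#' conservatively (H = Σ|Q_i| H_i / Σ|Q_i|); diverging bifurcations with two
#' outgoing daughters split red cells by [phase_separation_fractions()];
#' nodes with three or more outgoing daughters split red cells in proportion
#' to blood flow (the bifurcation law is undefined there) with a warning.
#' Zero-flow segments keep their previous hematocrit. The returned field is
#' the damped update (1 − damping)·H_old + damping·H_raw, clamped to \[0, 1\].
#'
#' @param net The (mirrored) network the flows refer to.
#' @param state A flow state from [assemble_and_solve()] with elements
#'   `flow` (per segment, signed node_a→node_b) and `hct` (per segment).
#' @param rheo A [rheology_params()].
#' @param damping Override of `rheo$damping` (set 1 for the raw update).
#' @return The state with `hct` replaced by the updated field.
#' @export
update_hematocrit <- function(net, state, rheo = rheology_params(),
                              damping = rheo$damping) {
  if (rheo$mode == "constant_hct") return(state)
  sg <- net$segments
  q <- state$flow
  h_old <- state$hct
  n_seg <- nrow(sg)
  if (n_seg == 0) return(state)
  # orient by flow: from -> to; periodic-merged nodes collapse to their
  # representative so red cells crossing a periodic face re-enter correctly
  from <- ifelse(q >= 0, sg$node_a, sg$node_b)
  to <- ifelse(q >= 0, sg$node_b, sg$node_a)
  if (!is.null(state$node_rep)) {
    from <- unname(state$node_rep[as.character(from)])
    to <- unname(state$node_rep[as.character(to)])
  }
  aq <- abs(q)
  # segments carrying only numerical-roundoff flow have an arbitrary
  # orientation; treat them as stagnant (they keep their previous hematocrit)
  flow_floor <- 1e-12 * max(aq, 0)
  active <- aq > flow_floor & from != to
  node_ids <- if (is.null(state$node_rep)) net$nodes$id else
    sort(unique(unname(state$node_rep)))
  order_nodes <- topological_node_order(node_ids, from[active], to[active], aq[active])

  out_by_node <- split(which(active), factor(from[active], levels = node_ids))
  in_by_node <- split(which(active), factor(to[active], levels = node_ids))

  h_raw <- h_old
  warned <- FALSE
  for (v in order_nodes) {
    key <- as.character(v)
    ins <- in_by_node[[key]]
    outs <- out_by_node[[key]]
    if (length(outs) == 0) next
    if (length(ins) == 0) {
      h_node <- rheo$inlet_hct        # boundary inflow
      parent_d <- NA_real_
    } else {
      qin <- aq[ins]
      h_node <- sum(qin * h_raw[ins]) / sum(qin)
      parent_d <- 2 * sg$radius[ins[which.max(qin)]]
    }
    qout <- aq[outs]
    if (length(outs) == 1) {
      h_raw[outs] <- h_node
    } else if (length(outs) == 2 && is.finite(parent_d)) {
      fr <- qout / sum(qout)
      fqe <- phase_separation_fractions(parent_d, 2 * sg$radius[outs], fr, h_node)
      h_raw[outs] <- pmin(1, fqe * h_node * sum(qout) / qout)
    } else {
      # >2 daughters (or a source splitting immediately): flow-proportional
      if (length(outs) > 2 && !warned) {
        warning("node with >2 outgoing daughters: red cells split with the flow",
                call. = FALSE)
        warned <- TRUE
      }
      h_raw[outs] <- h_node
    }
  }
  state$hct <- pmin(1, pmax(0, (1 - damping) * h_old + damping * h_raw))
  state
}

# Topological order of nodes under the flow orientation; falls back to
# descending-|Q| discovery order if the orientation has cycles.
topological_node_order <- function(node_ids, from, to, weights) {
  if (length(from) == 0) return(node_ids)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to)),
    directed = TRUE, vertices = data.frame(name = as.character(node_ids)))
  ord <- tryCatch(igraph::topo_sort(g, mode = "out"),
                  warning = function(w) NULL, error = function(e) NULL)
  if (!is.null(ord) && length(ord) == length(node_ids)) {
    return(as.integer(names(ord)))
  }
  warning("cyclic flow orientation; processing nodes by descending inflow",
          call. = FALSE)
  total_in <- tapply(weights, factor(to, levels = as.character(node_ids)), sum)
  total_in[is.na(total_in)] <- 0
  node_ids[order(-total_in)]
}
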