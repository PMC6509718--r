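#' Declare a vascular remodeling scenario
#'
#' Scenario families: uniform dilation or constriction of every vessel
#' (`dilate_all`, `constrict_all`), dilation or constriction of a random
#' subset (`dilate_subset`, `constrict_subset`), diameter-dependent
#' vasodilation (`dilate_diameter_dependent`: smaller vessels dilate more,
#' linearly down to zero at the largest diameter), and pruning of the
#' smallest-radius vessels (`prune_smallest`).
#'
#' @param mode One of `dilate_all`, `dilate_subset`,
#'   `dilate_diameter_dependent`, `constrict_all`, `constrict_subset`,
#'   `prune_smallest`.
#' @param magnitude Fractional diameter change (e.g. 0.1, 0.2, 0.3); for
#'   `dilate_diameter_dependent` the peak change at the smallest diameter;
#'   for `prune_smallest` the fraction of segments removed.
#' @param subset_fraction Fraction of segments remodeled in subset modes.
#' @param seed Integer seed making random subset selection reproducible.
#' @param d_min,d_max Diameter range (μm) of the linear vasodilation profile:
#'   peak response at `d_min` (0.4 μm), zero response at `d_max` (20 μm).
#' @return A list of class `remodeling_scenario`.
#' @export
remodeling_scenario <- function(mode = c("dilate_all", "dilate_subset",
                                         "dilate_diameter_dependent",
                                         "constrict_all", "constrict_subset",
                                         "prune_smallest"),
                                magnitude, subset_fraction = NA_real_,
                                seed = 1L, d_min = 0.4, d_max = 20) {
  mode <- match.arg(mode)
  stopifnot(magnitude > 0, magnitude < 1)
  if (mode %in% c("dilate_subset", "constrict_subset")) {
    stopifnot(!is.na(subset_fraction), subset_fraction > 0, subset_fraction <= 1)
  }
  structure(list(mode = mode, magnitude = magnitude,
                 subset_fraction = subset_fraction, seed = as.integer(seed),
                 d_min = d_min, d_max = d_max),
            class = "remodeling_scenario")
}

#' Diameter-dependent vasodilation factor
#'
#' Linear response profile: the fractional diameter increase equals `f_max`
#' at the smallest diameter (`d_min`, 0.4 μm), decreases linearly with
#' diameter, and reaches zero at the largest (`d_max`, 20 μm). Diameters are
#' clamped to the profile range.
#'
#' @param d Vessel diameter, μm (vectorized).
#' @param f_max Peak fractional increase.
#' @param d_min,d_max Profile endpoints, μm.
#' @return Fractional diameter increase per vessel.
#' @export
#' @examples
#' diameter_dependent_factor(0.4, 0.3) # 0.3
#' diameter_dependent_factor(20, 0.3)  # 0
diameter_dependent_factor <- function(d, f_max, d_min = 0.4, d_max = 20) {
  stopifnot(f_max > 0, d_max > d_min)
  f_max * (d_max - pmin(pmax(d, d_min), d_max)) / (d_max - d_min)
}

#' Apply a remodeling scenario to a subnetwork
#'
#' Returns a modified copy: radii scaled per the scenario mode, or the
#' smallest-radius segments removed (ties broken by segment id) followed by a
#' re-run of blind-end pruning so dangling remnants disappear. Subset
#' selection is uniformly random without replacement under the scenario
#' seed, so identical seeds give identical networks. Pruning may disconnect
#' all face-to-face paths; the downstream tensor is then zero, which is a
#' legitimate outcome.
#'
#' @param sub A preprocessed `vessel_subnetwork` (or network, coerced).
#' @param sc A [remodeling_scenario()].
#' @return The remodeled subnetwork.
#' @export
apply_scenario <- function(sub, sc) {
  stopifnot(inherits(sc, "remodeling_scenario"))
  sub <- as_subnetwork(sub)
  sg <- sub$segments
  n <- nrow(sg)
  if (n == 0) return(sub)
  if (sc$mode == "dilate_all") {
    sg$radius <- sg$radius * (1 + sc$magnitude)
  } else if (sc$mode == "constrict_all") {
    sg$radius <- sg$radius * (1 - sc$magnitude)
  } else if (sc$mode %in% c("dilate_subset", "constrict_subset")) {
    k <- max(1L, round(sc$subset_fraction * n))
    pick <- withr::with_seed(sc$seed, sample.int(n, k))
    sgn <- if (sc$mode == "dilate_subset") 1 else -1
    sg$radius[pick] <- sg$radius[pick] * (1 + sgn * sc$magnitude)
  } else if (sc$mode == "dilate_diameter_dependent") {
    f <- diameter_dependent_factor(2 * sg$radius, sc$magnitude, sc$d_min, sc$d_max)
    sg$radius <- sg$radius * (1 + f)
  } else if (sc$mode == "prune_smallest") {
    k <- floor(sc$magnitude * n)
    if (k > 0) {
      ord <- order(sg$radius, sg$id)
      sg <- sg[-ord[seq_len(k)], , drop = FALSE]
    }
    sub$segments <- sg
    keep <- unique(c(sg$node_a, sg$node_b))
    sub$nodes <- sub$nodes[sub$nodes$id %in% keep, , drop = FALSE]
    return(prune_blind_ends(sub))
  }
  sub$segments <- sg
  sub$volume_pruned <- network_volume(sub)
  sub
}

#' Percentage change of sorted tensor diagonals
#'
#' @param before,after Sorted `permeability_tensor` objects.
#' @return Tibble with `element` (k11, k22, k33), `before`, `after` and
#'   `percent_change` = 100 (after − before)/before; `NA` where the baseline
#'   element is zero.
#' @export
percent_change <- function(before, after) {
  if (!before$sorted) before <- sort_tensor(before)
  if (!after$sorted) after <- sort_tensor(after)
  b <- unname(diag(before$k))
  a <- unname(diag(after$k))
  tibble::tibble(
    element = c("k11", "k22", "k33"),
    before = b, after = a,
    percent_change = ifelse(b != 0, 100 * (a - b) / b, NA_real_)
  )
}

#' Run a battery of remodeling scenarios on a subnetwork
#'
#' Computes the baseline tensor, applies each scenario, recomputes, and
#' reports percentage changes of the sorted diagonals.
#'
#' @param sub A preprocessed `vessel_subnetwork`.
#' @param scenarios List of [remodeling_scenario()] objects.
#' @param rheo,solver Passed to [permeability_tensor()].
#' @return Tibble with one row per scenario and diagonal element.
#' @export
remodeling_report <- function(sub, scenarios, rheo = rheology_params(),
                              solver = solver_config()) {
  base <- sort_tensor(permeability_tensor(sub, rheo, solver))
  rows <- purrr::map(scenarios, function(sc) {
    mod <- apply_scenario(sub, sc)
    after <- sort_tensor(permeability_tensor(mod, rheo, solver))
    pc <- percent_change(base, after)
    pc$mode <- sc$mode
    pc$magnitude <- sc$magnitude
    pc$subset_fraction <- sc$subset_fraction
    pc$seed <- sc$seed
    pc
  })
  dplyr::bind_rows(rows)[, c("mode", "magnitude", "subset_fraction", "seed",
                             "element", "before", "after", "percent_change")]
}

#' Bar chart of remodeling percent changes
#' @param object A [remodeling_report()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_remodeling <- function(object, ...) {
  object$label <- paste0(object$mode, " ", 100 * object$magnitude, "%")
  ggplot2::ggplot(object, ggplot2::aes(.data$label, .data$percent_change,
                                       fill = .data$element)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "change in permeability (%)",
                  title = "Impact of vascular remodeling on conductivity") +
    ggplot2::theme_minimal()
}
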