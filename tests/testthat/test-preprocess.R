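test_that("component labels are dense, volume-ordered from 0", {
  net <- label_components(make_two_tube_net(r1 = 4, r2 = 2))
  # larger-volume tube (r=4) must be component 0
  expect_equal(net$segments$component[net$segments$radius == 4], 0L)
  expect_equal(net$segments$component[net$segments$radius == 2], 1L)
  lat <- label_components(make_cubic_lattice(c(120, 120, 40), 40, 4))
  expect_true(all(lat$segments$component == 0L))
})

test_that("density filter retains components at or above the threshold", {
  # three parallel-tube components with volume fractions 0.5 / 0.3 / 0.2
  r <- sqrt(c(0.5, 0.3, 0.2))      # volume ~ r^2 at equal length
  nodes <- tibble::tibble(id = 1:6, x = rep(c(0, 100), 3),
                          y = rep(c(25, 50, 75), each = 2), z = 50)
  seg <- tibble::tibble(id = 1:3, node_a = c(1L, 3L, 5L),
                        node_b = c(2L, 4L, 6L), radius = r)
  net <- vessel_network(nodes, seg, c(100, 100, 100))
  expect_length(filter_by_density(net), 3)

  # fractions 0.86 / 0.14: only the first survives
  net2 <- make_two_tube_net(r1 = sqrt(0.86), r2 = sqrt(0.14))
  expect_length(filter_by_density(net2), 1)

  # a fraction of exactly 0.15 is retained (inclusive threshold)
  net3 <- make_two_tube_net(r1 = sqrt(0.85), r2 = sqrt(0.15))
  subs <- filter_by_density(net3)
  expect_length(subs, 2)
  expect_equal(subs[[2]]$volume_initial / (100 * pi * (0.85 + 0.15)), 0.15,
               tolerance = 1e-12)
  expect_length(filter_by_density(vessel_network(
    tibble::tibble(id = integer(), x = double(), y = double(), z = double()),
    tibble::tibble(id = integer(), node_a = integer(), node_b = integer(),
                   radius = double()), c(10, 10, 10))), 0)
})

test_that("border ends elongate onto the nearest face with axis tie-break", {
  nodes <- tibble::tibble(id = 1:2, x = c(0, 98), y = 50, z = 50)
  seg <- tibble::tibble(id = 1L, node_a = 1L, node_b = 2L, radius = 4)
  sub <- as_subnetwork(vessel_network(nodes, seg, c(100, 100, 100)))
  el <- elongate_border_ends(sub, epsilon = 5)
  expect_equal(el$nodes$x[el$nodes$id == 2], 100)
  expect_equal(el$segments$length, 100)          # 98 + 2
  expect_match(el$nodes$faces[el$nodes$id == 2], "x_hi")

  # out of reach: unchanged
  nodes$x[2] <- 90
  sub2 <- as_subnetwork(vessel_network(nodes, seg, c(100, 100, 100)))
  el2 <- elongate_border_ends(sub2, epsilon = 5)
  expect_equal(el2$nodes$x[el2$nodes$id == 2], 90)
  expect_equal(attr(el2, "n_elongated"), 0L)

  # corner: equidistant from x_hi and y_hi snaps to x (lower axis index)
  nodes3 <- tibble::tibble(id = 1:2, x = c(0, 97), y = c(50, 97), z = 50)
  sub3 <- as_subnetwork(vessel_network(nodes3, seg, c(100, 100, 100)))
  el3 <- elongate_border_ends(sub3, epsilon = 5)
  expect_equal(el3$nodes$x[el3$nodes$id == 2], 100)
  expect_equal(el3$nodes$y[el3$nodes$id == 2], 97)
})

test_that("blind-end pruning cascades, protects border ends, is idempotent", {
  # spanning tube untouched
  tube <- prune_blind_ends(as_subnetwork(make_single_tube()))
  expect_equal(nrow(tube$segments), 1)

  # trunk + dangling side branch: branch removed, trunk intact
  y <- prune_blind_ends(elongate_border_ends(as_subnetwork(make_y_fixture())))
  expect_equal(nrow(y$segments), 2)
  expect_equal(y$volume_pruned, 1600 * pi)

  # chain A(x_lo)-B-C with C interior: cascade empties the subnetwork
  nodes <- tibble::tibble(id = 1:3, x = c(0, 40, 80), y = 50, z = 50)
  seg <- tibble::tibble(id = 1:2, node_a = c(1L, 2L), node_b = c(2L, 3L),
                        radius = 4)
  chain <- as_subnetwork(vessel_network(nodes, seg, c(100, 100, 100)))
  pr <- prune_blind_ends(chain)
  expect_true(attr(pr, "empty"))
  expect_equal(nrow(pr$segments), 0)
  expect_equal(attr(pr, "pruned_per_iteration"), c(1L, 1L))

  # idempotence and the no-untagged-degree-1 invariant on random beds
  for (seed in 1:3) {
    rc <- make_random_capillary(seed = seed, box = c(200, 200, 80), spacing = 40)
    sub <- filter_by_density(label_components(rc))[[1]]
    p1 <- prune_blind_ends(elongate_border_ends(sub))
    p2 <- prune_blind_ends(p1)
    expect_equal(p2$segments, p1$segments)
    deg <- node_degrees(p1)
    ends <- p1$nodes[deg == 1, ]
    expect_true(all(ends$faces != ""))
  }
})

test_that("REV gate is inclusive and applies to x-y only", {
  fake_sub <- function(ex, ey, ez) {
    s <- as_subnetwork(make_single_tube())
    s$extent <- c(x = ex, y = ey, z = ez)
    s
  }
  expect_true(rev_gate(fake_sub(200, 180, 90)))
  expect_false(rev_gate(fake_sub(160, 300, 90)))
  expect_true(rev_gate(fake_sub(170, 170, 50)))   # inclusive, z ungated
})

test_that("preprocess report fractions sum to one and flag exclusions", {
  rc <- make_random_capillary(seed = 3)
  pp <- preprocess_network(rc)
  expect_equal(sum(pp$report$density_fraction), 1, tolerance = 1e-12)
  expect_true(all(pp$report$density_fraction[pp$report$retained] >= 0.15))
  expect_true(all(!pp$report$rev_pass[!pp$report$retained]))
  expect_gt(length(pp$subnetworks), 0)
  expect_gt(sum(pp$report$n_pruned_segments, na.rm = TRUE), 0)
})
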