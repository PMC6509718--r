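rheo0 <- rheology_params(plasma_viscosity = 1, inlet_hct = 0)

test_that("diameter-dependent vasodilation profile is linear with clamped ends", {
  expect_equal(diameter_dependent_factor(0.4, 0.3), 0.3)
  expect_equal(diameter_dependent_factor(20, 0.3), 0)
  expect_equal(diameter_dependent_factor(10.2, 0.3), 0.15)  # midpoint
  expect_equal(diameter_dependent_factor(0.1, 0.2), 0.2)    # clamped below
  expect_equal(diameter_dependent_factor(50, 0.2), 0)       # clamped above
})

test_that("uniform dilation and constriction follow the quartic law", {
  tube <- as_subnetwork(make_single_tube())
  base <- sort_tensor(permeability_tensor(tube, rheo = rheo0))
  dil <- apply_scenario(tube, remodeling_scenario("dilate_all", 0.10))
  kd <- sort_tensor(permeability_tensor(dil, rheo = rheo0))
  pc <- percent_change(base, kd)
  expect_equal(pc$percent_change[1], 100 * (1.1^4 - 1), tolerance = 1e-9)

  lat <- as_subnetwork(make_cubic_lattice(c(120, 120, 40), 40, 4))
  kb <- sort_tensor(permeability_tensor(lat, rheo = rheo0))
  con <- apply_scenario(lat, remodeling_scenario("constrict_all", 0.30))
  kc <- sort_tensor(permeability_tensor(con, rheo = rheo0))
  pcl <- percent_change(kb, kc)
  expect_equal(pcl$percent_change, rep(100 * (0.7^4 - 1), 3), tolerance = 1e-6)
})

test_that("percent change handles identity, doubling and zero baselines", {
  a <- sort_tensor(new_tensor_for_test(diag(c(3, 2, 1))))
  expect_equal(percent_change(a, a)$percent_change, c(0, 0, 0))
  b <- sort_tensor(new_tensor_for_test(diag(c(6, 4, 2))))
  expect_equal(percent_change(a, b)$percent_change, c(100, 100, 100))
  z <- sort_tensor(new_tensor_for_test(diag(c(3, 2, 0))))
  expect_true(is.na(percent_change(z, a)$percent_change[3]))
})

test_that("pruning the smallest vessels removes them and re-prunes blind ends", {
  two <- as_subnetwork(make_parallel_tubes(radii = c(3, 5), n = 2))
  pruned <- apply_scenario(two, remodeling_scenario("prune_smallest", 0.5))
  expect_equal(nrow(pruned$segments), 1)
  expect_equal(pruned$segments$radius, 5)
  k <- permeability_tensor(pruned, rheo = rheo0)
  expect_equal(k$k["x", "x"], tube_k11(5), tolerance = 1e-9)
  # pruning the only spanning segment zeroes the tensor row
  one <- as_subnetwork(make_single_tube())
  gone <- apply_scenario(one, remodeling_scenario("prune_smallest", 0.9))
  expect_s3_class(gone, "vessel_subnetwork")
  if (nrow(gone$segments) == 0) {
    expect_true(attr(gone, "empty"))
  }
})

test_that("seeded subset scenarios are exactly reproducible", {
  rc <- preprocess_network(make_random_capillary(
    seed = 2, box = c(160, 160, 80), spacing = 40), rev_cutoff = 0)$subnetworks[[1]]
  sc <- remodeling_scenario("dilate_subset", 0.3, subset_fraction = 0.2, seed = 42)
  m1 <- apply_scenario(rc, sc)
  m2 <- apply_scenario(rc, sc)
  expect_identical(m1$segments, m2$segments)
  k1 <- permeability_tensor(m1, rheo = rheo0)
  k2 <- permeability_tensor(m2, rheo = rheo0)
  expect_identical(k1$k, k2$k)
  # a different seed changes the selection
  m3 <- apply_scenario(rc, remodeling_scenario("dilate_subset", 0.3,
                                               subset_fraction = 0.2, seed = 43))
  expect_false(identical(m1$segments$radius, m3$segments$radius))
})

test_that("with the viscosity law active, constriction is amplified beyond
           the constant-viscosity quartic loss", {
  rc <- preprocess_network(make_random_capillary(
    seed = 2, box = c(160, 160, 80), spacing = 40), rev_cutoff = 0)$subnetworks[[1]]
  rheo <- rheology_params()   # in-vitro law at hematocrit 0.4
  base <- sort_tensor(permeability_tensor(rc, rheo = rheo))
  con <- apply_scenario(rc, remodeling_scenario("constrict_all", 0.30))
  after <- sort_tensor(permeability_tensor(con, rheo = rheo))
  pc <- percent_change(base, after)$percent_change
  expect_true(all(pc < 100 * (0.7^4 - 1)))   # lose more than 75.99%
  # and dilation changes increase monotonically with magnitude
  mags <- c(0.1, 0.2, 0.3)
  gains <- vapply(mags, function(f) {
    d <- apply_scenario(rc, remodeling_scenario("dilate_all", f))
    percent_change(base, sort_tensor(permeability_tensor(d, rheo = rheo)))$percent_change[1]
  }, numeric(1))
  expect_true(all(diff(gains) > 0))
})
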