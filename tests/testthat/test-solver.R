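rheo0 <- rheology_params(plasma_viscosity = 1, inlet_hct = 0)  # constant μ = 1 mPa·s

test_that("mirroring produces the expected images and merges plane nodes", {
  # axial tube: x-plane endpoint merges, y and z images -> 4 parallel tubes
  mir <- mirror_network(as_subnetwork(make_single_tube()))
  expect_equal(mir$box, c(x = 200, y = 200, z = 200))
  expect_equal(nrow(mir$segments), 8)   # 4 tubes, each split at the x plane
  expect_equal(nrow(mir$nodes), 12)     # 3 nodes per tube after the merge
  # a network with no face nodes multiplies node count by exactly 8
  nodes <- tibble::tibble(id = 1:2, x = c(20, 60), y = 50, z = 50)
  seg <- tibble::tibble(id = 1L, node_a = 1L, node_b = 2L, radius = 3)
  inner <- vessel_network(nodes, seg, c(100, 100, 100))
  expect_equal(nrow(mirror_network(as_subnetwork(inner))$nodes), 16)
})

test_that("single mirrored tube reproduces the Poiseuille closed form", {
  mir <- mirror_network(as_subnetwork(make_single_tube(radius = 4)))
  st <- assemble_and_solve(mir, "x", rheo0)
  g <- pi * 4^4 / (8 * 1e-3 * 100)      # per 100 μm image segment
  expect_equal(abs(st$flow), rep(g * 100, 8), tolerance = 1e-12)
  expect_equal(surface_flux(mir, st, "x"), 4 * g * 100, tolerance = 1e-9)
})

test_that("series combination of unequal tubes follows the harmonic law", {
  nodes <- tibble::tibble(id = 1:3, x = c(0, 50, 100), y = 50, z = 50)
  seg <- tibble::tibble(id = 1:2, node_a = c(1L, 2L), node_b = c(2L, 3L),
                        radius = c(4, 3))
  chain <- vessel_network(nodes, seg, c(100, 100, 100))
  k <- permeability_tensor(chain, rheo = rheo0)
  r_half <- function(r) 8 * 1e-3 * 50 / (pi * r^4)   # Pa·s/μm³ per half
  g_chain <- 1 / (r_half(4) + r_half(3))
  expect_equal(k$k["x", "x"], g_chain / 100^2 * 1e-3 * 100, tolerance = 1e-9)
  # equal radii: end-to-end conductance is half of one 50 μm tube
  seg$radius <- c(4, 4)
  chain2 <- vessel_network(nodes, seg, c(100, 100, 100))
  k2 <- permeability_tensor(chain2, rheo = rheo0)
  expect_equal(k2$k["x", "x"], tube_k11(4), tolerance = 1e-9)
})

test_that("nodal pressures match an independent dense solve", {
  lat <- make_cubic_lattice(c(100, 100, 20), 20, 3)   # 5x5x1 staggered cells
  mir <- mirror_network(as_subnetwork(lat))
  st <- assemble_and_solve(mir, "x", rheo0)
  oracle <- dense_pressure_oracle(mir, "x", 1)
  expect_equal(unname(st$pressure[names(oracle)]), unname(oracle),
               tolerance = 1e-10)
})

test_that("flow is conserved on seeded random networks", {
  worst_kirchhoff <- 0
  worst_balance <- 0
  for (seed in 1:100) {
    rc <- make_random_capillary(seed = seed, box = c(120, 120, 40), spacing = 40,
                                jitter = 6, blind_end_fraction = 0.05,
                                disconnect_fraction = 0)
    pp <- preprocess_network(rc, rev_cutoff = 0)
    mir <- mirror_network(pp$subnetworks[[1]])
    st <- assemble_and_solve(mir, "x", rheology_params())
    worst_kirchhoff <- max(worst_kirchhoff, kirchhoff_residual(mir, st))
    outflow <- surface_flux(mir, st, "x", "hi")
    inflow <- surface_flux(mir, st, "x", "lo")
    worst_balance <- max(worst_balance, abs(outflow - inflow) / abs(outflow))
  }
  expect_lt(worst_kirchhoff, 1e-10)
  expect_lt(worst_balance, 1e-10)
})

test_that("directions without spanning paths yield a zero state, not an error", {
  # tube spans x only: y and z solves return all-zero flow
  mir <- mirror_network(as_subnetwork(make_single_tube()))
  for (d in c("y", "z")) {
    st <- assemble_and_solve(mir, d, rheo0)
    expect_true(all(st$flow == 0))
    expect_equal(surface_flux(mir, st, d), 0)
  }
})

test_that("linearity in the gradient and quartic scaling in radius", {
  lat <- make_cubic_lattice(c(120, 120, 40), 40, 4)
  sub <- as_subnetwork(lat)
  k1 <- permeability_tensor(sub, rheo = rheo0, solver = solver_config(1))
  k10 <- permeability_tensor(sub, rheo = rheo0, solver = solver_config(10))
  expect_equal(k10$k, k1$k, tolerance = 1e-12)
  lat2 <- lat
  lat2$segments$radius <- lat2$segments$radius * 1.5
  k_scaled <- permeability_tensor(as_subnetwork(lat2), rheo = rheo0)
  expect_equal(k_scaled$k, k1$k * 1.5^4, tolerance = 1e-6)
})
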