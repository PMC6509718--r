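rheo0 <- rheology_params(plasma_viscosity = 1, inlet_hct = 0)

test_that("closed-form fixtures: tube, parallel additivity, lattice", {
  k <- permeability_tensor(make_single_tube(radius = 4), rheo = rheo0)
  expect_equal(k$k["x", "x"], tube_k11(4), tolerance = 1e-9)
  off <- k$k
  diag(off) <- 0
  expect_true(all(abs(off) <= 1e-9 * k$k["x", "x"]))
  expect_equal(k$k["y", "y"], 0)
  expect_equal(k$k["z", "z"], 0)

  # two parallel tubes double the conductivity; unequal radii add
  k2 <- permeability_tensor(make_parallel_tubes(radii = 4, n = 2), rheo = rheo0)
  expect_equal(k2$k["x", "x"], 2 * tube_k11(4), tolerance = 1e-9)
  k35 <- permeability_tensor(make_parallel_tubes(radii = c(3, 5), n = 2),
                             rheo = rheo0)
  expect_equal(k35$k["x", "x"], tube_k11(3) + tube_k11(5), tolerance = 1e-9)

  # staggered cubic lattice: unit-cell closed form on every axis
  lat <- make_cubic_lattice(c(200, 200, 200), 50, 4)
  kl <- permeability_tensor(lat, rheo = rheo0)
  cf <- pi * 4^4 / (8 * 1e-3 * 50^2) * 1e-3
  expect_equal(unname(diag(kl$k)), rep(cf, 3), tolerance = 0.02)
  offl <- kl$k
  diag(offl) <- 0
  expect_true(all(abs(offl) <= 1e-8 * kl$k["x", "x"]))
})

test_that("double mirroring leaves the tensor unchanged on all fixtures", {
  fixtures <- list(
    make_single_tube(),
    make_parallel_tubes(radii = c(3, 5), n = 2),
    make_cubic_lattice(c(120, 120, 40), 40, 4),
    preprocess_network(make_random_capillary(
      seed = 2, box = c(160, 160, 80), spacing = 40), rev_cutoff = 0)$subnetworks[[1]]
  )
  for (fx in fixtures) {
    k1 <- permeability_tensor(fx, rheo = rheo0, mirror_times = 1)
    k2 <- permeability_tensor(fx, rheo = rheo0, mirror_times = 2)
    expect_lt(max(abs(k2$k - k1$k)) / max(abs(k1$k)), 1e-8)
  }
})

test_that("phase separation: symmetric fixtures match constant hematocrit,
           asymmetric networks converge to the brute-force fixed point", {
  rheo_ps <- rheology_params(mode = "phase_separation")
  rheo_ch <- rheology_params()
  # single tube: identical tensors
  kt_ps <- permeability_tensor(make_single_tube(), rheo = rheo_ps)
  kt_ch <- permeability_tensor(make_single_tube(), rheo = rheo_ch)
  expect_equal(kt_ps$k, kt_ch$k, tolerance = 1e-12)
  # symmetric lattice: uniform inlet hematocrit is the fixed point
  lat <- make_cubic_lattice(c(120, 120, 40), 40, 4)
  kl_ps <- permeability_tensor(lat, rheo = rheo_ps)
  kl_ch <- permeability_tensor(lat, rheo = rheo_ch)
  expect_equal(kl_ps$k, kl_ch$k, tolerance = 1e-9)
  expect_true(all(kl_ps$meta$hct_converged))

  # asymmetric radii: tensors differ; brute-force fixed point agrees
  rc <- preprocess_network(make_random_capillary(
    seed = 4, box = c(160, 160, 80), spacing = 40), rev_cutoff = 0)$subnetworks[[1]]
  k_ps <- permeability_tensor(rc, rheo = rheo_ps)
  k_ch <- permeability_tensor(rc, rheo = rheo_ch)
  expect_gt(max(abs(k_ps$k - k_ch$k)) / max(abs(k_ch$k)), 1e-6)
  expect_true(all(k_ps$meta$hct_converged))
  # brute force: undamped alternation run far beyond the default tolerance
  mir <- mirror_network(rc)
  h <- rep(0.4, nrow(mir$segments))
  for (i in 1:300) {
    st <- assemble_and_solve(mir, "x", rheo_ps, hct = h)
    st2 <- update_hematocrit(mir, st, rheo_ps, damping = 1)
    if (max(abs(st2$hct - h)) < 1e-12) { h <- st2$hct; break }
    h <- st2$hct
  }
  st <- assemble_and_solve(mir, "x", rheo_ps, hct = h)
  flux <- surface_flux(mir, st, "x")
  k_oracle <- flux / (mir$box[["y"]] * mir$box[["z"]] * st$gradient) * 1e-3
  expect_equal(k_ps$k["x", "x"], unname(k_oracle), tolerance = 1e-4)
})

test_that("red-cell flux is conserved in the converged phase-separation state", {
  rheo_ps <- rheology_params(mode = "phase_separation", hct_tol = 1e-10,
                             max_iter = 300)
  rc <- preprocess_network(make_random_capillary(
    seed = 6, box = c(120, 120, 40), spacing = 40), rev_cutoff = 0)$subnetworks[[1]]
  mir <- mirror_network(rc)
  h <- rep(0.4, nrow(mir$segments))
  for (i in 1:300) {
    st <- assemble_and_solve(mir, "x", rheo_ps, hct = h)
    st2 <- update_hematocrit(mir, st, rheo_ps, damping = 1)
    delta <- max(abs(st2$hct - h))
    h <- st2$hct
    if (delta < 1e-12) break
  }
  st$hct <- h
  # node-wise red-cell flux balance at interior representatives
  rep_of <- st$node_rep
  ra <- unname(rep_of[as.character(mir$segments$node_a)])
  rb <- unname(rep_of[as.character(mir$segments$node_b)])
  rbc <- st$flow * h
  net_rbc <- tapply(c(-rbc, rbc), c(ra, rb), sum)
  co <- mir$nodes$x
  dir_ids <- mir$nodes$id[co <= mir$face_tol | co >= mir$box[["x"]] - mir$face_tol]
  interior <- setdiff(as.integer(names(net_rbc)), unname(rep_of[as.character(dir_ids)]))
  scale <- mean(abs(rbc[rbc != 0]))
  expect_lt(max(abs(net_rbc[as.character(interior)])) / scale, 1e-9)
  expect_true(all(h >= 0 & h <= 1))
})

test_that("fusion: identity, surface-weighted mean, overlapping sum", {
  tube <- as_subnetwork(make_single_tube())
  kt <- permeability_tensor(tube, rheo = rheo0)
  fused1 <- fuse_tensors(list(tube), list(kt))
  expect_equal(fused1$k, kt$k)   # w = 1, scale = 1

  # two diagonally offset boxes with equal faces and no projected overlap
  # along any axis: every weight is 1/2, so fusion is the arithmetic mean
  sub_a <- tube; sub_b <- tube
  sub_a$origin <- c(x = 0, y = 0, z = 0)
  sub_a$extent <- c(x = 100, y = 50, z = 50)
  sub_b$origin <- c(x = 0, y = 50, z = 50)
  sub_b$extent <- c(x = 100, y = 50, z = 50)
  ka <- kt; kb <- kt
  kb$k <- 2 * kb$k
  mean_f <- fuse_tensors(list(sub_a, sub_b), list(ka, kb), apply_scale = FALSE)
  expect_equal(mean_f$k, (ka$k + kb$k) / 2)

  # fully overlapping equal boxes: denominator collapses, tensors add
  sub_b$origin <- sub_a$origin
  sum_f <- fuse_tensors(list(sub_a, sub_b), list(ka, kb), apply_scale = FALSE)
  expect_equal(sum_f$k, ka$k + kb$k)

  # volume-ratio rescaling multiplies by V_init/V_pruned
  half <- tube
  half$volume_pruned <- half$volume_initial / 2
  scaled <- fuse_tensors(list(half), list(kt), apply_scale = TRUE)
  expect_equal(scaled$k, 2 * kt$k)
  unscaled <- fuse_tensors(list(half), list(kt), apply_scale = FALSE)
  expect_equal(unscaled$k, kt$k)
})

test_that("sorting permutes rows and columns together, preserving eigenvalues", {
  k <- new_tensor_for_test(diag(c(1, 3, 2)))
  s <- sort_tensor(k)
  expect_equal(unname(diag(s$k)), c(3, 2, 1))
  expect_equal(s$permutation, c(2, 3, 1))
  # already sorted: identity permutation
  s2 <- sort_tensor(new_tensor_for_test(diag(c(5, 4, 3))))
  expect_equal(s2$permutation, 1:3)
  # full matrix with off-diagonals: equals the explicit P K P^T
  m <- matrix(c(2, 0.1, 0.2,
                0.1, 5, 0.3,
                0.2, 0.3, 3), 3, 3, byrow = TRUE)
  s3 <- sort_tensor(new_tensor_for_test(m))
  perm <- s3$permutation
  P <- diag(3)[perm, ]
  expect_equal(unname(s3$k), P %*% m %*% t(P))
  expect_equal(sort(eigen(s3$k)$values), sort(eigen(m)$values))
  expect_true(all(diff(diag(s3$k)) <= 0))
})

test_that("REV scan is consistent with the direct tensor and flags small units", {
  lat <- make_cubic_lattice(c(240, 240, 40), 40, 4)
  scan <- rev_scan(lat, unit_sizes = c(240, 120), rheo = rheo0, rev_cutoff = 0)
  s <- attr(scan, "summary")
  # unit = full domain reproduces the whole-network tensor
  full <- permeability_tensor(lat, rheo = rheo0)
  expect_equal(s$median_k11[s$unit_size == 240], unname(full$k[1, 1]),
               tolerance = 1e-9)
  # homogeneous lattice: median diagonal constant across unit sizes within 5%
  expect_equal(s$median_k11[s$unit_size == 120],
               s$median_k11[s$unit_size == 240], tolerance = 0.05)
  # units below the anatomical REV cutoff are excluded and flagged
  gated <- rev_scan(lat, unit_sizes = 120, rheo = rheo0, rev_cutoff = 170)
  expect_true(all(gated$excluded))
  expect_true(all(gated$reason == "below REV cutoff"))
})
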