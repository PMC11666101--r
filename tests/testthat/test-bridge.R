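# Trans-dimer assembly, extension geometry, and coarse pulling.

test_that("tip-to-tip interfaces localize to the distal turn regions", {
  ig <- make_toy_ig()
  d <- build_dimer(ig, "tip")
  ca <- d$atoms_a[d$atoms_a$elety == "CA", ]
  z_top <- max(ca$z)
  iface_z <- ca$z[match(unique(d$interface$resno_a), ca$resno)]
  expect_true(all(iface_z > z_top - 6)) # contacts at the membrane-distal tips
})

test_that("placements without an interface are rejected", {
  ig <- make_toy_ig()
  expect_error(build_dimer(ig, "tip", gap = 100), "empty interface")
})

test_that("max extension distance follows its closed form", {
  ig <- make_toy_ig()
  # zero-length linkers: distance reduces to the anchor span alone
  d0 <- build_dimer(ig, "tip", linker_residues = 0)
  span <- abs(d0$anchor_b[3] - d0$anchor_a[3])
  expect_equal(max_extension_distance(d0), span / 10)
  # monotone increasing in linker residue count
  dists <- vapply(
    c(0, 5, 10, 15, 20),
    function(nl) max_extension_distance(build_dimer(ig, "tip", linker_residues = nl)),
    0
  )
  expect_true(all(diff(dists) > 0))
  expect_equal(dists[4] - dists[1], 2 * 15 * 3.63 / 10, tolerance = 1e-9)
})

test_that("max extension is invariant under rigid transforms of the assembly", {
  ig <- make_toy_ig()
  d <- build_dimer(ig, "tip")
  ref <- max_extension_distance(d)
  rot <- glycoshield:::rotation_about_axis(c(1, 1, 0), 35)
  shift <- c(12, -7, 30)
  d2 <- d
  d2$anchor_a <- as.numeric(rot %*% d$anchor_a + shift)
  d2$anchor_b <- as.numeric(rot %*% d$anchor_b + shift)
  d2$normal <- as.numeric(rot %*% d$normal)
  expect_equal(max_extension_distance(d2), ref, tolerance = 1e-9)
})

test_that("tip-to-tip spans farther than side-to-side, inside the 15-30 nm window", {
  ig <- make_toy_ig()
  tip <- max_extension_distance(build_dimer(ig, "tip"))
  side <- max_extension_distance(build_dimer(ig, "side"))
  expect_gte(tip, side)
  expect_gte(side, 15 - 2) # acceptance tolerance band on the window edge
  expect_lte(tip, 30)
})

test_that("pulling ruptures below the geometric maximum, deterministically", {
  ig <- make_toy_ig()
  for (mode in c("tip", "side")) {
    d <- build_dimer(ig, mode)
    pr <- coarse_pull(d, pull_params(), seed = 1)
    expect_equal(pr$status, "ruptured")
    expect_lte(pr$rupture_distance_nm, max_extension_distance(d))
    expect_lte(pr$reported_distance_nm, pr$rupture_distance_nm + 1e-9)
    pr2 <- coarse_pull(d, pull_params(), seed = 1)
    expect_identical(pr, pr2)
  }
})

test_that("zero pull velocity never ruptures", {
  ig <- make_toy_ig()
  d <- build_dimer(ig, "tip")
  pr <- coarse_pull(d, pull_params(velocity = 0, max_steps = 2000), seed = 1)
  expect_equal(pr$status, "no-rupture")
  expect_true(is.na(pr$rupture_step))
})

test_that("stiffer interface springs rupture later", {
  ig <- make_toy_ig()
  d <- build_dimer(ig, "tip")
  steps <- vapply(
    c(1, 2, 6),
    function(k) coarse_pull(d, pull_params(k_interface = k), seed = 1)$rupture_step,
    0L
  )
  expect_true(all(diff(steps) > 0))
})
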