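# Occupancy grids, interface footprints, occlusion scoring, pore checks.

test_that("interface extraction recovers the constructed footprint exactly", {
  cx <- make_toy_complex()
  fp <- extract_interface(cx, "A", "B", cutoff = 5.0)
  expect_equal(fp$residues, attr(cx, "footprint"))
  expect_equal(fp$status, "ok")
  far <- make_toy_complex(displacement = 100)
  expect_warning(fp2 <- extract_interface(far, "A", "B"), "empty")
  expect_equal(length(fp2$residues), 0L)
  expect_error(extract_interface(cx, "Z", "B"), "not found")
})

test_that("grid occupancy fractions follow the frame-counting oracle", {
  # single frame, single atom -> one voxel at fraction 1
  e1 <- fake_ensemble(list(rbind(c(0.5, 0.5, 0.5))))
  g1 <- build_grid(e1, 1.0)
  expect_equal(sum(g1$occupancy > 0), 1L)
  expect_equal(max(g1$occupancy), 1)
  # two frames, different voxels -> two voxels at 0.5
  e2 <- fake_ensemble(list(rbind(c(0.5, 0.5, 0.5)), rbind(c(3.5, 0.5, 0.5))))
  g2 <- build_grid(e2, 1.0)
  expect_equal(sort(g2$occupancy[g2$occupancy > 0]), c(0.5, 0.5))
  # random ensembles match the direct counting oracle
  withr::with_seed(13, {
    frames <- lapply(1:6, function(i) matrix(runif(45, 0, 8), ncol = 3))
  })
  er <- fake_ensemble(frames)
  gr <- build_grid(er, 1.0)
  expect_equal(
    gr$occupancy,
    oracle_grid(frames, gr$origin, gr$voxel, gr$dim)
  )
  expect_error(build_grid(er, 0), "positive")
})

test_that("the ever-occupied voxel set is monotone under frame addition", {
  withr::with_seed(14, {
    frames <- lapply(1:8, function(i) matrix(runif(30, 0, 6), ncol = 3))
  })
  g_few <- build_grid(fake_ensemble(frames[1:4]), 1.0)
  g_all <- build_grid(fake_ensemble(frames), 1.0)
  occ_few <- which(g_few$occupancy > 0, arr.ind = TRUE)
  # re-index into the bigger grid (same voxel size; origins may differ)
  shift <- round((g_few$origin - g_all$origin) / g_all$voxel)
  occ_few_in_all <- sweep(occ_few, 2, shift, `+`)
  for (r in seq_len(nrow(occ_few_in_all))) {
    expect_gt(g_all$occupancy[
      occ_few_in_all[r, 1], occ_few_in_all[r, 2], occ_few_in_all[r, 3]
    ], 0)
  }
})

test_that("grid text maps round-trip", {
  withr::with_seed(15, {
    frames <- lapply(1:3, function(i) matrix(runif(15, 0, 4), ncol = 3))
  })
  g <- build_grid(fake_ensemble(frames), 1.0)
  path <- withr::local_tempfile(fileext = ".map")
  write_grid_map(g, path)
  back <- read_grid_map(path)
  expect_equal(back$dim, g$dim)
  expect_equal(back$occupancy, g$occupancy, tolerance = 1e-6)
})

test_that("occlusion coverage is monotone in its thresholds", {
  cx <- make_toy_complex()
  fp <- attr(cx, "footprint")
  withr::with_seed(16, {
    # a loose cloud near some footprint residues
    frames <- lapply(1:10, function(i) {
      cbind(
        runif(40, 3.8 * 12, 3.8 * 22), runif(40, -4, 8), runif(40, -4, 4)
      )
    })
  })
  ens <- fake_ensemble(frames)
  cov <- vapply(
    c(2, 4.5, 7, 10),
    function(cut) {
      occlusion_score(ens, cx, "A", fp, contact_cutoff = cut)$coverage
    },
    0
  )
  expect_true(all(diff(cov) >= 0)) # nondecreasing in contact cutoff
  cov_thr <- vapply(
    c(0.1, 0.3, 0.6, 0.9),
    function(thr) {
      occlusion_score(ens, cx, "A", fp, frame_threshold = thr)$coverage
    },
    0
  )
  expect_true(all(diff(cov_thr) <= 0)) # nonincreasing in frame threshold
})

test_that("engulfed footprints are blocked and empty ensembles accessible", {
  cx <- make_toy_complex()
  fp <- attr(cx, "footprint")
  # dense cloud engulfing every footprint residue in every frame
  res_xyz <- structure_coords(cx, chain = "A", resno = fp)
  frames <- lapply(1:5, function(i) {
    sweep(res_xyz, 2, c(0, 2.0, 0), `+`) # 2 A off every residue
  })
  rep_blocked <- occlusion_score(fake_ensemble(frames), cx, "A", fp)
  expect_equal(rep_blocked$coverage, 1)
  expect_equal(rep_blocked$verdict, "blocked")
  rep_empty <- occlusion_score(fake_ensemble(list()), cx, "A", fp)
  expect_equal(rep_empty$coverage, 0)
  expect_equal(rep_empty$verdict, "accessible")
})

test_that("binding verdicts follow the documented thresholds", {
  expect_equal(glycoshield:::occlusion_verdict(0), "accessible")
  expect_equal(glycoshield:::occlusion_verdict(1), "blocked")
  expect_equal(glycoshield:::occlusion_verdict(0.5), "partial")
  expect_equal(glycoshield:::occlusion_verdict(0.8), "blocked") # boundary
  expect_equal(glycoshield:::occlusion_verdict(0.2), "accessible") # boundary
  cx <- make_toy_complex()
  fp <- attr(cx, "footprint")
  res_xyz <- structure_coords(cx, chain = "A", resno = fp)
  blocked <- occlusion_score(
    fake_ensemble(list(sweep(res_xyz, 2, c(0, 2, 0), `+`))), cx, "A", fp
  )
  open <- occlusion_score(fake_ensemble(list()), cx, "A", fp)
  v <- binding_verdict(list(beta1 = blocked, beta2 = open))
  expect_equal(v$verdict, c("blocked", "accessible"))
})

test_that("pore block fractions equal the cylinder-containment oracle", {
  axis_p <- c(0, 0, 0)
  axis_d <- c(0, 0, 1)
  inside <- rbind(c(1, 1, 10)) # r ~ 1.4, z 10
  outside <- rbind(c(20, 0, 10))
  ens <- fake_ensemble(list(inside, outside, inside))
  expect_equal(pore_block_check(ens, axis_p, axis_d, radius = 6, length = 30), 2 / 3)
  expect_equal(pore_block_check(fake_ensemble(list(outside)), axis_p, axis_d), 0)
  expect_equal(pore_block_check(fake_ensemble(list(inside)), axis_p, axis_d), 1)
  expect_error(pore_block_check(ens, axis_p, c(0, 0, 0)), "degenerate")
  # oracle comparison on random frames
  withr::with_seed(17, {
    frames <- lapply(1:20, function(i) matrix(runif(30, -10, 40), ncol = 3))
  })
  got <- pore_block_check(fake_ensemble(frames), axis_p, axis_d, 6, 30)
  want <- mean(vapply(frames, function(fr) {
    any(fr[, 3] >= 0 & fr[, 3] <= 30 & sqrt(fr[, 1]^2 + fr[, 2]^2) <= 6)
  }, NA))
  expect_equal(got, want)
})
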