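# Excluded-volume energy and torsional Metropolis sampling.

test_that("clash_energy matches its contract and the pair-sum oracle", {
  expect_equal(clash_energy(rbind(c(0, 0, 0)), rbind(c(10, 0, 0)), 2.4), 0)
  expect_equal(clash_energy(rbind(c(0, 0, 0)), rbind(c(0, 0, 0)), 2.4), 2.4^2)
  withr::with_seed(8, {
    a <- matrix(runif(30, 0, 5), ncol = 3)
    b <- matrix(runif(24, 0, 5), ncol = 3)
    expect_equal(clash_energy(a, b, 2.4), oracle_pair_energy(a, b, 2.4))
    expect_equal(clash_energy(a, b, 2.4), clash_energy(b, a, 2.4)) # symmetry
  })
})

test_that("membrane slabs validate their leaflet composition", {
  comp <- read.csv(
    system.file("extdata", "membrane_composition.csv", package = "glycoshield")
  )
  m <- membrane_slab(-15, 15, comp)
  expect_equal(sum(m$composition$upper_pct), 100, tolerance = 0.1)
  expect_equal(sum(m$composition$inner_pct), 100, tolerance = 0.1)
  bad <- comp
  bad$upper_pct[1] <- bad$upper_pct[1] + 5
  expect_error(membrane_slab(-15, 15, bad), "sum to")
  expect_error(membrane_slab(15, -15, comp), "outer plane")
})

test_that("the default protocol yields 30 reproducible clash-free frames", {
  fix <- cached_toy_ensemble()
  ens <- fix$ens
  expect_equal(length(ens$frames), 30L) # 150/5 protocol analog
  expect_equal(ens$status, "ok")
  # bit-identical rerun under the same seed
  ens2 <- sample_ensemble(fix$toy, fix$grafts, params = sampler_params(seed = 7))
  expect_identical(ens$frames, ens2$frames)
})

test_that("every frame passes the independent pair-distance clash oracle", {
  fix <- cached_toy_ensemble()
  toy <- fix$toy
  cutoff <- 2.4
  # protein context excluding the grafted Asn side-chain neighborhoods
  sites <- vapply(fix$grafts, function(g) g$site$resno, 0L)
  own <- toy$atoms$resno %in% sites & toy$atoms$elety %in% c("ND2", "CG", "OD1")
  ctx <- as.matrix(toy$atoms[!own, c("x", "y", "z")])
  tree <- fix$grafts[[1]]$tree
  parent_of <- setNames(tree$linkages$parent, tree$linkages$child)
  up <- function(id) if (id %in% names(parent_of)) parent_of[[id]] else NA
  near_tree <- function(a, b) {
    pa <- up(a)
    pb <- up(b)
    identical(pa, b) || identical(pb, a) ||
      (!is.na(pa) && !is.na(pb) && pa == pb) ||
      (!is.na(pa) && identical(up(pa), b)) || (!is.na(pb) && identical(up(pb), a))
  }
  for (fr in fix$ens$frames[c(1, 10, 20, 30)]) {
    info <- attr(fr, "atom_info")
    expect_gte(oracle_min_dist(fr, ctx), cutoff)
    # cross-graft clashes
    g1 <- fr[info$graft == 1, , drop = FALSE]
    g2 <- fr[info$graft == 2, , drop = FALSE]
    expect_gte(oracle_min_dist(g1, g2), cutoff)
    # intra-glycan beyond the 1-2/1-3 neighborhood
    for (gi in 1:2) {
      sub <- fr[info$graft == gi, , drop = FALSE]
      si <- info[info$graft == gi, ]
      nodes <- unique(si$node)
      for (i in seq_along(nodes)) {
        for (j in seq_along(nodes)) {
          if (j <= i || near_tree(nodes[i], nodes[j])) next
          expect_gte(oracle_min_dist(
            sub[si$node == nodes[i], , drop = FALSE],
            sub[si$node == nodes[j], , drop = FALSE]
          ), cutoff)
        }
      }
    }
    # membrane exclusion: nothing below the outer head-group plane minus
    # the head tolerance
    expect_true(all(fr[, 3] >= 15 - 1.5 - 1e-9))
  }
})

test_that("zero move width degenerates to the graft pose", {
  fix <- cached_toy_ensemble()
  sp0 <- sampler_params(seed = 7, move_width = 0, n_frames = 4)
  ens <- sample_ensemble(fix$toy, fix$grafts[1], params = sp0)
  ref <- fix$grafts[[1]]$coords
  attributes(ref) <- attributes(ref)["dim"]
  for (fr in ens$frames) {
    bare <- fr
    attributes(bare) <- attributes(bare)["dim"]
    expect_equal(bare, ref, tolerance = 1e-12)
  }
})

test_that("a wall beside the glycan is never penetrated", {
  st_atoms <- rbind(
    data.frame(
      chain = "A", resno = 1L, resid = "ASN",
      elety = c("CA", "CB", "CG", "OD1", "ND2"),
      x = c(0, 1.2, 2.2, 2.8, 2.7), y = c(0, 0.9, 0.2, -0.8, 1.2),
      z = c(0, 0.6, 1.5, 1.6, 2.4), stringsAsFactors = FALSE
    ),
    data.frame(
      chain = "A", resno = 2:3, resid = c("ALA", "THR"), elety = "CA",
      x = c(-3.8, -7.6), y = 0, z = 0, stringsAsFactors = FALSE
    )
  )
  grid <- expand.grid(y = seq(-20, 20, 1.2), z = seq(-16, 24, 1.2))
  wall <- data.frame(
    chain = "W", resno = seq_len(nrow(grid)) + 10L, resid = "UNK",
    elety = "CA", x = 6, y = grid$y, z = grid$z, stringsAsFactors = FALSE
  )
  st <- channel_structure(rbind(st_atoms, wall))
  g <- graft_glycan(st, "A", 1, default_glycan_tree(),
    params = sampler_params(seed = 5)
  )
  ens <- sample_ensemble(st, list(g), params = sampler_params(seed = 5, n_frames = 10))
  for (fr in ens$frames) {
    expect_true(all(fr[, 1] < 6)) # containment: everything stays wall-side
  }
})

test_that("ensembles export as multi-model PDB with metadata", {
  fix <- cached_toy_ensemble()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(fix$ens, path)
  lines <- readLines(path)
  expect_equal(sum(grepl("^MODEL", lines)), 30L)
  expect_true(file.exists(paste0(path, ".json")))
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  expect_equal(meta$seed, 7L)
})
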