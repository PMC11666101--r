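# Glycan grafting: anchoring geometry, rigidity, clash repair.

asn_platform <- function(x_res = "ALA") {
  atoms <- rbind(
    data.frame(
      chain = "A", resno = 1L, resid = "ASN",
      elety = c("CA", "CB", "CG", "OD1", "ND2"),
      x = c(0, 1.2, 2.2, 2.8, 2.7), y = c(0, 0.9, 0.2, -0.8, 1.2),
      z = c(0, 0.6, 1.5, 1.6, 2.4), stringsAsFactors = FALSE
    ),
    data.frame(
      chain = "A", resno = 2:3, resid = c(x_res, "THR"), elety = "CA",
      x = c(-3.8, -7.6), y = 0, z = 0, stringsAsFactors = FALSE
    )
  )
  channel_structure(atoms)
}

single_glcnac <- function() {
  glycan_tree(
    data.frame(id = "g1", sugar = "GlcNAc"),
    data.frame(
      parent = character(0), child = character(0), anomeric = character(0),
      donor = integer(0), acceptor = integer(0)
    ),
    name = "single"
  )
}

test_that("the root GlcNAc is bonded to the Asn nitrogen at template length", {
  st <- asn_platform()
  g <- graft_glycan(st, "A", 1, single_glcnac())
  info <- attr(g$coords, "atom_info")
  c1 <- g$coords[info$atom == "C1", ]
  expect_equal(sqrt(sum((c1 - g$anchor$ND2)^2)), 1.45, tolerance = 1e-8)
  expect_equal(g$energy, 0)
})

test_that("grafting the representative tree yields a clash-free pose", {
  st <- asn_platform()
  tree <- default_glycan_tree()
  g <- graft_glycan(st, "A", 1, tree, params = sampler_params(seed = 2))
  ctx <- structure_coords(st)
  ctx <- ctx[-(3:5), , drop = FALSE] # drop CG/OD1/ND2 (covalent neighborhood)
  expect_gte(oracle_min_dist(g$coords, ctx), 2.4)
})

test_that("grafting onto a non-sequon or proline-X site is rejected", {
  expect_error(
    graft_glycan(asn_platform("PRO"), "A", 1, single_glcnac()),
    "not a sequon"
  )
  st <- asn_platform()
  expect_error(graft_glycan(st, "A", 2, single_glcnac()), "not an asparagine")
})

test_that("torsion moves preserve ring geometry and glycosidic bond lengths", {
  st <- asn_platform()
  tree <- default_glycan_tree()
  anchor <- list(
    ND2 = c(2.7, 1.2, 2.4), CG = c(2.2, 0.2, 1.5), CB = c(1.2, 0.9, 0.6)
  )
  ring <- c("C1", "C2", "C3", "C4", "C5", "O5")
  withr::with_seed(4, {
    for (rep in 1:5) {
      tor <- default_torsions(tree)
      tor$phi <- runif(nrow(tor), -180, 180)
      tor$psi <- runif(nrow(tor), -180, 180)
      tor$omega[!is.na(tor$omega)] <- runif(sum(!is.na(tor$omega)), -180, 180)
      coords <- glycoshield:::build_glycan_coords(tree, tor, anchor)
      info <- attr(coords, "atom_info")
      for (node in unique(info$node)) {
        sugar <- info$sugar[info$node == node][1]
        tpl <- monosaccharide_template(sugar)$coords[ring, ]
        got <- coords[info$node == node, ][match(ring, info$atom[info$node == node]), ]
        expect_equal(as.numeric(dist(got)), as.numeric(dist(tpl)),
          tolerance = 1e-7
        )
      }
      # glycosidic bonds sit at template length for any torsions
      for (i in seq_len(nrow(tree$linkages))) {
        lk <- tree$linkages[i, ]
        c1 <- coords[info$node == lk$child & info$atom == "C1", ]
        o_name <- paste0("O", lk$acceptor)
        ok <- coords[info$node == lk$parent & info$atom == o_name, ]
        expect_equal(sqrt(sum((c1 - ok)^2)), 1.43, tolerance = 1e-7)
      }
    }
  })
})

test_that("an unresolvable steric lock is reported as an error", {
  st <- asn_platform()
  # cage the site in a dense shell so no torsion pose can be clash-free
  sph <- expand.grid(x = seq(-8, 10, 2), y = seq(-8, 10, 2), z = seq(-6, 12, 2))
  cage <- data.frame(
    chain = "W", resno = seq_len(nrow(sph)) + 100L, resid = "UNK",
    elety = "CA", x = sph$x, y = sph$y, z = sph$z, stringsAsFactors = FALSE
  )
  keep <- sqrt((cage$x - 2.7)^2 + (cage$y - 1.2)^2 + (cage$z - 2.4)^2) > 3
  caged <- channel_structure(rbind(st$atoms, cage[keep, ]))
  expect_error(
    graft_glycan(caged, "A", 1, default_glycan_tree(),
      params = sampler_params(seed = 1, max_attempts = 150)
    ),
    "steric lock"
  )
})
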