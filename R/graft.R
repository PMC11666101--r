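# Grafting a glycan tree onto an asparagine site.
#
# The glycan is built residue-by-residue from rigid templates along the tree
# by forward kinematics: each glycosidic linkage carries phi/psi torsions
# (plus omega for 1-6 linkages), and the root linkage to the Asn side-chain
# nitrogen carries its own phi/psi. Rebuilding from a torsion vector is exact
# and preserves all template-internal geometry, so torsional moves can never
# distort bonds or rings.

GLYC_BOND_C1_O <- 1.43 # anomeric C to acceptor O, Angstrom
GLYC_BOND_C1_N <- 1.45 # anomeric C to Asn ND2
GLYC_ANGLE_AT_O <- 116
GLYC_ANGLE_AT_C1 <- 109.5
ANOMER_DELTA <- c(alpha = -122, beta = 122) # C2 offset about the glycosidic bond

#' Default torsion table for a glycan tree
#'
#' One row per linkage (the pseudo-linkage `"root"` attaches the tree to the
#' Asn) with starting values phi = -80, psi = 180, omega = 60 (omega only for
#' 1-6 linkages, `NA` elsewhere).
#'
#' @param tree A [glycan_tree()].
#' @return Data frame `child`, `phi`, `psi`, `omega`.
#' @export
default_torsions <- function(tree) {
  stopifnot(inherits(tree, "glycan_tree"))
  children <- c("root", tree$linkages$child)
  acceptor <- c(NA_integer_, tree$linkages$acceptor)
  data.frame(
    child = children,
    phi = rep(-80, length(children)),
    psi = rep(180, length(children)),
    omega = ifelse(!is.na(acceptor) & acceptor == 6L, 60, NA_real_),
    stringsAsFactors = FALSE
  )
}

# Precomputed kinematic plan for a tree: BFS placement order, per-node
# template matrices and attachment atom indices, torsion-row mapping, the
# atom-info table (built once), and the torsion move slots. The rebuild hot
# path works on plain matrices only.
glycan_plan <- function(tree) {
  stopifnot(inherits(tree, "glycan_tree"), nrow(tree$nodes) > 0L)
  ids <- tree$nodes$id
  sugar_of <- setNames(tree$nodes$sugar, ids)
  # BFS order
  order_ids <- tree$root
  frontier <- tree$root
  while (length(frontier) > 0L) {
    nxt <- tree$linkages$child[tree$linkages$parent %in% frontier]
    order_ids <- c(order_ids, nxt)
    frontier <- nxt
  }
  tor_children <- c("root", tree$linkages$child)
  atom_index <- function(tpl, name) which(rownames(tpl$coords) == name)
  nodes <- list()
  offset <- 0L
  offsets <- setNames(integer(length(order_ids)), order_ids)
  for (k in seq_along(order_ids)) {
    id <- order_ids[k]
    tpl <- monosaccharide_template(sugar_of[[id]])
    na <- nrow(tpl$coords)
    tpl_local <- to_local_frame(
      tpl$coords, tpl$coords["C1", ], tpl$coords["O5", ], tpl$coords["C2", ]
    )
    offsets[id] <- offset
    lk <- tree$linkages[tree$linkages$child == id, , drop = FALSE]
    if (nrow(lk) == 1L) {
      ptpl <- monosaccharide_template(sugar_of[[lk$parent]])
      att <- ptpl$attach[[as.character(lk$acceptor)]]
      if (is.null(att)) {
        stop("no attachment defined for acceptor carbon ", lk$acceptor)
      }
      att_idx <- vapply(att, function(nm) atom_index(ptpl, nm), 0L)
      omega_idx <- if (lk$acceptor == 6L) {
        c(atom_index(ptpl, "C4"), atom_index(ptpl, "C5"), atom_index(ptpl, "C6"),
          atom_index(ptpl, "O6"))
      } else {
        NULL
      }
      nodes[[k]] <- list(
        id = id, tpl = tpl$coords, tpl_local = tpl_local, n_atoms = na,
        frame_idx = c(atom_index(tpl, "C1"), atom_index(tpl, "O5"),
                      atom_index(tpl, "C2")),
        parent = lk$parent, acceptor = lk$acceptor,
        anomer_delta = ANOMER_DELTA[[lk$anomeric]],
        att_idx = att_idx, omega_idx = omega_idx,
        tor_row = match(id, tor_children), bond = GLYC_BOND_C1_O
      )
    } else {
      nodes[[k]] <- list(
        id = id, tpl = tpl$coords, tpl_local = tpl_local, n_atoms = na,
        frame_idx = c(atom_index(tpl, "C1"), atom_index(tpl, "O5"),
                      atom_index(tpl, "C2")),
        parent = NA_character_, anomer_delta = ANOMER_DELTA[["beta"]],
        tor_row = 1L, bond = GLYC_BOND_C1_N
      )
    }
    offset <- offset + na
  }
  info <- data.frame(
    residue_index = rep(match(order_ids, order_ids), # 1..n in placement order
      vapply(nodes, `[[`, 0L, "n_atoms")
    ),
    node = rep(order_ids, vapply(nodes, `[[`, 0L, "n_atoms")),
    sugar = rep(unname(sugar_of[order_ids]), vapply(nodes, `[[`, 0L, "n_atoms")),
    atom = unlist(lapply(nodes, function(n) rownames(n$tpl))),
    stringsAsFactors = FALSE
  )
  # torsion move slots (row, col): phi = 1, psi = 2, omega = 3 where defined
  acceptor <- c(NA_integer_, tree$linkages$acceptor)
  nrow_t <- length(tor_children)
  slots <- rbind(
    cbind(seq_len(nrow_t), 1L),
    cbind(seq_len(nrow_t), 2L),
    if (any(!is.na(acceptor) & acceptor == 6L)) {
      cbind(which(!is.na(acceptor) & acceptor == 6L), 3L)
    }
  )
  list(
    nodes = nodes, order_ids = order_ids, offsets = offsets, info = info,
    n_atoms = offset, tor_children = tor_children, slots = slots
  )
}

tor_df_to_mat <- function(torsions, plan) {
  m <- as.matrix(torsions[
    match(plan$tor_children, torsions$child), c("phi", "psi", "omega")
  ])
  rownames(m) <- plan$tor_children
  m
}

tor_mat_to_df <- function(m, plan) {
  data.frame(
    child = plan$tor_children, phi = m[, 1], psi = m[, 2], omega = m[, 3],
    stringsAsFactors = FALSE, row.names = NULL
  )
}

# Matrix-only forward-kinematic rebuild (hot path).
build_coords_fast <- function(plan, tor, anchor) {
  coords <- matrix(0, plan$n_atoms, 3)
  for (nd in plan$nodes) {
    row <- nd$tor_row
    phi <- tor[row, 1]
    psi <- tor[row, 2]
    if (is.na(nd$parent)) {
      a <- anchor$ND2
      b <- anchor$CG
      c3 <- anchor$CB
    } else {
      poff <- plan$offsets[[nd$parent]]
      if (!is.null(nd$omega_idx)) {
        oi <- nd$omega_idx
        a <- place_atom(
          coords[poff + oi[1], ], coords[poff + oi[2], ],
          coords[poff + oi[3], ], 1.43, 109.5, tor[row, 3]
        )
        coords[poff + oi[4], ] <- a
        b <- coords[poff + nd$att_idx[2], ]
        c3 <- coords[poff + nd$att_idx[3], ]
      } else {
        a <- coords[poff + nd$att_idx[1], ]
        b <- coords[poff + nd$att_idx[2], ]
        c3 <- coords[poff + nd$att_idx[3], ]
      }
    }
    c1 <- place_atom(c3, b, a, nd$bond, GLYC_ANGLE_AT_O, psi)
    o5 <- place_atom(b, a, c1, 1.43, GLYC_ANGLE_AT_C1, phi)
    c2 <- place_atom(b, a, c1, 1.52, GLYC_ANGLE_AT_C1, phi + nd$anomer_delta)
    off <- plan$offsets[[nd$id]]
    coords[off + seq_len(nd$n_atoms), ] <- from_local_frame(
      nd$tpl_local, c1, o5, c2
    )
  }
  coords
}

# Forward-kinematic rebuild of glycan coordinates from a torsion table.
# anchor: named list with ND2, CG, CB coordinates of the Asn side chain.
# Returns an atom coordinate matrix with an "atom_info" attribute
# (residue_index, node id, sugar, atom name).
build_glycan_coords <- function(tree, torsions, anchor, plan = NULL) {
  if (is.null(plan)) plan <- glycan_plan(tree)
  coords <- build_coords_fast(plan, tor_df_to_mat(torsions, plan), anchor)
  attr(coords, "atom_info") <- plan$info
  coords
}

#' Graft a glycan tree onto an asparagine site of a structure
#'
#' Builds the glycan from rigid templates at default glycosidic torsions,
#' then greedily adjusts torsions (downhill moves only) until the pose is
#' clash-free against the protein at the configured cutoff, or the attempt
#' budget is exhausted. The site must be a sequon: Asn with a non-proline
#' following residue and S/T at N+2, with a resolvable side-chain nitrogen.
#'
#' @param struct A [channel_structure()].
#' @param chain Chain id of the site.
#' @param resno Residue number of the Asn.
#' @param tree A [glycan_tree()].
#' @param params A [sampler_params()]; `clash_cutoff`, `move_width`,
#'   `max_attempts` and `seed` are used.
#' @return A `grafted_glycan`: list with `site`, `tree`, `torsions`,
#'   `coords` (atom matrix with `atom_info` attribute), `anchor`, `energy`.
#' @export
graft_glycan <- function(struct, chain, resno, tree, params = sampler_params()) {
  stopifnot(inherits(struct, "channel_structure"), inherits(tree, "glycan_tree"))
  check_sequon_site(struct, chain, resno)
  res <- residue_atoms(struct, chain, resno)
  need <- c("ND2", "CG", "CB")
  if (!all(need %in% names(res))) {
    stop(
      "Asn ", resno, " lacks side-chain atoms (",
      paste(setdiff(need, names(res)), collapse = ", "), ")"
    )
  }
  anchor <- res[need]
  # protein context: exclude the anchor Asn side chain itself
  a <- struct$atoms
  own <- a$chain == chain & a$resno == resno & a$elety %in% c("ND2", "CG", "OD1")
  context <- as.matrix(a[!own, c("x", "y", "z")])
  # only atoms near the site matter for clashes
  d2 <- (context[, 1] - anchor$ND2[1])^2 + (context[, 2] - anchor$ND2[2])^2 +
    (context[, 3] - anchor$ND2[3])^2
  context <- context[d2 < 40^2, , drop = FALSE]

  plan <- glycan_plan(tree)
  mask <- self_exempt_mask(tree, plan$info)
  tor <- tor_df_to_mat(default_torsions(tree), plan)
  energy_of <- function(tor) {
    coords <- build_coords_fast(plan, tor, anchor)
    attr(coords, "atom_info") <- plan$info
    clash_energy(coords, context, cutoff = params$clash_cutoff) +
      glycan_self_energy(coords, tree, cutoff = params$clash_cutoff, mask = mask)
  }
  e <- energy_of(tor)
  best <- tor
  e_best <- e
  withr::with_seed(params$seed, {
    attempts <- 0L
    stale <- 0L
    while (e_best > 0 && attempts < params$max_attempts) {
      attempts <- attempts + 1L
      if (stale >= 100L) {
        # basin hop: re-randomize every torsion and descend again
        tor[, 1] <- runif(nrow(tor), -180, 180)
        tor[, 2] <- runif(nrow(tor), -180, 180)
        tor[!is.na(tor[, 3]), 3] <- runif(sum(!is.na(tor[, 3])), -180, 180)
        e <- energy_of(tor)
        stale <- 0L
      }
      cand <- perturb_tor_mat(tor, plan$slots, max(params$move_width, 15))
      e2 <- energy_of(cand)
      if (e2 <= e) {
        stale <- if (e2 < e) 0L else stale + 1L
        tor <- cand
        e <- e2
        if (e < e_best) {
          best <- tor
          e_best <- e
        }
      } else {
        stale <- stale + 1L
      }
    }
  })
  if (e_best > 0) {
    stop(
      "could not resolve steric lock at ", chain, "/", resno, " within ",
      params$max_attempts, " attempts (residual clash energy ",
      signif(e_best, 3), ")"
    )
  }
  torsions <- tor_mat_to_df(best, plan)
  coords <- build_glycan_coords(tree, torsions, anchor, plan = plan)
  structure(
    list(
      site = list(chain = chain, resno = resno),
      tree = tree, torsions = torsions, coords = coords,
      anchor = anchor, energy = e_best, plan = plan
    ),
    class = "grafted_glycan"
  )
}

#' @export
print.grafted_glycan <- function(x, ...) {
  cat(sprintf(
    "<grafted_glycan> '%s' on %s/%d (%d atoms, clash energy %g)\n",
    x$tree$name, x$site$chain, x$site$resno, nrow(x$coords), x$energy
  ))
  invisible(x)
}

check_sequon_site <- function(struct, chain, resno) {
  aa3to1 <- c(
    ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
    GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
    MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
    TYR = "Y", VAL = "V"
  )
  res1 <- function(rn) {
    a <- struct$atoms[struct$atoms$chain == chain & struct$atoms$resno == rn, ]
    if (nrow(a) == 0L) {
      return(NA_character_)
    }
    code <- aa3to1[a$resid[1L]]
    if (is.na(code)) "X" else unname(code)
  }
  r0 <- res1(resno)
  r1 <- res1(resno + 1L)
  r2 <- res1(resno + 2L)
  if (is.na(r0) || r0 != "N") {
    stop("residue ", resno, " in chain ", chain, " is not an asparagine")
  }
  if (is.na(r1) || is.na(r2) || r1 == "P" || r1 == "X" || !(r2 %in% c("S", "T"))) {
    stop(
      "residue ", resno, " in chain ", chain,
      " is not a sequon start (need NX[S/T], X != P)"
    )
  }
  invisible(TRUE)
}

# Single-torsion move on the matrix representation (row, col) slots.
perturb_tor_mat <- function(tor, slots, move_width) {
  pick <- slots[sample.int(nrow(slots), 1L), ]
  delta <- runif(1L, -move_width, move_width)
  val <- tor[pick[1L], pick[2L]] + delta
  tor[pick[1L], pick[2L]] <- ((val + 180) %% 360) - 180
  tor
}
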