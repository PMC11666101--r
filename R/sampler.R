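# Excluded-volume energy and torsional Metropolis sampling of glycan
# conformers over a fixed protein frame -- the desk-scale stand-in for
# all-atom MD: the quantity of interest is the geometric envelope of glycan
# conformations, which torsional sampling with excluded volume reproduces.

#' Soft-repulsion clash energy between two atom sets
#'
#' Sum over atom pairs closer than `cutoff` of `(cutoff - d)^2`; zero iff no
#' pair is below the cutoff, symmetric in its arguments, and maximal
#' (`cutoff^2` per pair) for coincident atoms.
#'
#' @param coords Numeric matrix (n x 3).
#' @param context Numeric matrix (m x 3). When `NULL`, all pairs *within*
#'   `coords` are scored.
#' @param cutoff Heavy-atom clash cutoff in Angstrom (default 2.4).
#' @return Non-negative scalar.
#' @export
clash_energy <- function(coords, context = NULL, cutoff = 2.4) {
  stopifnot(cutoff > 0)
  coords <- as.matrix(coords)
  if (is.null(context)) {
    if (nrow(coords) < 2L) {
      return(0)
    }
    d <- as.numeric(dist(coords))
    return(sum(pmax(cutoff - d, 0)^2))
  }
  context <- as.matrix(context)
  if (nrow(coords) == 0L || nrow(context) == 0L) {
    return(0)
  }
  d2 <- outer(rowSums(coords^2), rowSums(context^2), `+`) -
    2 * tcrossprod(coords, context)
  near <- d2 < cutoff^2
  if (!any(near)) {
    return(0)
  }
  sum((cutoff - sqrt(pmax(d2[near], 0)))^2)
}

# Atom-pair exemption mask for intra-glycan clashes: pairs within one
# residue, between a residue and its parent, and between residues two
# linkages apart (grandparent or sibling) are exempt -- their proximity is
# fixed by the linkage geometry, not a steric violation.
self_exempt_mask <- function(tree, info) {
  ids <- info$node[!duplicated(info$residue_index)] # placement order
  nr <- length(ids)
  parent_of <- setNames(tree$linkages$parent, tree$linkages$child)
  up <- function(id) if (id %in% names(parent_of)) parent_of[[id]] else NA_character_
  close <- diag(TRUE, nr)
  if (nr > 1L) {
    for (i in seq_len(nr - 1L)) {
      for (j in (i + 1L):nr) {
        pi_ <- up(ids[i])
        pj_ <- up(ids[j])
        near <- identical(pi_, ids[j]) || identical(pj_, ids[i]) ||
          (!is.na(pi_) && !is.na(pj_) && pi_ == pj_) ||
          (!is.na(pi_) && identical(up(pi_), ids[j])) ||
          (!is.na(pj_) && identical(up(pj_), ids[i]))
        close[i, j] <- close[j, i] <- near
      }
    }
  }
  close[info$residue_index, info$residue_index]
}

# Intra-glycan clash energy with the 1-2/1-3 neighbor exemption above.
glycan_self_energy <- function(coords, tree, cutoff = 2.4, mask = NULL) {
  if (is.null(mask)) {
    info <- attr(coords, "atom_info")
    if (is.null(info)) stop("coordinates lack an atom_info attribute")
    if (max(info$residue_index) < 2L) {
      return(0)
    }
    mask <- self_exempt_mask(tree, info)
  }
  if (all(mask)) {
    return(0)
  }
  s <- rowSums(coords^2)
  d2 <- outer(s, s, `+`) - 2 * tcrossprod(coords)
  near <- d2 < cutoff^2 & !mask
  if (!any(near)) {
    return(0)
  }
  sum((cutoff - sqrt(pmax(d2[near], 0)))^2) / 2
}

#' Membrane slab model
#'
#' Two head-group planes (z, Angstrom) with a per-leaflet lipid composition
#' carried as reporting metadata. Per-leaflet fractions must each sum to 100
#' within 0.1.
#'
#' @param z_inner,z_outer Inner/outer head-group plane z (outer > inner).
#' @param composition Data frame `lipid`, `upper_pct`, `inner_pct`; defaults
#'   to the packaged plasma-membrane composition table.
#' @param head_tolerance Head-group tolerance (Angstrom) subtracted from the
#'   outer plane when testing slab penetration.
#' @return A `membrane_slab` object.
#' @export
membrane_slab <- function(z_inner = -15, z_outer = 15, composition = NULL,
                          head_tolerance = 1.5) {
  if (z_outer <= z_inner) stop("outer plane must lie above the inner plane")
  if (is.null(composition)) {
    composition <- load_paper_tables()$membrane
  }
  for (col in c("upper_pct", "inner_pct")) {
    s <- sum(composition[[col]])
    if (abs(s - 100) > 0.1) {
      stop("leaflet fractions ('", col, "') sum to ", s, ", not 100")
    }
  }
  structure(
    list(
      z_inner = z_inner, z_outer = z_outer, composition = composition,
      head_tolerance = head_tolerance
    ),
    class = "membrane_slab"
  )
}

membrane_energy <- function(coords, membrane) {
  if (is.null(membrane)) {
    return(0)
  }
  lim <- membrane$z_outer - membrane$head_tolerance
  z <- coords[, 3]
  viol <- z < lim & z > membrane$z_inner
  sum((lim - z[viol])^2)
}

#' Sampler parameters
#'
#' Defaults mirror the snapshot protocol of the reference MD analysis: 30
#' snapshots (a 150-unit horizon sampled every 5 units); the graft pose at
#' t = 0 is not counted as a frame.
#'
#' @param n_frames Snapshots to collect (default `horizon / interval` = 30).
#' @param horizon,interval Protocol analogs (150, 5) that set the default
#'   frame count.
#' @param move_width Torsion move half-width, degrees (moves are uniform in
#'   +/- `move_width`).
#' @param temperature Metropolis temperature factor on the excluded-volume
#'   energy (Angstrom^2 units).
#' @param clash_cutoff Heavy-atom clash cutoff, Angstrom.
#' @param seed RNG seed (recorded in ensemble metadata).
#' @param max_attempts Attempt budget per snapshot (and per graft repair).
#' @param steps_per_frame Metropolis sweeps between snapshots.
#' @return A `sampler_params` list.
#' @export
sampler_params <- function(n_frames = NULL, horizon = 150, interval = 5,
                           move_width = 30, temperature = 0.5,
                           clash_cutoff = 2.4, seed = 1L,
                           max_attempts = 20000L, steps_per_frame = 15L) {
  if (is.null(n_frames)) n_frames <- as.integer(horizon / interval)
  stopifnot(n_frames >= 1L, clash_cutoff > 0, move_width >= 0)
  structure(
    list(
      n_frames = as.integer(n_frames), horizon = horizon, interval = interval,
      move_width = move_width, temperature = temperature,
      clash_cutoff = clash_cutoff, seed = as.integer(seed),
      max_attempts = as.integer(max_attempts),
      steps_per_frame = as.integer(steps_per_frame)
    ),
    class = "sampler_params"
  )
}

#' Sample a clash-free glycan conformer ensemble
#'
#' Metropolis Monte Carlo over the glycosidic torsions of all grafted
#' glycans, with a hard-sphere-soft-penalty excluded volume against the
#' protein, the membrane slab, the glycan itself and the other glycans.
#' Snapshots are recorded every `steps_per_frame` sweeps, re-sampling until
#' the snapshot is clash-free; a snapshot that cannot be made clash-free
#' within the attempt budget truncates the ensemble (returned with a
#' warning and `status = "partial"`).
#'
#' @param struct A [channel_structure()] (the fixed protein frame).
#' @param grafts List of [graft_glycan()] results on `struct`.
#' @param membrane Optional [membrane_slab()]; defaults to the structure's
#'   own slab reference (possibly `NULL` = no membrane term).
#' @param params A [sampler_params()].
#' @return A `conformer_ensemble`: `frames` (list of atom matrices with
#'   `atom_info` attributes), `torsion_trace`, `params` (with seed and
#'   acceptance rate echoed), `status` (`"ok"`/`"partial"`), `sites`.
#' @export
sample_ensemble <- function(struct, grafts, membrane = NULL,
                            params = sampler_params()) {
  stopifnot(inherits(struct, "channel_structure"), length(grafts) >= 1L)
  if (is.null(membrane)) membrane <- struct$membrane
  if (inherits(grafts, "grafted_glycan")) grafts <- list(grafts)

  contexts <- lapply(grafts, function(g) {
    a <- struct$atoms
    own <- a$chain == g$site$chain & a$resno == g$site$resno &
      a$elety %in% c("ND2", "CG", "OD1")
    ctx <- as.matrix(a[!own, c("x", "y", "z")])
    d2 <- (ctx[, 1] - g$anchor$ND2[1])^2 + (ctx[, 2] - g$anchor$ND2[2])^2 +
      (ctx[, 3] - g$anchor$ND2[3])^2
    ctx[d2 < 40^2, , drop = FALSE]
  })

  plans <- lapply(grafts, function(g) {
    if (!is.null(g$plan)) g$plan else glycan_plan(g$tree)
  })
  state <- lapply(seq_along(grafts), function(i) {
    tor_df_to_mat(grafts[[i]]$torsions, plans[[i]])
  })
  coords_of <- function(i, tor) {
    build_coords_fast(plans[[i]], tor, grafts[[i]]$anchor)
  }
  coords <- lapply(seq_along(grafts), function(i) coords_of(i, state[[i]]))
  masks <- lapply(seq_along(grafts), function(i) {
    self_exempt_mask(grafts[[i]]$tree, plans[[i]]$info)
  })
  ng <- length(grafts)

  own_energy <- function(i, crd_i) {
    clash_energy(crd_i, contexts[[i]], cutoff = params$clash_cutoff) +
      glycan_self_energy(crd_i, grafts[[i]]$tree,
        cutoff = params$clash_cutoff, mask = masks[[i]]
      ) +
      membrane_energy(crd_i, membrane)
  }
  # cached decomposition: per-graft own terms and the pairwise cross matrix
  e_own <- vapply(seq_len(ng), function(i) own_energy(i, coords[[i]]), 0)
  e_cross <- matrix(0, ng, ng)
  if (ng > 1L) {
    for (i in 2:ng) {
      for (j in seq_len(i - 1L)) {
        e_cross[i, j] <- e_cross[j, i] <-
          clash_energy(coords[[i]], coords[[j]], cutoff = params$clash_cutoff)
      }
    }
  }

  frames <- vector("list", params$n_frames)
  n_acc <- 0L
  n_try <- 0L
  status <- "ok"
  withr::with_seed(params$seed, {
    sweep_once <- function(temperature = params$temperature) {
      gi <- sample.int(ng, 1L)
      cand_tor <- perturb_tor_mat(state[[gi]], plans[[gi]]$slots, params$move_width)
      cand_crd <- coords_of(gi, cand_tor)
      cand_own <- own_energy(gi, cand_crd)
      cand_cross <- vapply(seq_len(ng), function(j) {
        if (j == gi) {
          return(0)
        }
        clash_energy(cand_crd, coords[[j]], cutoff = params$clash_cutoff)
      }, 0)
      delta <- (cand_own - e_own[gi]) + sum(cand_cross) - sum(e_cross[gi, ])
      n_try <<- n_try + 1L
      accept <- if (temperature <= 0) {
        delta <= 0
      } else {
        runif(1L) < exp(-delta / temperature)
      }
      if (accept) {
        state[[gi]] <<- cand_tor
        coords[[gi]] <<- cand_crd
        e_own[gi] <<- cand_own
        e_cross[gi, ] <<- cand_cross
        e_cross[, gi] <<- cand_cross
        n_acc <<- n_acc + 1L
      }
      accept
    }
    total_now <- function() sum(e_own) + sum(e_cross) / 2
    for (f in seq_len(params$n_frames)) {
      for (s in seq_len(params$steps_per_frame)) sweep_once()
      # repair phase: sample at a colder temperature until clash-free
      extra <- 0L
      while (total_now() > 1e-9 && extra < params$max_attempts) {
        sweep_once(temperature = params$temperature * 0.2)
        extra <- extra + 1L
      }
      if (total_now() > 1e-9) {
        frames <- frames[seq_len(f - 1L)]
        status <- "partial"
        warning(
          "could not reach a clash-free snapshot for frame ", f,
          " within the attempt budget; returning ", f - 1L, " frames"
        )
        break
      }
      fr <- do.call(rbind, coords)
      info <- do.call(rbind, lapply(seq_along(coords), function(i) {
        gi <- plans[[i]]$info
        gi$graft <- i
        gi$site_resno <- grafts[[i]]$site$resno
        gi
      }))
      attr(fr, "atom_info") <- info
      frames[[f]] <- fr
    }
  })

  meta <- unclass(params)
  meta$acceptance_rate <- if (n_try > 0L) n_acc / n_try else NA_real_
  meta$rng <- "Mersenne-Twister (R default)"
  structure(
    list(
      frames = frames,
      params = meta,
      status = status,
      sites = lapply(grafts, `[[`, "site"),
      structure_ref = struct
    ),
    class = "conformer_ensemble"
  )
}

#' @export
print.conformer_ensemble <- function(x, ...) {
  cat(sprintf(
    "<conformer_ensemble> %d frames over %d glycan(s), status %s, acceptance %.2f\n",
    length(x$frames), length(x$sites), x$status, x$params$acceptance_rate
  ))
  invisible(x)
}
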