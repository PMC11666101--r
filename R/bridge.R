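# Beta1 Ig-domain trans dimers bridging opposed membranes: dimer assembly in
# tip-to-tip or side-to-side mode, closed-form maximum membrane-to-membrane
# distance at full linker extension, and a coarse bead-spring pulling routine
# mirroring a constant-velocity rupture protocol.

LINKER_CONTOUR_PER_RES <- 3.63 # trans Calpha-Calpha, Angstrom

#' Assemble a trans dimer of Ig domains between opposed membranes
#'
#' Copy A keeps the input coordinates (long axis along +z, C-terminal linker
#' anchor at the bottom); copy B is copy A rotated 180 degrees about the x
#' axis (so its anchor points at the opposing membrane) and placed according
#' to the mode: `"tip"` stacks the membrane-distal turn tips of both copies
#' with a contact `gap`, `"side"` packs the beta-sheet faces laterally with a
#' stagger of `side_offset` along z. Interface residue pairs are the
#' cross-copy Calpha pairs within `contact_cutoff`.
#'
#' @param ig A [channel_structure()] with one chain: the Ig domain, long axis
#'   along z, anchor residue at minimal z (e.g. [make_toy_ig()]).
#' @param mode `"tip"` (tip-to-tip) or `"side"` (side-to-side).
#' @param anchor_resno Residue number of the linker anchor on the domain
#'   (defaults to the structure's `anchor_resno` attribute).
#' @param linker_residues Number of flexible linker residues between the
#'   domain boundary and the pulled terminal residue (M154 analog).
#' @param gap Tip contact gap, Angstrom.
#' @param side_offset z stagger of the side-to-side packing, Angstrom.
#' @param contact_cutoff Interface contact cutoff, Angstrom.
#' @param anchor_offset Membrane anchoring offset per side, Angstrom.
#' @return A `trans_assembly`: atom tables for both copies, `mode`,
#'   `normal` (membrane normal), `anchor_a`/`anchor_b` (xyz + resno),
#'   `linker` (count, contour per residue), `interface` (pair table),
#'   `membranes` (z of both head-group planes at full extension).
#' @export
build_dimer <- function(ig, mode = c("tip", "side"), anchor_resno = NULL,
                        linker_residues = 15L, gap = 4.0, side_offset = 8.0,
                        contact_cutoff = 6.0, anchor_offset = 0) {
  stopifnot(inherits(ig, "channel_structure"))
  mode <- match.arg(mode)
  if (is.null(anchor_resno)) anchor_resno <- attr(ig, "anchor_resno")
  if (is.null(anchor_resno)) stop("anchor residue not given and not annotated")
  a <- ig$atoms
  if (!anchor_resno %in% a$resno) stop("anchor residue missing from the domain")

  xyz_a <- as.matrix(a[, c("x", "y", "z")])
  cen <- colMeans(xyz_a)
  # 180-degree rotation about x through the centroid: y -> -y, z -> -z
  xyz_b <- sweep(xyz_a, 2, cen)
  xyz_b[, 2] <- -xyz_b[, 2]
  xyz_b[, 3] <- -xyz_b[, 3]
  xyz_b <- sweep(xyz_b, 2, cen, `+`)

  if (mode == "tip") {
    shift <- c(0, 0, max(xyz_a[, 3]) + gap - min(xyz_b[, 3]))
  } else {
    shift <- c(
      max(xyz_a[, 1]) + 4.5 - min(xyz_b[, 1]), 0,
      (min(xyz_a[, 3]) + side_offset) - min(xyz_b[, 3])
    )
  }
  xyz_b <- sweep(xyz_b, 2, shift, `+`)

  atoms_a <- a
  atoms_a$chain <- "A"
  atoms_b <- a
  atoms_b$chain <- "B"
  atoms_b[, c("x", "y", "z")] <- xyz_b

  ca_a <- atoms_a[atoms_a$elety == "CA", , drop = FALSE]
  ca_b <- atoms_b[atoms_b$elety == "CA", , drop = FALSE]
  ma <- as.matrix(ca_a[, c("x", "y", "z")])
  mb <- as.matrix(ca_b[, c("x", "y", "z")])
  d2 <- outer(rowSums(ma^2), rowSums(mb^2), `+`) - 2 * ma %*% t(mb)
  pairs <- which(d2 <= contact_cutoff^2, arr.ind = TRUE)
  if (nrow(pairs) == 0L) {
    stop("dimer placement produced an empty interface; not a dimer")
  }
  if (min(d2) < (0.8 * contact_cutoff / 3)^2) {
    stop("dimer placement clashes (Calpha pairs nearly coincident)")
  }
  interface <- data.frame(
    resno_a = ca_a$resno[pairs[, 1]],
    resno_b = ca_b$resno[pairs[, 2]],
    dist = sqrt(d2[pairs])
  )

  anchor_a <- as.numeric(ca_a[ca_a$resno == anchor_resno, c("x", "y", "z")])
  anchor_b <- as.numeric(ca_b[ca_b$resno == anchor_resno, c("x", "y", "z")])
  normal <- c(0, 0, 1)
  contour <- linker_residues * LINKER_CONTOUR_PER_RES
  z_a <- sum(anchor_a * normal) - contour - anchor_offset
  z_b <- sum(anchor_b * normal) + contour + anchor_offset
  if (z_b <= z_a) stop("membranes are not separated; invalid assembly")

  structure(
    list(
      atoms_a = atoms_a, atoms_b = atoms_b, mode = mode,
      normal = normal,
      anchor_a = anchor_a, anchor_b = anchor_b, anchor_resno = anchor_resno,
      linker = list(
        residues = as.integer(linker_residues),
        contour_per_res = LINKER_CONTOUR_PER_RES
      ),
      anchor_offset = anchor_offset,
      interface = interface,
      membranes = c(a = z_a, b = z_b)
    ),
    class = "trans_assembly"
  )
}

#' @export
print.trans_assembly <- function(x, ...) {
  cat(sprintf(
    "<trans_assembly> %s-to-%s dimer, %d interface contacts, max extension %.2f nm\n",
    x$mode, x$mode, nrow(x$interface), max_extension_distance(x)
  ))
  invisible(x)
}

#' Maximum membrane-to-membrane distance of a trans assembly
#'
#' Closed form at full linker extension normal to the membranes:
#' `2 x (linker contour) + dimer span along the normal + 2 x anchor offset`,
#' where the span is the anchor-to-anchor separation projected on the
#' membrane normal. Deterministic; invariant under rigid transforms of the
#' whole assembly and monotone in the linker residue count.
#'
#' @param assembly A [build_dimer()] result.
#' @return Distance in nm.
#' @export
max_extension_distance <- function(assembly) {
  stopifnot(inherits(assembly, "trans_assembly"))
  span <- abs(sum((assembly$anchor_b - assembly$anchor_a) * assembly$normal))
  contour <- assembly$linker$residues * assembly$linker$contour_per_res
  (2 * contour + span + 2 * assembly$anchor_offset) / 10
}

#' Pulling parameters for the coarse rupture protocol
#'
#' Analogs of a constant-velocity steered protocol: default velocity 5
#' (nm/ns analog) with spring constant 100 (kJ/mol nm^2 analog) on the
#' pulled termini, and the reported structure taken `report_offset` steps
#' before interface rupture (the 10-ps-before-rupture analog at the default
#' time step).
#'
#' @param velocity Pull velocity, nm/ns analog (>= 0).
#' @param spring_constant Pull spring constant (> 0), force-unit analog.
#' @param time_step Integration step, ns analog (default 0.0004, i.e. 0.02 A
#'   of pull-point travel per step at the default velocity).
#' @param max_steps Step budget.
#' @param report_offset Steps before rupture at which the reported structure
#'   is extracted (default 25 = 10 ps analog).
#' @param k_interface Breakable interface spring constant.
#' @param break_extension Extension beyond rest length at which an interface
#'   contact breaks, Angstrom.
#' @param noise Thermal noise amplitude (default 0: deterministic
#'   overdamped relaxation).
#' @return A `pull_params` list.
#' @export
pull_params <- function(velocity = 5, spring_constant = 100,
                        time_step = 4e-4, max_steps = 20000L,
                        report_offset = 25L, k_interface = 1,
                        break_extension = 0.5, noise = 0) {
  stopifnot(velocity >= 0, spring_constant > 0, time_step > 0)
  structure(
    list(
      velocity = velocity, spring_constant = spring_constant,
      time_step = time_step, max_steps = as.integer(max_steps),
      report_offset = as.integer(report_offset), k_interface = k_interface,
      break_extension = break_extension, noise = noise
    ),
    class = "pull_params"
  )
}

#' Coarse pulling of a trans dimer to rupture
#'
#' A coarse mechanical model of the constant-velocity rupture protocol: each
#' Ig copy is a rigid body of Calpha beads, the flexible linkers are bead
#' chains with harmonic bonds (rest 3.0 Angstrom) hard-capped at the
#' per-residue trans contour (3.63 Angstrom), and the interface contacts are
#' breakable springs that fail once stretched beyond `break_extension`. The
#' two linker termini are pulled apart along the membrane normal by harmonic
#' restraints moving at constant velocity; integration is overdamped and,
#' with the default zero noise, fully deterministic (with noise > 0 it is
#' bit-reproducible for a fixed seed). Rupture is the first step at which
#' every interface contact has broken; the reported structure is taken
#' `report_offset` steps earlier (the 10-ps-before-rupture analog). Because
#' the linkers can never pass their contour and ride below it at rupture
#' tensions, the rupture-time membrane-normal distance stays below the
#' closed-form [max_extension_distance()].
#'
#' @param assembly A [build_dimer()] result.
#' @param params A [pull_params()].
#' @param seed RNG seed (only consumed when `noise > 0`, but always echoed).
#' @return A `pull_record`: `status` (`"ruptured"`/`"no-rupture"`),
#'   `rupture_step`, `rupture_distance_nm`, `reported_distance_nm`,
#'   `reported_coords`, `trajectory` (data frame step/distance/contacts),
#'   `params` echo.
#' @export
coarse_pull <- function(assembly, params = pull_params(), seed = 1L) {
  stopifnot(inherits(assembly, "trans_assembly"))
  ca_a <- assembly$atoms_a[assembly$atoms_a$elety == "CA", , drop = FALSE]
  ca_b <- assembly$atoms_b[assembly$atoms_b$elety == "CA", , drop = FALSE]
  n_dom <- nrow(ca_a)
  nl <- assembly$linker$residues
  step_len <- assembly$linker$contour_per_res

  # linker beads leave the anchors toward the membranes as a relaxed zigzag
  # (segment length = the 3.0 A relaxed bond rest; the 3.63 A trans contour
  # is a hard cap that straightening and stretching approach, never pass)
  rest_linker <- 3.0
  zig <- function(anchor, dir) {
    t(vapply(seq_len(nl), function(i) {
      anchor + c(0.54 * ((i %% 2) * 2 - 1), 0, dir * 2.8 * i)
    }, numeric(3)))
  }
  xyz <- rbind(
    as.matrix(ca_a[, c("x", "y", "z")]),
    as.matrix(ca_b[, c("x", "y", "z")]),
    zig(assembly$anchor_a, -1),
    zig(assembly$anchor_b, +1)
  )
  idx_a <- seq_len(n_dom)
  idx_b <- n_dom + seq_len(n_dom)
  idx_la <- 2 * n_dom + seq_len(nl)
  idx_lb <- 2 * n_dom + nl + seq_len(nl)
  term_a <- idx_la[nl]
  term_b <- idx_lb[nl]
  anchor_bead_a <- idx_a[ca_a$resno == assembly$anchor_resno]
  anchor_bead_b <- idx_b[ca_b$resno == assembly$anchor_resno]

  chain_springs <- function(order_idx, attach_from) {
    from <- c(attach_from, order_idx[-length(order_idx)])
    cbind(from, order_idx)
  }
  bonds <- rbind(
    chain_springs(idx_la, anchor_bead_a),
    chain_springs(idx_lb, anchor_bead_b)
  )
  iface <- cbind(
    idx_a[match(assembly$interface$resno_a, ca_a$resno)],
    idx_b[match(assembly$interface$resno_b, ca_b$resno)]
  )
  iface_rest <- assembly$interface$dist
  alive <- rep(TRUE, nrow(iface))

  k_bond <- 300
  gamma_body <- 3 # effective drag of one rigid Ig unit
  dt <- 0.001 # integration step over friction; k_bond * dt stays well inside
  # the overdamped-Euler stability bound for chain modes
  travel <- params$velocity * params$time_step * 10 # A per step per side
  k_pull <- params$spring_constant / 50 # rescaled to the bead-spring units
  normal <- assembly$normal

  spring_force <- function(pairs, rest, k, xyz) {
    dvec <- xyz[pairs[, 2], , drop = FALSE] - xyz[pairs[, 1], , drop = FALSE]
    d <- sqrt(rowSums(dvec^2))
    f <- k * (d - rest) / pmax(d, 1e-9)
    list(fvec = dvec * f, d = d)
  }

  # one-sided rope cap along each linker chain, walking out from the anchor:
  # a bond may shorten freely but never exceeds the contour
  cap_chain <- function(xyz, chain, cap) {
    for (k in seq_len(length(chain) - 1L)) {
      i <- chain[k]
      j <- chain[k + 1L]
      v <- xyz[j, ] - xyz[i, ]
      d <- sqrt(sum(v^2))
      if (d > cap) xyz[j, ] <- xyz[i, ] + v * (cap / d)
    }
    xyz
  }
  chain_a <- c(anchor_bead_a, idx_la)
  chain_b <- c(anchor_bead_b, idx_lb)

  pull_a0 <- xyz[term_a, ]
  pull_b0 <- xyz[term_b, ]
  dist_nm <- function(xyz) {
    (abs(sum((xyz[term_b, ] - xyz[term_a, ]) * normal)) +
      2 * assembly$anchor_offset) / 10
  }

  traj_step <- integer(0)
  traj_dist <- numeric(0)
  traj_contacts <- integer(0)
  snapshots <- list()
  snap_every <- max(1L, params$report_offset)
  rupture_step <- NA_integer_
  withr::with_seed(as.integer(seed), {
    for (step in seq_len(params$max_steps)) {
      force <- matrix(0, nrow(xyz), 3)
      sf <- spring_force(bonds, rest_linker, k_bond, xyz)
      force[bonds[, 1], ] <- force[bonds[, 1], ] + sf$fvec
      # linker chains have distinct beads per row except the anchor attach
      for (kk in seq_len(nrow(bonds))) {
        force[bonds[kk, 2], ] <- force[bonds[kk, 2], ] - sf$fvec[kk, ]
      }
      if (any(alive)) {
        sfi <- spring_force(
          iface[alive, , drop = FALSE], iface_rest[alive],
          params$k_interface, xyz
        )
        broke <- sfi$d > iface_rest[alive] + params$break_extension
        ia <- iface[alive, , drop = FALSE]
        for (kk in seq_len(nrow(ia))) {
          force[ia[kk, 1], ] <- force[ia[kk, 1], ] + sfi$fvec[kk, ]
          force[ia[kk, 2], ] <- force[ia[kk, 2], ] - sfi$fvec[kk, ]
        }
        alive[which(alive)[broke]] <- FALSE
      }
      # moving pull restraints on the linker termini, opposite directions
      pa <- pull_a0 - normal * travel * step
      pb <- pull_b0 + normal * travel * step
      force[term_a, ] <- force[term_a, ] + k_pull * (pa - xyz[term_a, ])
      force[term_b, ] <- force[term_b, ] + k_pull * (pb - xyz[term_b, ])
      # rigid-body translation of each Ig copy; free motion of linker beads
      shift_a <- dt * colSums(force[idx_a, , drop = FALSE]) / gamma_body
      shift_b <- dt * colSums(force[idx_b, , drop = FALSE]) / gamma_body
      xyz[idx_a, ] <- sweep(xyz[idx_a, , drop = FALSE], 2, shift_a, `+`)
      xyz[idx_b, ] <- sweep(xyz[idx_b, , drop = FALSE], 2, shift_b, `+`)
      lk <- c(idx_la, idx_lb)
      xyz[lk, ] <- xyz[lk, ] + dt * force[lk, ]
      if (params$noise > 0) {
        xyz[lk, ] <- xyz[lk, ] + matrix(
          rnorm(length(lk) * 3, sd = params$noise * sqrt(dt)),
          length(lk), 3
        )
      }
      xyz <- cap_chain(xyz, chain_a, step_len)
      xyz <- cap_chain(xyz, chain_b, step_len)
      if (step %% snap_every == 0L || !any(alive)) {
        traj_step <- c(traj_step, step)
        traj_dist <- c(traj_dist, dist_nm(xyz))
        traj_contacts <- c(traj_contacts, sum(alive))
        snapshots[[length(snapshots) + 1L]] <- xyz
      }
      if (!any(alive)) {
        rupture_step <- step
        break
      }
    }
  })

  trajectory <- data.frame(
    step = traj_step, distance_nm = traj_dist, contacts = traj_contacts
  )
  if (is.na(rupture_step)) {
    return(structure(
      list(
        status = "no-rupture", rupture_step = NA_integer_,
        rupture_distance_nm = NA_real_, reported_distance_nm = NA_real_,
        reported_coords = NULL, trajectory = trajectory,
        params = c(unclass(params), seed = as.integer(seed))
      ),
      class = "pull_record"
    ))
  }
  # reported structure: report_offset steps before rupture (nearest snapshot)
  target <- max(rupture_step - params$report_offset, min(traj_step))
  pick <- which.min(abs(traj_step - target))
  structure(
    list(
      status = "ruptured", rupture_step = rupture_step,
      rupture_distance_nm = traj_dist[length(traj_dist)],
      reported_distance_nm = traj_dist[pick],
      reported_coords = snapshots[[pick]],
      trajectory = trajectory,
      params = c(unclass(params), seed = as.integer(seed))
    ),
    class = "pull_record"
  )
}

#' @export
print.pull_record <- function(x, ...) {
  if (x$status == "ruptured") {
    cat(sprintf(
      "<pull_record> ruptured at step %d (%.2f nm); reported %.2f nm\n",
      x$rupture_step, x$rupture_distance_nm, x$reported_distance_nm
    ))
  } else {
    cat("<pull_record> no rupture within the step budget\n")
  }
  invisible(x)
}
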