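# Occupancy grids and occlusion scoring: converting a conformer ensemble
# into the 3D space the glycans occupy, and deciding whether annotated
# regions (interface footprints, pore, VSDs) are blocked, partially covered,
# or accessible.

#' Extract the interface footprint a partner chain leaves on an alpha chain
#'
#' @param struct A [channel_structure()] holding the complex.
#' @param alpha_chain Chain id of the alpha-subunit.
#' @param partner_chain Chain id of the partner (e.g. a beta-subunit).
#' @param cutoff Heavy-atom contact cutoff, Angstrom (default 5.0).
#' @param partner_label Free-text partner label carried in the result.
#' @return An `interface_footprint`: list with `residues` (alpha residue
#'   numbers with any heavy atom within `cutoff` of any partner heavy atom),
#'   `partner`, `cutoff`, `status` (`"ok"` or `"empty"`, with a warning when
#'   empty).
#' @export
extract_interface <- function(struct, alpha_chain, partner_chain, cutoff = 5.0,
                              partner_label = partner_chain) {
  stopifnot(inherits(struct, "channel_structure"))
  a <- struct$atoms
  if (!alpha_chain %in% a$chain) stop("chain '", alpha_chain, "' not found")
  if (!partner_chain %in% a$chain) stop("chain '", partner_chain, "' not found")
  aa <- a[a$chain == alpha_chain, , drop = FALSE]
  pp <- as.matrix(a[a$chain == partner_chain, c("x", "y", "z")])
  am <- as.matrix(aa[, c("x", "y", "z")])
  d2 <- outer(rowSums(am^2), rowSums(pp^2), `+`) - 2 * am %*% t(pp)
  near <- sqrt(pmax(d2, 0)) <= cutoff
  res <- sort(unique(aa$resno[rowSums(near) > 0L]))
  status <- "ok"
  if (length(res) == 0L) {
    warning("empty interface footprint between '", alpha_chain, "' and '",
      partner_chain, "' at ", cutoff, " A")
    status <- "empty"
  }
  structure(
    list(
      residues = res, alpha_chain = alpha_chain, partner = partner_label,
      cutoff = cutoff, status = status
    ),
    class = "interface_footprint"
  )
}

#' @export
print.interface_footprint <- function(x, ...) {
  cat(sprintf(
    "<interface_footprint> %s on chain %s: %d residues (cutoff %.1f A)\n",
    x$partner, x$alpha_chain, length(x$residues), x$cutoff
  ))
  invisible(x)
}

#' Voxelize a conformer ensemble into an occupancy grid
#'
#' Per voxel, the fraction of frames in which at least one glycan heavy atom
#' falls inside the voxel. Grid bounds enclose all frames.
#'
#' @param ensemble A [sample_ensemble()] result (non-empty).
#' @param voxel Voxel edge length, Angstrom (default 1.0).
#' @return An `occupancy_grid`: `origin`, `voxel`, `dim`, and `occupancy`
#'   (3D array of fractions in \[0, 1\]).
#' @export
build_grid <- function(ensemble, voxel = 1.0) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (voxel <= 0) stop("voxel size must be positive")
  if (length(ensemble$frames) == 0L) stop("ensemble has no frames")
  all_xyz <- do.call(rbind, ensemble$frames)
  origin <- floor(apply(all_xyz, 2, min) / voxel) * voxel
  dims <- pmax(1L, as.integer(floor((apply(all_xyz, 2, max) - origin) / voxel)) + 1L)
  occ <- array(0, dim = dims)
  nf <- length(ensemble$frames)
  for (fr in ensemble$frames) {
    ix <- floor(sweep(fr, 2, origin) / voxel) + 1L
    ix <- unique(ix)
    occ[ix] <- occ[ix] + 1
  }
  structure(
    list(origin = origin, voxel = voxel, dim = dims, occupancy = occ / nf,
         n_frames = nf),
    class = "occupancy_grid"
  )
}

#' @export
print.occupancy_grid <- function(x, ...) {
  cat(sprintf(
    "<occupancy_grid> %d x %d x %d voxels of %.1f A, %d frames, %d ever occupied\n",
    x$dim[1], x$dim[2], x$dim[3], x$voxel, x$n_frames, sum(x$occupancy > 0)
  ))
  invisible(x)
}

#' Write an occupancy grid in a simple text map layout
#'
#' Plain-text layout: a header (origin, voxel, dim, frames) followed by one
#' `i j k fraction` line per ever-occupied voxel. Readable by
#' [read_grid_map()].
#'
#' @param grid An [build_grid()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_grid_map <- function(grid, path) {
  stopifnot(inherits(grid, "occupancy_grid"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(sprintf("# glycoshield occupancy map"), con)
  writeLines(sprintf("origin %g %g %g", grid$origin[1], grid$origin[2], grid$origin[3]), con)
  writeLines(sprintf("voxel %g", grid$voxel), con)
  writeLines(sprintf("dim %d %d %d", grid$dim[1], grid$dim[2], grid$dim[3]), con)
  writeLines(sprintf("frames %d", grid$n_frames), con)
  idx <- which(grid$occupancy > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    writeLines(sprintf(
      "%d %d %d %.6f", idx[r, 1], idx[r, 2], idx[r, 3],
      grid$occupancy[idx[r, 1], idx[r, 2], idx[r, 3]]
    ), con)
  }
  invisible(path)
}

#' Read an occupancy grid text map
#' @param path Path written by [write_grid_map()].
#' @return An `occupancy_grid`.
#' @export
read_grid_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  kv <- strsplit(lines, " +")
  origin <- as.numeric(kv[[1]][-1])
  voxel <- as.numeric(kv[[2]][-1])
  dims <- as.integer(kv[[3]][-1])
  nf <- as.integer(kv[[4]][-1])
  occ <- array(0, dim = dims)
  for (row in kv[-(1:4)]) {
    occ[as.integer(row[1]), as.integer(row[2]), as.integer(row[3])] <-
      as.numeric(row[4])
  }
  structure(
    list(origin = origin, voxel = voxel, dim = dims, occupancy = occ,
         n_frames = nf),
    class = "occupancy_grid"
  )
}

#' Score glycan occlusion of a region over an ensemble
#'
#' Per region residue, the fraction of frames with any glycan heavy atom
#' within `contact_cutoff` of any of the residue's heavy atoms. The region's
#' coverage fraction is the share of residues contacted in at least
#' `frame_threshold` of frames; the verdict follows the configured coverage
#' thresholds (`blocked` at or above the upper, `accessible` at or below the
#' lower, else `partial`).
#'
#' @param ensemble A [sample_ensemble()] result (may have zero frames:
#'   coverage 0, verdict accessible).
#' @param struct The [channel_structure()] the region lives on.
#' @param chain Chain id of the region residues.
#' @param residues Integer vector of region residue numbers (non-empty).
#' @param contact_cutoff Glycan-to-residue heavy-atom cutoff (default 4.5).
#' @param frame_threshold Frame-fraction threshold for counting a residue as
#'   covered (default 0.5).
#' @param blocked_at,accessible_at Coverage thresholds for the verdict
#'   (defaults 0.8 / 0.2, boundary inclusive).
#' @param region Free-text region label.
#' @return An `occlusion_report` row (list): `region`, `coverage`,
#'   `mean_contact_fraction`, `verdict`, `per_residue` (named frequencies),
#'   parameter echo.
#' @export
occlusion_score <- function(ensemble, struct, chain, residues,
                            contact_cutoff = 4.5, frame_threshold = 0.5,
                            blocked_at = 0.8, accessible_at = 0.2,
                            region = "region") {
  stopifnot(length(residues) > 0L)
  frames <- if (is.null(ensemble)) list() else ensemble$frames
  res_xyz <- lapply(residues, function(rn) {
    m <- structure_coords(struct, chain = chain, resno = rn)
    if (nrow(m) == 0L) stop("region residue ", rn, " not found in chain ", chain)
    m
  })
  if (length(frames) == 0L) {
    freq <- setNames(rep(0, length(residues)), residues)
  } else {
    hits <- matrix(FALSE, nrow = length(frames), ncol = length(residues))
    for (f in seq_along(frames)) {
      g <- frames[[f]]
      for (r in seq_along(residues)) {
        m <- res_xyz[[r]]
        d2 <- outer(rowSums(m^2), rowSums(g^2), `+`) - 2 * m %*% t(g)
        hits[f, r] <- any(d2 <= contact_cutoff^2)
      }
    }
    freq <- setNames(colMeans(hits), residues)
  }
  coverage <- mean(freq >= frame_threshold)
  mean_contact <- mean(freq)
  verdict <- occlusion_verdict(coverage, blocked_at, accessible_at)
  structure(
    list(
      region = region, coverage = coverage,
      mean_contact_fraction = mean_contact, verdict = verdict,
      per_residue = freq,
      params = list(
        contact_cutoff = contact_cutoff, frame_threshold = frame_threshold,
        blocked_at = blocked_at, accessible_at = accessible_at,
        n_frames = length(frames)
      )
    ),
    class = "occlusion_report"
  )
}

occlusion_verdict <- function(coverage, blocked_at = 0.8, accessible_at = 0.2) {
  if (coverage >= blocked_at) {
    "blocked"
  } else if (coverage <= accessible_at) {
    "accessible"
  } else {
    "partial"
  }
}

#' @export
print.occlusion_report <- function(x, ...) {
  cat(sprintf(
    "<occlusion_report> %s: coverage %.2f, mean contact %.2f -> %s\n",
    x$region, x$coverage, x$mean_contact_fraction, x$verdict
  ))
  invisible(x)
}

#' Fraction of frames in which glycans enter the pore cylinder
#'
#' The pore is modeled as a cylinder of radius `radius` starting at the
#' extracellular mouth `point` and extending `length` along `direction`
#' (the membrane normal). A frame counts as blocked when any glycan heavy
#' atom lies inside the cylinder.
#'
#' @param ensemble A [sample_ensemble()] result.
#' @param point Numeric xyz of the pore mouth (selectivity-filter centroid
#'   projected to the extracellular opening).
#' @param direction Numeric xyz axis direction (need not be unit length).
#' @param radius Cylinder radius, Angstrom (default 6).
#' @param length Cylinder extent above the mouth, Angstrom (default 30).
#' @return Blocked fraction in \[0, 1\].
#' @export
pore_block_check <- function(ensemble, point, direction, radius = 6,
                             length = 30) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  if (vnorm(direction) < 1e-9) stop("degenerate pore axis")
  u <- unit(direction)
  blocked <- vapply(ensemble$frames, function(g) {
    rel <- sweep(g, 2, point)
    t_ax <- rel %*% u
    perp2 <- rowSums(rel^2) - t_ax^2
    any(t_ax >= 0 & t_ax <= length & perp2 <= radius^2)
  }, NA)
  mean(blocked)
}

#' Per-partner binding verdicts from occlusion reports
#'
#' @param reports Named list of [occlusion_score()] reports (e.g. for the
#'   beta1, beta2 and beta4 footprints), computed with matched parameters.
#' @return Data frame `partner`, `coverage`, `verdict`, with the thresholds
#'   echoed as attributes.
#' @export
binding_verdict <- function(reports) {
  stopifnot(length(reports) > 0L)
  out <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(
      partner = nm, coverage = r$coverage, verdict = r$verdict,
      stringsAsFactors = FALSE
    )
  }))
  attr(out, "thresholds") <- reports[[1L]]$params[c("blocked_at", "accessible_at")]
  out
}
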