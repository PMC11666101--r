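# Synthetic data generators: sequence families with planted sequons, a
# nine-isoform NaV stand-in family reproducing the printed site architecture,
# toy channels with loop-borne glycosites, toy alpha/beta complexes with
# constructed interfaces, toy Ig domains, and the packaged in-paper tables.
#
# Every generator is deterministic under a fixed seed and emits its ground
# truth alongside the data.

AA_BACKGROUND <- setdiff(AA_CANONICAL, character(0))

# ---------------------------------------------------------------------------
# generic sequence-family engine

# Apply insertion/deletion edits (list of c(at, n): n > 0 inserts n random
# residues after scaffold position `at`; n < 0 deletes positions
# at+1 .. at+|n|). Returns the edited character vector and the map from
# scaffold position to new position (NA where deleted).
apply_edits <- function(chars, edits) {
  n <- length(chars)
  del <- rep(FALSE, n)
  ins_after <- vector("list", n + 1L)
  for (e in edits) {
    at <- e[[1L]]
    k <- e[[2L]]
    if (k > 0) {
      ins_after[[at + 1L]] <- c(
        ins_after[[at + 1L]], sample(AA_BACKGROUND, k, replace = TRUE)
      )
    } else if (k < 0) {
      if (at - k > n) stop("deletion extends beyond the scaffold")
      del[(at + 1L):(at - k)] <- TRUE
    }
  }
  out <- character(0)
  map <- rep(NA_integer_, n)
  out <- c(out, ins_after[[1L]])
  for (i in seq_len(n)) {
    if (!del[i]) {
      out <- c(out, chars[i])
      map[i] <- length(out)
    }
    out <- c(out, ins_after[[i + 1L]])
  }
  list(chars = out, map = map)
}

# Offset arithmetic equivalent of apply_edits for a single scaffold column.
scaffold_to_member_pos <- function(col, edits) {
  pos <- col
  for (e in edits) {
    at <- e[[1L]]
    k <- e[[2L]]
    if (k > 0) {
      if (at < col) pos <- pos + k
    } else if (k < 0) {
      if (at - k < col) {
        pos <- pos + k
      } else if (at < col) {
        return(NA_integer_) # column itself deleted
      }
    }
  }
  pos
}

# Remove every sequon not in the allowed set (per-member positions) by
# mutating its asparagine to glutamine. One pass suffices: no new N appears.
destroy_unplanned_sequons <- function(chars, allowed_pos) {
  s <- paste(chars, collapse = "")
  hits <- scan_sequons(isoform_sequence("tmp", s))
  bad <- setdiff(hits$asn_position, allowed_pos)
  if (length(bad) > 0L) chars[bad] <- "Q"
  chars
}

#' Generate a sequence family with planted sequon columns
#'
#' Builds a random scaffold, applies optional per-member insertions and
#' deletions, applies per-member substitutions at `substitution_rate`
#' (planted motif windows are protected), stamps each planted column with its
#' motif in exactly the designated members (non-members receive the motif
#' with N replaced by Q, destroying the site while anchoring the alignment
#' column), and removes every accidental sequon. Ground truth is returned
#' alongside.
#'
#' @param member_ids Character vector of member names.
#' @param length Scaffold length (residues).
#' @param planted Data frame with `column` (scaffold position of the N),
#'   `members` (list-column or "+"-separated string of member ids; `"all"`
#'   for every member), `motif` (3-residue NX\[S/T\] string), and optionally
#'   `overrides` (list-column of named motif overrides per member).
#' @param substitution_rate Per-position substitution probability in
#'   \[0, 1\].
#' @param edits Optional named list (per member) of edit lists; each edit is
#'   `c(at, n)` (insertion of `n` after `at` when positive, deletion of
#'   `|n|` starting at `at + 1` when negative).
#' @param seed RNG seed.
#' @return List with `sequences` (named list of [isoform_sequence()]),
#'   `truth` (data frame: `member`, `column`, `asn_position`, `motif`,
#'   `class` among all/subset/unique), and `scaffold`.
#' @export
make_sequence_family <- function(member_ids, length, planted,
                                 substitution_rate = 0.05, edits = NULL,
                                 seed = 1L) {
  stopifnot(length(member_ids) >= 1L, length >= 10L,
            substitution_rate >= 0, substitution_rate <= 1)
  planted <- as.data.frame(planted)
  if (any(planted$column > length - 2L | planted$column < 1L)) {
    stop("planted column outside the scaffold")
  }
  members_of <- lapply(seq_len(nrow(planted)), function(i) {
    m <- planted$members[[i]]
    if (identical(m, "all")) {
      member_ids
    } else if (is.character(m) && length(m) == 1L && grepl("+", m, fixed = TRUE)) {
      strsplit(m, "+", fixed = TRUE)[[1L]]
    } else {
      m
    }
  })
  for (m in members_of) {
    if (!all(m %in% member_ids)) stop("planted member not in member_ids")
  }
  # feasibility: stamped windows must not collide within any one member
  for (id in member_ids) {
    cols <- planted$column[vapply(members_of, function(m) id %in% m, NA)]
    cols <- sort(cols)
    if (any(diff(cols) < 3L)) {
      stop("infeasible plant: overlapping sequon windows in member '", id, "'")
    }
  }
  withr::with_seed(as.integer(seed), {
    scaffold <- sample(AA_BACKGROUND, length, replace = TRUE)
    sequences <- list()
    truth <- list()
    for (id in member_ids) {
      ed <- if (!is.null(edits) && !is.null(edits[[id]])) edits[[id]] else list()
      res <- apply_edits(scaffold, ed)
      chars <- res$chars
      # per-member substitutions (motif windows protected below by stamping
      # after substitution)
      if (substitution_rate > 0) {
        flip <- which(runif(base::length(chars)) < substitution_rate)
        if (base::length(flip) > 0L) {
          chars[flip] <- sample(AA_BACKGROUND, base::length(flip), replace = TRUE)
        }
      }
      motif_for <- function(i) {
        motif <- planted$motif[i]
        if (!is.null(planted$overrides) &&
          !is.null(planted$overrides[[i]]) &&
          !is.null(planted$overrides[[i]][[id]])) {
          motif <- planted$overrides[[i]][[id]]
        }
        motif
      }
      # live motifs first; their windows are protected from dead stamps
      allowed <- integer(0)
      protected <- integer(0)
      for (i in seq_len(nrow(planted))) {
        col <- planted$column[i]
        pos <- res$map[col]
        if (!id %in% members_of[[i]]) next
        if (is.na(pos)) {
          stop("planted column ", col, " deleted in member '", id, "'")
        }
        motif <- motif_for(i)
        chars[pos:(pos + 2L)] <- strsplit(motif, "")[[1L]]
        allowed <- c(allowed, pos)
        protected <- c(protected, pos:(pos + 2L))
        truth[[base::length(truth) + 1L]] <- data.frame(
          member = id, column = col, asn_position = pos, motif = motif,
          n_members = base::length(members_of[[i]]),
          stringsAsFactors = FALSE
        )
      }
      # destroyed variants anchor non-member columns without a sequon
      for (i in seq_len(nrow(planted))) {
        col <- planted$column[i]
        pos <- res$map[col]
        if (id %in% members_of[[i]] || is.na(pos)) next
        dead <- strsplit(motif_for(i), "")[[1L]]
        dead[1L] <- "Q"
        for (k in 0:2) {
          if (!(pos + k) %in% protected) chars[pos + k] <- dead[k + 1L]
        }
      }
      chars <- destroy_unplanned_sequons(chars, allowed)
      sequences[[id]] <- isoform_sequence(id, paste(chars, collapse = ""))
    }
  })
  truth <- do.call(rbind, truth)
  n_all <- length(member_ids)
  truth$class <- ifelse(
    truth$n_members == n_all, "all",
    ifelse(truth$n_members == 1L, "unique", "subset")
  )
  list(
    sequences = sequences, truth = truth,
    scaffold = paste(scaffold, collapse = "")
  )
}

# ---------------------------------------------------------------------------
# the NaV nine-isoform stand-in family

#' Isoform roster used by the synthetic NaV family
#'
#' Labels, UniProt accessions and canonical lengths of the nine human NaV
#' channel alpha-subunit isoforms, plus the cryo-EM structure each resolved
#' site list refers to (none for NaV1.9).
#'
#' @return Data frame `isoform_id`, `accession`, `length`, `structure_id`.
#' @export
nav_isoforms <- function() {
  data.frame(
    isoform_id = paste0("NaV1.", 1:9),
    accession = c(
      "P35498", "Q99250", "Q9NY46", "P35499", "Q14524", "Q9UQD0",
      "Q15858", "Q9Y5Y9", "Q9UI33"
    ),
    length = c(2009L, 2005L, 2000L, 1836L, 2016L, 1980L, 1977L, 1956L, 1791L),
    structure_id = c(
      "7DTD", "6J8E", "7W7F", "6AGF", "6QLA", "8FHD", "7W9K", "7WFW",
      NA_character_
    ),
    stringsAsFactors = FALSE
  )
}

# Per-isoform edit lists (scaffold = NaV1.5 numbering, length 2016). Edits
# sit in inter-domain linkers, away from every planted column; the single
# deletions inside ECTL III reproduce the NaV1.1/NaV1.4 numbering of the
# conserved DIII sites.
nav_edits <- function() {
  list(
    "NaV1.1" = list(c(150, 47), c(480, -20), c(1000, -14), c(1372, -1), c(1900, -19)),
    "NaV1.2" = list(c(150, 10), c(480, -5), c(1900, -16)),
    "NaV1.3" = list(c(150, 5), c(480, -5), c(1900, -16)),
    "NaV1.4" = list(c(480, -100), c(1000, -74), c(1370, -1), c(1900, -5)),
    "NaV1.5" = list(),
    "NaV1.6" = list(c(150, 12), c(480, -10), c(1000, -9), c(1900, -29)),
    "NaV1.7" = list(c(150, -5), c(480, -10), c(1000, -15), c(1900, -9)),
    "NaV1.8" = list(c(150, -10), c(480, -10), c(1000, -30), c(1900, -10)),
    "NaV1.9" = list(c(150, -15), c(480, -50), c(1000, -55), c(1900, -105))
  )
}

nav_group <- function(...) paste0("NaV1.", c(...))

# Site plan in scaffold (NaV1.5) coordinates. Membership encodes the
# conservation architecture stated in the source analysis: three sites in all
# nine isoforms (N291/N1365/N1380 in NaV1.5 numbering), N328 in all but
# NaV1.7/1.9, N1374 shared by NaV1.5/1.7/1.8, four NaV1.5-unique sites
# (N283/N288/N318 on DI, N1388 on DIII), two NaV1.6-unique and one
# NaV1.7-unique DI sites, the NaV1.8-unique DII site (N819), and the block of
# ECTL I motifs giving NaV1.4 seven in that loop.
nav_site_plan <- function() {
  all9 <- nav_group(1:9)
  g14 <- nav_group(1:4)
  plan <- list(
    list(col = 283, members = "NaV1.5", motif = "NIT"),
    list(col = 285, members = "NaV1.6", motif = "NLT"),
    list(col = 288, members = "NaV1.5", motif = "NKT"),
    list(col = 291, members = all9, motif = "NGS"),
    list(col = 296, members = g14, motif = "NQS"),
    list(col = 301, members = g14, motif = "NMT"),
    list(col = 306, members = g14, motif = "NDS"),
    list(col = 308, members = "NaV1.7", motif = "NRT"),
    list(col = 311, members = g14, motif = "NFT"),
    list(col = 315, members = "NaV1.6", motif = "NWS"),
    list(col = 318, members = "NaV1.5", motif = "NAT"),
    list(col = 323, members = g14, motif = "NYS"),
    list(col = 328, members = nav_group(1:6, 8), motif = "NGT"),
    list(col = 839, members = "NaV1.8", motif = "NQT"),
    list(
      col = 1365, members = all9, motif = "NVS",
      overrides = list("NaV1.6" = "NDT")
    ),
    list(col = 1374, members = nav_group(5, 7, 8), motif = "NGT"),
    list(
      col = 1380, members = all9, motif = "NES",
      overrides = list("NaV1.1" = "NHT")
    ),
    list(col = 1388, members = "NaV1.5", motif = "NQT")
  )
  data.frame(
    column = vapply(plan, `[[`, 0, "col"),
    members = I(lapply(plan, `[[`, "members")),
    motif = vapply(plan, `[[`, "", "motif"),
    overrides = I(lapply(plan, function(p) p$overrides)),
    stringsAsFactors = FALSE
  )
}

# Scaffold columns whose glycan moiety is resolved in each isoform's cryo-EM
# structure (NaV1.9 has no structure). ECTL I is flexible, so its motif block
# is unresolved everywhere; NaV1.4's DI sites are likewise unresolved.
nav_resolved_columns <- function() {
  list(
    "NaV1.1" = c(291, 328, 1365, 1380),
    "NaV1.2" = c(291, 328, 1365, 1380),
    "NaV1.3" = c(291, 328, 1365, 1380),
    "NaV1.4" = c(1365, 1380),
    "NaV1.5" = c(283, 288, 291, 318, 328, 1365, 1374, 1380, 1388),
    "NaV1.6" = c(285, 291, 315, 328, 1365, 1380),
    "NaV1.7" = c(291, 308, 1365, 1374, 1380),
    "NaV1.8" = c(291, 328, 839, 1365, 1374, 1380),
    "NaV1.9" = integer(0)
  )
}

#' Resolved glycosite table for the synthetic NaV family
#'
#' The per-isoform asparagine positions carrying a resolved glycan moiety in
#' the corresponding cryo-EM structure, in each isoform's own numbering.
#' This is a synthetic reconstruction: positions named in the source text
#' (e.g. NaV1.5 N291/N1365/N1380, NaV1.8 N819) are authoritative; the
#' remaining cells follow the stated conservation architecture.
#'
#' @return Data frame `isoform_id`, `asn_position`, `column` (scaffold),
#'   `structure_id`.
#' @export
nav_resolved_sites <- function() {
  iso <- nav_isoforms()
  edits <- nav_edits()
  cols <- nav_resolved_columns()
  rows <- lapply(iso$isoform_id, function(id) {
    cc <- cols[[id]]
    if (length(cc) == 0L) {
      return(NULL)
    }
    pos <- vapply(cc, function(c0) {
      as.integer(scaffold_to_member_pos(c0, edits[[id]]))
    }, 0L)
    data.frame(
      isoform_id = id, asn_position = pos, column = cc,
      structure_id = iso$structure_id[iso$isoform_id == id],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Region annotations for the synthetic NaV family
#'
#' 1-based inclusive residue ranges for domains DI-DIV, the voltage-sensing
#' domains, the extracellular turret loops (ECTL I-IV) and the pore region,
#' per isoform, consistent with the synthetic family's numbering.
#'
#' @return Data frame `isoform_id`, `region`, `start`, `end`.
#' @export
nav_region_annotations <- function() {
  iso <- nav_isoforms()
  edits <- nav_edits()
  off_at <- function(id, col) {
    scaffold_to_member_pos(col, edits[[id]]) - col
  }
  rows <- lapply(iso$isoform_id, function(id) {
    o1 <- off_at(id, 200)
    o2 <- off_at(id, 700)
    o3 <- off_at(id, 1340)
    o4 <- off_at(id, 1480)
    reg <- data.frame(
      region = c(
        "DI", "VSD_I", "ECTL_I", "DII", "VSD_II", "ECTL_II",
        "DIII", "VSD_III", "ECTL_III", "DIV", "VSD_IV", "ECTL_IV", "pore"
      ),
      start = c(
        160 + o1, 160 + o1, 277 + o1, 650 + o2, 650 + o2, 800 + o2,
        1150 + o3, 1150 + o3, 1350 + o3, 1500 + o4, 1500 + o4, 1650 + o4,
        1355 + o3
      ),
      end = c(
        450 + o1, 270 + o1, 340 + o1, 950 + o2, 760 + o2, 860 + o2,
        1470 + o4, 1260 + o3, 1400 + o4, 1780 + o4, 1610 + o4, 1710 + o4,
        1372 + o3
      ),
      stringsAsFactors = FALSE
    )
    reg$isoform_id <- id
    reg
  })
  out <- do.call(rbind, rows)
  out[, c("isoform_id", "region", "start", "end")]
}

#' Synthetic nine-isoform NaV sequence family
#'
#' A deterministic stand-in for the nine UniProt NaV channel isoform
#' sequences (which this package does not download): full-length synthetic
#' sequences at the canonical isoform lengths, with the printed glycosite
#' architecture planted at the printed positions -- e.g. the three
#' all-isoform sites at NaV1.5 N291/N1365/N1380 (NaV1.1 N338/N1378/N1392),
#' the NaV1.5-unique N283/N288/N318/N1388, NaV1.8 N819, the seven ECTL I
#' motifs of NaV1.4, and the wild-type residues required by the packaged
#' clinical variant table (NaV1.1 S340/H1393/T1394, NaV1.5 T320/S1382,
#' NaV1.6 T1360).
#'
#' @param seed RNG seed for the scaffold and background substitutions.
#' @param substitution_rate Per-position background divergence between
#'   isoforms (default 0.06, giving roughly 90 percent pairwise identity).
#' @return List with `sequences` (named list of [isoform_sequence()] with
#'   accessions), `sites` (ground-truth planted sequon table with class),
#'   `resolved` ([nav_resolved_sites()]), `regions`
#'   ([nav_region_annotations()]).
#' @export
synthetic_nav_family <- function(seed = 101L, substitution_rate = 0.06) {
  iso <- nav_isoforms()
  fam <- make_sequence_family(
    member_ids = iso$isoform_id,
    length = 2016L,
    planted = nav_site_plan(),
    substitution_rate = substitution_rate,
    edits = nav_edits(),
    seed = seed
  )
  for (i in seq_len(nrow(iso))) {
    id <- iso$isoform_id[i]
    fam$sequences[[id]]$accession <- iso$accession[i]
    stopifnot(nchar(fam$sequences[[id]]$residues) == iso$length[i])
  }
  names(fam$truth)[names(fam$truth) == "member"] <- "isoform_id"
  list(
    sequences = fam$sequences,
    sites = fam$truth,
    resolved = nav_resolved_sites(),
    regions = nav_region_annotations()
  )
}

# ---------------------------------------------------------------------------
# packaged in-paper tables

#' Packaged study tables
#'
#' Returns the packaged fixture tables: the clinical variant list (per
#' isoform, with phenotypes), the plasma-membrane lipid composition per
#' leaflet, the resolved glycosite table, and the representative glycan
#' tree.
#'
#' @return List with `variants`, `membrane`, `resolved_sites`,
#'   `glycan_tree`.
#' @export
load_paper_tables <- function() {
  vpath <- system.file("extdata", "nav_variants.csv", package = "glycoshield")
  mpath <- system.file("extdata", "membrane_composition.csv",
    package = "glycoshield"
  )
  list(
    variants = read_variant_csv(vpath),
    membrane = read.csv(mpath, stringsAsFactors = FALSE),
    resolved_sites = nav_resolved_sites(),
    glycan_tree = default_glycan_tree()
  )
}

# ---------------------------------------------------------------------------
# toy structures

helix_ca <- function(n, origin, direction = c(0, 0, 1), phase = 0,
                     radius = 2.3, rise = 1.5, twist = 100) {
  u <- unit(direction)
  # orthonormal frame around the helix axis
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- unit(cross3(u, ref))
  e2 <- cross3(u, e1)
  t(vapply(seq_len(n) - 1L, function(i) {
    a <- (phase + i * twist) * pi / 180
    origin + u * (i * rise) + radius * (cos(a) * e1 + sin(a) * e2)
  }, numeric(3)))
}

arc_points <- function(p, q, n, bulge) {
  # n points along the p->q chord, bowed outward radially and upward in z
  t(vapply(seq_len(n), function(i) {
    t_i <- i / (n + 1)
    base <- p + t_i * (q - p)
    mid_lift <- sin(pi * t_i) * bulge
    out <- base + c(0, 0, mid_lift)
    radial <- c(base[1], base[2], 0)
    if (vnorm(radial) > 1e-6) out <- out + unit(radial) * (0.3 * mid_lift)
    out
  }, numeric(3)))
}

asn_side_chain <- function(ca, direction) {
  d <- unit(direction)
  cb <- ca + 1.53 * d
  side <- unit(cross3(d, if (abs(d[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)))
  cg <- cb + 1.52 * unit(d + 0.35 * side)
  od1 <- cg + 1.23 * unit(side + 0.3 * d)
  nd2 <- cg + 1.33 * unit(d - 0.35 * side)
  list(CB = cb, CG = cg, OD1 = od1, ND2 = nd2)
}

#' Idealized toy channel with loop-borne glycosites
#'
#' A four-helix transmembrane bundle around a central pore axis (the z axis),
#' spanning a membrane slab, with extracellular loops connecting the helix
#' tops. Each requested glycosite places an Asn (full side chain) at a loop
#' apex with Thr at N+2, so the emitted sequence carries NAT sequons exactly
#' at the planted positions. Optionally an extra "plug" sequon is placed
#' directly over the pore mouth, whose grafted glycan necessarily threads the
#' pore cylinder.
#'
#' @param n_helices Helices in the bundle (default 4).
#' @param bundle_radius Distance of helix axes from the pore axis, Angstrom.
#' @param helix_len Residues per helix.
#' @param loop_len Residues per extracellular loop.
#' @param sites_per_loop Glycosites planted on each extracellular loop.
#' @param pore_site Also plant the pore-plug site?
#' @param membrane A [membrane_slab()] (default z -15..15).
#' @return A [channel_structure()] (chain "A") with attributes:
#'   `glycosites` (Asn residue numbers), `sequence` (emitted one-letter
#'   sequence), `regions` (toy annotation), `pore_point`, `pore_axis`,
#'   `pore_mouth_z`.
#' @export
make_toy_channel <- function(n_helices = 4L, bundle_radius = 11,
                             helix_len = 28L, loop_len = 9L,
                             sites_per_loop = 1L, pore_site = FALSE,
                             membrane = NULL) {
  if (n_helices < 2L) stop("need at least 2 helices")
  if (is.null(membrane)) {
    membrane <- membrane_slab(
      z_inner = -15, z_outer = 15,
      composition = utils::read.csv(
        system.file("extdata", "membrane_composition.csv", package = "glycoshield"),
        stringsAsFactors = FALSE
      )
    )
  }
  z_bot <- -((helix_len - 1) * 1.5) / 2
  z_top <- -z_bot
  angles <- (seq_len(n_helices) - 1L) * 360 / n_helices
  bases <- lapply(angles, function(a) {
    bundle_radius * c(cos(a * pi / 180), sin(a * pi / 180), 0)
  })
  # minimum separation guard for the requested geometry
  sep <- vnorm(bases[[1]] - bases[[2]])
  if (sep < 2 * 2.3 + 3) stop("helices overlap at the requested geometry")

  atoms <- list()
  seq_chars <- character(0)
  glycosites <- integer(0)
  resno <- 0L
  regions <- list()
  add_atom <- function(resid, elety, xyz) {
    atoms[[length(atoms) + 1L]] <<- data.frame(
      chain = "A", resno = resno, resid = resid, elety = elety,
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE
    )
  }
  add_ca_residue <- function(code3, code1, xyz) {
    resno <<- resno + 1L
    seq_chars <<- c(seq_chars, code1)
    add_atom(code3, "CA", xyz)
  }

  for (h in seq_len(n_helices)) {
    up <- h %% 2L == 1L
    dir <- if (up) c(0, 0, 1) else c(0, 0, -1)
    origin <- bases[[h]] + c(0, 0, if (up) z_bot else z_top)
    ca <- helix_ca(helix_len, origin, dir)
    h_start <- resno + 1L
    for (i in seq_len(helix_len)) add_ca_residue("ALA", "A", ca[i, ])
    regions[[length(regions) + 1L]] <- data.frame(
      region = paste0("helix_", h), start = h_start, end = resno
    )
    # loops connect helix ends; extracellular (top) loops carry glycosites
    if (h < n_helices) {
      p <- ca[helix_len, ]
      q_origin <- bases[[h + 1L]] + c(0, 0, if (up) z_top else z_bot)
      lp <- arc_points(p, q_origin, loop_len, bulge = if (up) 7 else -7)
      l_start <- resno + 1L
      site_slots <- if (up && sites_per_loop > 0L) {
        pick <- round(seq(2L, loop_len - 2L, length.out = sites_per_loop))
        unique(as.integer(pick))
      } else {
        integer(0)
      }
      i <- 1L
      while (i <= loop_len) {
        if (i %in% site_slots && i + 2L <= loop_len) {
          # Asn with full side chain pointing up/outward, then X=Ala, Thr
          add_ca_residue("ASN", "N", lp[i, ])
          sc <- asn_side_chain(lp[i, ], 0.3 * unit(c(lp[i, 1], lp[i, 2], 0)) + c(0, 0, 1))
          for (nm in names(sc)) add_atom("ASN", nm, sc[[nm]])
          glycosites <- c(glycosites, resno)
          add_ca_residue("ALA", "A", lp[i + 1L, ])
          add_ca_residue("THR", "T", lp[i + 2L, ])
          i <- i + 3L
        } else {
          add_ca_residue("GLY", "G", lp[i, ])
          i <- i + 1L
        }
      }
      regions[[length(regions) + 1L]] <- data.frame(
        region = paste0(if (up) "ECTL_" else "ICL_", h),
        start = l_start, end = resno
      )
    }
  }
  if (pore_site) {
    plug <- rbind(
      c(5.5, 0, z_top + 4), c(3.8, 1.5, z_top + 6), c(2.4, 0, z_top + 8)
    )
    add_ca_residue("ASN", "N", plug[1, ])
    sc <- asn_side_chain(plug[1, ], unit(c(-0.8, 0, 0.6)))
    for (nm in names(sc)) add_atom("ASN", nm, sc[[nm]])
    glycosites <- c(glycosites, resno)
    add_ca_residue("ALA", "A", plug[2, ])
    add_ca_residue("THR", "T", plug[3, ])
    regions[[length(regions) + 1L]] <- data.frame(
      region = "pore_plug", start = resno - 2L, end = resno
    )
  }
  atoms <- do.call(rbind, atoms)
  struct <- channel_structure(
    atoms,
    sequence = c(A = paste(seq_chars, collapse = "")),
    membrane = membrane
  )
  regions <- do.call(rbind, regions)
  regions$isoform_id <- "toy"
  attr(struct, "glycosites") <- glycosites
  attr(struct, "sequence") <- paste(seq_chars, collapse = "")
  attr(struct, "regions") <- regions[, c("isoform_id", "region", "start", "end")]
  attr(struct, "pore_point") <- c(0, 0, z_top + 2)
  attr(struct, "pore_axis") <- c(0, 0, 1)
  attr(struct, "pore_mouth_z") <- z_top + 2
  struct
}

#' Toy alpha/partner complex with a constructed interface
#'
#' The alpha chain is a straight Calpha peptide along x; the partner chain is
#' placed 4 Angstrom away in y over a designated residue window, so the
#' ground-truth interface footprint at a 5 Angstrom cutoff is exactly that
#' window.
#'
#' @param n_alpha Alpha-chain residues.
#' @param footprint_start,footprint_len Designated contact window.
#' @param displacement Extra y displacement of the partner (e.g. 100 to
#'   construct a non-interacting pair).
#' @return A [channel_structure()] with chains "A" (alpha) and "B"
#'   (partner); attribute `footprint` holds the designated residue numbers.
#' @export
make_toy_complex <- function(n_alpha = 40L, footprint_start = 15L,
                             footprint_len = 12L, displacement = 0) {
  if (footprint_start + footprint_len - 1L > n_alpha) {
    stop("footprint placement infeasible")
  }
  fp <- footprint_start:(footprint_start + footprint_len - 1L)
  alpha <- data.frame(
    chain = "A", resno = seq_len(n_alpha), resid = "ALA", elety = "CA",
    x = (seq_len(n_alpha) - 1L) * 3.8, y = 0, z = 0, stringsAsFactors = FALSE
  )
  partner <- data.frame(
    chain = "B", resno = seq_len(footprint_len), resid = "ALA", elety = "CA",
    x = (fp - 1L) * 3.8, y = 4.0 + displacement, z = 0,
    stringsAsFactors = FALSE
  )
  struct <- channel_structure(rbind(alpha, partner))
  attr(struct, "footprint") <- fp
  struct
}

#' Idealized toy Ig domain (Calpha beta-sandwich)
#'
#' Two four-stranded sheets (strand rise 3.4 Angstrom per residue, strands
#' along z, sheets 9.5 Angstrom apart), connected by short turns; the chain
#' ends at the bottom of the last strand, which is the linker anchor (the
#' domain-boundary analog of the beta1 C-terminal boundary upstream of the
#' pulled terminal residue). Realistic Ig dimensions: roughly 40 x 15 x 10
#' Angstrom.
#'
#' @param strand_len Residues per strand (default 11).
#' @param first_resno Numbering of the first residue (default 20).
#' @return A [channel_structure()] (chain "A") with attribute
#'   `anchor_resno`.
#' @export
make_toy_ig <- function(strand_len = 11L, first_resno = 20L) {
  sheets_x <- c(0, 9.5)
  strand_y <- c(0, 4.8, 9.6, 14.4)
  rise <- 3.4
  z_top <- (strand_len - 1L) * rise
  atoms <- list()
  resno <- first_resno - 1L
  add <- function(xyz) {
    resno <<- resno + 1L
    atoms[[length(atoms) + 1L]] <<- data.frame(
      chain = "A", resno = resno, resid = "ALA", elety = "CA",
      x = xyz[1], y = xyz[2], z = xyz[3], stringsAsFactors = FALSE
    )
  }
  last_end <- NULL
  strand_no <- 0L
  for (sx in sheets_x) {
    for (sy in strand_y) {
      strand_no <- strand_no + 1L
      up <- strand_no %% 2L == 1L
      zs <- if (up) seq(0, z_top, by = rise) else seq(z_top, 0, by = -rise)
      start <- c(sx, sy, zs[1])
      if (!is.null(last_end)) {
        # 3-residue turn bulging beyond the strand ends
        bulge_z <- if (last_end[3] > z_top / 2) 3.5 else -3.5
        for (t_i in 1:3) {
          frac <- t_i / 4
          p <- last_end + frac * (start - last_end)
          p[3] <- p[3] + sin(pi * frac) * bulge_z
          add(p)
        }
      }
      for (z in zs) add(c(sx, sy, z))
      last_end <- c(sx, sy, zs[length(zs)])
    }
  }
  struct <- channel_structure(do.call(rbind, atoms))
  attr(struct, "anchor_resno") <- resno # bottom of the final strand
  struct
}
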