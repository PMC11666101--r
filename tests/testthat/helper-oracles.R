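# Independent oracles and shared fixtures for the test suite.

# Regex-based sliding-window sequon oracle (independent of scan_sequons'
# character-vector implementation). X never satisfies any motif position.
oracle_scan <- function(residues) {
  m <- gregexpr("N(?=[^PX][ST])", residues, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# Brute-force O(n^2) soft-repulsion pair sum between two atom sets.
oracle_pair_energy <- function(a, b, cutoff) {
  e <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((a[i, ] - b[j, ])^2))
      if (d < cutoff) e <- e + (cutoff - d)^2
    }
  }
  e
}

# Brute-force minimum cross distance between two atom sets.
oracle_min_dist <- function(a, b) {
  mn <- Inf
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      mn <- min(mn, sqrt(sum((a[i, ] - b[j, ])^2)))
    }
  }
  mn
}

# Direct frame-counting occupancy oracle.
oracle_grid <- function(frames, origin, voxel, dims) {
  occ <- array(0, dim = dims)
  for (fr in frames) {
    ix <- unique(floor(sweep(fr, 2, origin) / voxel) + 1L)
    occ[ix] <- occ[ix] + 1
  }
  occ / length(frames)
}

# Mutate-and-rescan variant oracle: full-sequence sequon diff.
oracle_variant_class <- function(residues, pos, mutant) {
  mut <- residues
  substr(mut, pos, pos) <- mutant
  wt <- oracle_scan(residues)
  mu <- oracle_scan(mut)
  lost <- setdiff(wt, mu)
  gained <- setdiff(mu, wt)
  if (length(lost) > 0L) {
    "disrupting"
  } else if (length(gained) > 0L) {
    "creating"
  } else {
    "silent"
  }
}

# A hand-made single-row "alignment" for degenerate cases.
manual_alignment <- function(seqs) {
  aligned <- vapply(seqs, `[[`, "", "residues")
  names(aligned) <- vapply(seqs, `[[`, "", "isoform_id")
  structure(
    list(
      aligned = aligned, ids = names(aligned),
      col_map = lapply(aligned, function(s) seq_len(nchar(s)))
    ),
    class = "isoform_alignment"
  )
}

# Fake minimal ensemble from a list of coordinate matrices.
fake_ensemble <- function(frames) {
  structure(
    list(frames = frames, params = list(), status = "ok", sites = list()),
    class = "conformer_ensemble"
  )
}

# Session-level cache for the expensive shared fixtures (synthetic family +
# alignment + conservation map), computed once for the whole test run.
.fixture_cache <- new.env(parent = emptyenv())

cached_family <- function() {
  if (is.null(.fixture_cache$family)) {
    .fixture_cache$family <- synthetic_nav_family()
  }
  .fixture_cache$family
}

cached_alignment <- function() {
  if (is.null(.fixture_cache$aln)) {
    .fixture_cache$aln <- align_isoforms(cached_family()$sequences)
  }
  .fixture_cache$aln
}

cached_conservation <- function() {
  if (is.null(.fixture_cache$cmap)) {
    fam <- cached_family()
    sequons <- do.call(rbind, lapply(fam$sequences, scan_sequons))
    .fixture_cache$cmap <- map_conserved_sequons(
      cached_alignment(), sequons,
      resolved = fam$resolved, resolved_only = TRUE
    )
  }
  .fixture_cache$cmap
}

cached_toy_ensemble <- function() {
  if (is.null(.fixture_cache$ens)) {
    toy <- make_toy_channel()
    tree <- default_glycan_tree()
    sp <- sampler_params(seed = 7)
    grafts <- lapply(
      attr(toy, "glycosites"),
      function(rn) graft_glycan(toy, "A", rn, tree, params = sp)
    )
    .fixture_cache$toy <- toy
    .fixture_cache$grafts <- grafts
    .fixture_cache$ens <- sample_ensemble(toy, grafts, params = sp)
  }
  list(
    toy = .fixture_cache$toy, grafts = .fixture_cache$grafts,
    ens = .fixture_cache$ens
  )
}
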