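# Lightweight structure container plus PDB/mmCIF I/O via bio3d.
#
# A channel_structure holds one atom table (chain, resno, resid, elety,
# x, y, z) in Angstrom, an optional per-chain sequence mapping (1-based
# isoform numbering), and an optional membrane slab reference.

#' Construct a structure from an atom table
#'
#' @param atoms Data frame with columns `chain`, `resno`, `resid` (3-letter
#'   residue name), `elety` (atom name), `x`, `y`, `z`.
#' @param sequence Optional named character vector: per-chain one-letter
#'   sequence in structure numbering.
#' @param membrane Optional [membrane_slab()].
#' @return A `channel_structure` object.
#' @export
channel_structure <- function(atoms, sequence = NULL, membrane = NULL) {
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z")
  stopifnot(all(need %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates")
  }
  structure(
    list(atoms = atoms, sequence = sequence, membrane = membrane),
    class = "channel_structure"
  )
}

#' @export
print.channel_structure <- function(x, ...) {
  cat(sprintf(
    "<channel_structure> %d atoms, %d chains (%s)\n",
    nrow(x$atoms), length(unique(x$atoms$chain)),
    paste(unique(x$atoms$chain), collapse = ", ")
  ))
  invisible(x)
}

#' Read a structure from PDB or mmCIF
#'
#' @param path File path (`.pdb` or `.cif`).
#' @return A [channel_structure()].
#' @export
read_structure <- function(path) {
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    bio3d::read.cif(path)
  } else {
    bio3d::read.pdb(path)
  }
  at <- pdb$atom
  channel_structure(data.frame(
    chain = at$chain, resno = at$resno, resid = at$resid, elety = at$elety,
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE
  ))
}

#' Write a structure as PDB
#'
#' @param struct A [channel_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(struct, path) {
  stopifnot(inherits(struct, "channel_structure"))
  a <- struct$atoms
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
    elety = a$elety, chain = a$chain
  )
  invisible(path)
}

#' Coordinate matrix of (a subset of) a structure
#'
#' @param struct A [channel_structure()].
#' @param chain Optional chain filter.
#' @param resno Optional residue-number filter.
#' @return Numeric matrix (n x 3).
#' @export
structure_coords <- function(struct, chain = NULL, resno = NULL) {
  a <- struct$atoms
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (!is.null(resno)) a <- a[a$resno %in% resno, , drop = FALSE]
  as.matrix(a[, c("x", "y", "z")])
}

# Atom coordinates of one residue as a named list of xyz vectors.
residue_atoms <- function(struct, chain, resno) {
  a <- struct$atoms[
    struct$atoms$chain == chain & struct$atoms$resno == resno, ,
    drop = FALSE
  ]
  if (nrow(a) == 0L) {
    stop("residue ", resno, " not found in chain ", chain)
  }
  setNames(
    lapply(seq_len(nrow(a)), function(i) as.numeric(a[i, c("x", "y", "z")])),
    a$elety
  )
}

#' Write a conformer ensemble as multi-model PDB
#'
#' One MODEL block per frame; glycan residues are written as HETATM with the
#' sugar name truncated to three characters. A JSON sidecar with the sampler
#' metadata is written next to it.
#'
#' @param ensemble A [sample_ensemble()] result.
#' @param path Output `.pdb` path.
#' @param write_meta Write `<path>.json` metadata sidecar?
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path, write_meta = TRUE) {
  stopifnot(inherits(ensemble, "conformer_ensemble"))
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  for (f in seq_along(ensemble$frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    fr <- ensemble$frames[[f]]
    lab <- attr(fr, "atom_info")
    for (i in seq_len(nrow(fr))) {
      writeLines(sprintf(
        "HETATM%5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        i, substr(lab$atom[i], 1, 4), toupper(substr(lab$sugar[i], 1, 3)),
        "G", lab$residue_index[i], fr[i, 1], fr[i, 2], fr[i, 3]
      ), con)
    }
    writeLines("ENDMDL", con)
  }
  if (write_meta) {
    jsonlite::write_json(
      ensemble$params,
      paste0(path, ".json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(path)
}
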