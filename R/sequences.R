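# Isoform sequences and sequon (NX[S/T], X != P) discovery.
#
# Positions are 1-based throughout, matching UniProt-style numbering.

AA_CANONICAL <- c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
)

#' Construct an isoform sequence record
#'
#' @param isoform_id Short label, e.g. `"NaV1.5"`.
#' @param residues Amino-acid string (one-letter codes; `X` allowed for
#'   unknown residues and never satisfies any motif position).
#' @param accession Free-text accession (optional).
#' @return An `isoform_sequence` object (list with `isoform_id`,
#'   `accession`, `residues`).
#' @examples
#' s <- isoform_sequence("toy", "MANGTAA")
#' scan_sequons(s)
#' @export
isoform_sequence <- function(isoform_id, residues, accession = NA_character_) {
  stopifnot(is.character(isoform_id), length(isoform_id) == 1L)
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) {
    stop("sequence for '", isoform_id, "' is empty")
  }
  chars <- strsplit(residues, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c(AA_CANONICAL, "X"))
  if (length(bad) > 0L) {
    stop(
      "sequence for '", isoform_id, "' contains non-amino-acid characters: ",
      paste(bad, collapse = ", ")
    )
  }
  structure(
    list(isoform_id = isoform_id, accession = accession, residues = residues),
    class = "isoform_sequence"
  )
}

#' @export
print.isoform_sequence <- function(x, ...) {
  cat(
    sprintf(
      "<isoform_sequence> %s (%s), %d residues\n",
      x$isoform_id, ifelse(is.na(x$accession), "no accession", x$accession),
      nchar(x$residues)
    )
  )
  invisible(x)
}

as_isoform_sequence <- function(x, isoform_id = NULL) {
  if (inherits(x, "isoform_sequence")) {
    return(x)
  }
  if (is.character(x) && length(x) == 1L) {
    if (is.null(isoform_id)) isoform_id <- "seq"
    return(isoform_sequence(isoform_id, x))
  }
  stop("cannot interpret input as an isoform sequence")
}

#' Read isoform sequences from a FASTA file
#'
#' Description lines are parsed as `isoform_id|accession`; anything after the
#' first whitespace is dropped, and a missing `|accession` part yields `NA`.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @return A list of [isoform_sequence()] objects, named by isoform id.
#' @export
read_isoform_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no sequences in ", path)
  heads <- sub("\\s.*$", "", names(aa))
  parts <- strsplit(heads, "|", fixed = TRUE)
  out <- lapply(seq_along(aa), function(i) {
    id <- parts[[i]][1L]
    acc <- if (length(parts[[i]]) >= 2L) parts[[i]][2L] else NA_character_
    isoform_sequence(id, as.character(aa[[i]]), acc)
  })
  names(out) <- vapply(out, `[[`, "", "isoform_id")
  out
}

#' Write isoform sequences to FASTA
#'
#' @param seqs List of [isoform_sequence()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isoform_fasta <- function(seqs, path) {
  seqs <- lapply(seqs, as_isoform_sequence)
  aa <- Biostrings::AAStringSet(vapply(seqs, `[[`, "", "residues"))
  names(aa) <- vapply(seqs, function(s) {
    if (is.na(s$accession)) s$isoform_id else paste0(s$isoform_id, "|", s$accession)
  }, "")
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Scan a sequence for N-glycosylation sequons
#'
#' Finds every occurrence of the canonical N-linked glycosylation motif
#' NX\[S/T\], where X is any amino acid except proline. Overlapping motifs
#' are each reported. An `X` (unknown) residue never satisfies any motif
#' position.
#'
#' @param seq An [isoform_sequence()] or a plain character string.
#' @param isoform_id Optional id when `seq` is a plain string.
#' @return A data frame with columns `isoform_id`, `asn_position` (1-based
#'   position of the N), `motif` (the 3-residue window), sorted by
#'   `asn_position`. Zero rows when no motif is present.
#' @examples
#' scan_sequons("ANGTA")  # one sequon at position 2
#' scan_sequons("ANPTA")  # none: proline at X
#' @export
scan_sequons <- function(seq, isoform_id = NULL) {
  seq <- as_isoform_sequence(seq, isoform_id)
  ch <- strsplit(seq$residues, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  if (n < 3L) {
    return(empty_sequon_table())
  }
  idx <- seq_len(n - 2L)
  hit <- ch[idx] == "N" &
    ch[idx + 1L] != "P" & ch[idx + 1L] != "X" &
    (ch[idx + 2L] == "S" | ch[idx + 2L] == "T")
  pos <- idx[hit]
  data.frame(
    isoform_id = rep(seq$isoform_id, length(pos)),
    asn_position = pos,
    motif = vapply(pos, function(p) paste(ch[p:(p + 2L)], collapse = ""), ""),
    stringsAsFactors = FALSE
  )
}

empty_sequon_table <- function() {
  data.frame(
    isoform_id = character(0), asn_position = integer(0), motif = character(0),
    stringsAsFactors = FALSE
  )
}

#' Count sequons within a named region of an isoform
#'
#' @param seq An [isoform_sequence()].
#' @param annotation Region annotation data frame with columns `isoform_id`,
#'   `region`, `start`, `end` (1-based inclusive), e.g. from
#'   [nav_region_annotations()].
#' @param region Region name, e.g. `"ECTL_I"`.
#' @return Integer count of sequon N positions inside the region range.
#' @export
count_region_sequons <- function(seq, annotation, region) {
  seq <- as_isoform_sequence(seq)
  row <- annotation[
    annotation$isoform_id == seq$isoform_id & annotation$region == region, ,
    drop = FALSE
  ]
  if (nrow(row) == 0L) {
    stop(
      "region '", region, "' not annotated for isoform '", seq$isoform_id, "'"
    )
  }
  if (nrow(row) > 1L) stop("duplicated region annotation for '", region, "'")
  if (row$end > nchar(seq$residues)) {
    stop("region '", region, "' extends beyond the sequence")
  }
  if (row$end < row$start) {
    return(0L)
  }
  sq <- scan_sequons(seq)
  sum(sq$asn_position >= row$start & sq$asn_position <= row$end)
}
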