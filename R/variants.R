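# Missense variants and their effect on N-glycosylation sequons.
#
# A substitution removes a glycosylation site when it hits the glycosylated
# asparagine itself (N-loss), the serine/threonine at N+2 (ST-loss), or puts
# a proline at the N+1 position (X-to-proline). It can also create a new
# sequon. Classification re-scans the +/-2 window around the substitution and
# diffs wild-type vs mutant sequon starts.

#' Parse a protein HGVS-style substitution string
#'
#' Accepts `"S340F"` style missense strings plus `"N1392fs"` (frameshift) and
#' `"W100*"`/`"W100X"` (nonsense) forms, which are classed structural.
#'
#' @param hgvs_p Character vector like `"S340F"`.
#' @return Data frame with `wild`, `position`, `mutant`, `type`
#'   (`"missense"`, `"frameshift"`, `"nonsense"`).
#' @export
parse_hgvs_p <- function(hgvs_p) {
  m <- regmatches(
    hgvs_p,
    regexec("^([A-Z])([0-9]+)(fs|\\*|X|[A-Z])$", hgvs_p)
  )
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad)) {
    stop("cannot parse variant string(s): ", paste(hgvs_p[bad], collapse = ", "))
  }
  wild <- vapply(m, `[`, "", 2L)
  pos <- as.integer(vapply(m, `[`, "", 3L))
  tail <- vapply(m, `[`, "", 4L)
  type <- ifelse(tail == "fs", "frameshift",
    ifelse(tail %in% c("*", "X"), "nonsense", "missense")
  )
  data.frame(
    wild = wild, position = pos,
    mutant = ifelse(type == "missense", tail, NA_character_),
    type = type, stringsAsFactors = FALSE
  )
}

#' Classify a variant's effect on N-glycosylation sequons
#'
#' Applies the substitution, re-scans the window of positions whose sequon
#' could be touched (N at `position - 2` through `position`), and compares
#' wild-type vs mutant sequon starts. A variant is `disrupting` when a
#' wild-type sequon's N start vanishes, `creating` when a new start appears,
#' and `silent` otherwise. A variant can disrupt one sequon and create
#' another; both facts are reported and `disrupting` takes precedence in the
#' summary class. Frameshift and nonsense variants are classed
#' `"structural"` with no sequon call.
#'
#' @param seq An [isoform_sequence()].
#' @param wild Wild-type residue (one letter); must match the sequence.
#' @param position 1-based position of the substitution.
#' @param mutant Mutant residue (one letter), or `NA` for
#'   frameshift/nonsense handled via `type`.
#' @param type `"missense"` (default), `"frameshift"`, or `"nonsense"`.
#' @return A `variant_effect` list: `class` (`disrupting`/`creating`/
#'   `silent`/`structural`), `affected_sequon` (N position or `NA`),
#'   `mechanism` (`N-loss`, `ST-loss`, `X-to-proline`, `new-motif`, `none`),
#'   `created_sequon` (N position of a created motif or `NA`).
#' @examples
#' s <- isoform_sequence("toy", "AANGSAA")
#' classify_variant(s, "S", 5, "F") # ST-loss at sequon N3
#' @export
classify_variant <- function(seq, wild, position, mutant,
                             type = c("missense", "frameshift", "nonsense")) {
  seq <- as_isoform_sequence(seq)
  type <- match.arg(type)
  n <- nchar(seq$residues)
  if (position < 1L || position > n) {
    stop("position ", position, " outside sequence (length ", n, ")")
  }
  at <- substr(seq$residues, position, position)
  if (!identical(at, wild)) {
    stop(
      "wild-residue mismatch for ", seq$isoform_id, " position ", position,
      ": sequence has '", at, "', variant says '", wild, "'"
    )
  }
  if (type != "missense") {
    return(variant_effect("structural", NA_integer_, "none", NA_integer_))
  }
  if (!mutant %in% AA_CANONICAL) stop("mutant residue must be a canonical code")
  if (identical(mutant, wild)) stop("wild and mutant residues are identical")

  lo <- max(1L, position - 2L)
  hi <- min(n - 2L, position)
  if (hi < lo) {
    return(variant_effect("silent", NA_integer_, "none", NA_integer_))
  }
  mut_res <- seq$residues
  substr(mut_res, position, position) <- mutant
  wt_start <- vapply(lo:hi, function(p) is_sequon_at(seq$residues, p), NA)
  mu_start <- vapply(lo:hi, function(p) is_sequon_at(mut_res, p), NA)
  lost <- (lo:hi)[wt_start & !mu_start]
  gained <- (lo:hi)[!wt_start & mu_start]

  if (length(lost) > 0L) {
    npos <- lost[1L]
    mech <- if (position == npos) {
      "N-loss"
    } else if (position == npos + 1L && mutant == "P") {
      "X-to-proline"
    } else {
      "ST-loss"
    }
    return(variant_effect(
      "disrupting", npos, mech,
      if (length(gained) > 0L) gained[1L] else NA_integer_
    ))
  }
  if (length(gained) > 0L) {
    return(variant_effect("creating", NA_integer_, "new-motif", gained[1L]))
  }
  variant_effect("silent", NA_integer_, "none", NA_integer_)
}

is_sequon_at <- function(residues, p) {
  a <- substr(residues, p, p)
  b <- substr(residues, p + 1L, p + 1L)
  c3 <- substr(residues, p + 2L, p + 2L)
  a == "N" && b != "P" && b != "X" && (c3 == "S" || c3 == "T")
}

variant_effect <- function(class, affected, mechanism, created) {
  structure(
    list(
      class = class, affected_sequon = affected, mechanism = mechanism,
      created_sequon = created
    ),
    class = "variant_effect"
  )
}

#' @export
print.variant_effect <- function(x, ...) {
  cat(sprintf(
    "<variant_effect> %s (mechanism: %s%s)\n", x$class, x$mechanism,
    if (!is.na(x$affected_sequon)) {
      paste0(", sequon N", x$affected_sequon)
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Read a variant table from CSV
#'
#' Expected columns: `isoform` (or `isoform_id`), and either `hgvs_p` or the
#' triple `wild`/`position`/`mutant`; optional `phenotype`, `source`,
#' `clinvar_class`.
#'
#' @param path CSV path.
#' @return Data frame with `isoform_id`, `wild`, `position`, `mutant`,
#'   `type`, `phenotype`, `source`, `flagged_benign`.
#' @export
read_variant_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  iso <- if ("isoform_id" %in% names(raw)) raw$isoform_id else raw$isoform
  if (is.null(iso)) stop("variant CSV needs an 'isoform' column")
  if ("hgvs_p" %in% names(raw)) {
    parsed <- parse_hgvs_p(raw$hgvs_p)
  } else {
    if (!all(c("wild", "position", "mutant") %in% names(raw))) {
      stop("variant CSV needs 'hgvs_p' or wild/position/mutant columns")
    }
    parsed <- data.frame(
      wild = raw$wild, position = as.integer(raw$position),
      mutant = raw$mutant, type = "missense", stringsAsFactors = FALSE
    )
  }
  cl <- if ("clinvar_class" %in% names(raw)) raw$clinvar_class else NA_character_
  data.frame(
    isoform_id = iso, parsed,
    phenotype = if ("phenotype" %in% names(raw)) raw$phenotype else NA_character_,
    source = if ("source" %in% names(raw)) raw$source else NA_character_,
    flagged_benign = !is.na(cl) & grepl("benign", cl, ignore.case = TRUE),
    stringsAsFactors = FALSE
  )
}

#' Build a per-variant sequon-disruption report
#'
#' One row per variant with its effect class, affected sequon, mechanism and
#' phenotype; the `"disrupting_counts"` attribute carries the per-isoform
#' count of disrupting variants.
#'
#' @param seqs Named list of [isoform_sequence()] objects covering every
#'   isoform in `variants`.
#' @param variants Data frame as returned by [read_variant_csv()] (columns
#'   `isoform_id`, `wild`, `position`, `mutant`, `type`; optional
#'   `phenotype`, `source`).
#' @return Data frame report; see Details.
#' @export
build_variant_report <- function(seqs, variants) {
  seqs <- lapply(seqs, as_isoform_sequence)
  names(seqs) <- vapply(seqs, `[[`, "", "isoform_id")
  if (nrow(variants) == 0L) {
    out <- data.frame(
      isoform_id = character(0), variant = character(0), class = character(0),
      affected_sequon = integer(0), mechanism = character(0),
      created_sequon = integer(0), phenotype = character(0),
      stringsAsFactors = FALSE
    )
    attr(out, "disrupting_counts") <- integer(0)
    return(out)
  }
  if (!all(variants$isoform_id %in% names(seqs))) {
    stop("variants reference isoforms without sequences")
  }
  rows <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    eff <- classify_variant(
      seqs[[v$isoform_id]], v$wild, v$position, v$mutant,
      type = if (is.na(v$type)) "missense" else v$type
    )
    data.frame(
      isoform_id = v$isoform_id,
      variant = paste0(
        v$wild, v$position,
        if (v$type == "missense") v$mutant else if (v$type == "frameshift") "fs" else "*"
      ),
      class = eff$class,
      affected_sequon = eff$affected_sequon,
      mechanism = eff$mechanism,
      created_sequon = eff$created_sequon,
      phenotype = if ("phenotype" %in% names(v)) v$phenotype else NA_character_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  counts <- tapply(out$class == "disrupting", out$isoform_id, sum)
  attr(out, "disrupting_counts") <- counts[order(names(counts))]
  out
}
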