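# Conservation mapping of sequon sites across an isoform alignment.
#
# Two sequons are homologous iff their asparagines occupy the same alignment
# column (strict column match, no +/-1 fuzz).

#' Group sequons by alignment column and classify conservation
#'
#' Sequons whose N residues share an alignment column form one site group.
#' A group is classed `"all"` when every isoform in the alignment carries a
#' sequon at that column, `"unique"` when exactly one does, and `"subset"`
#' otherwise. With `resolved_only = TRUE`, groups are *seeded* only from
#' columns carrying at least one structurally resolved site, but membership
#' testing still spans all isoforms (an unresolved sequon joins the group of
#' its column).
#'
#' @param aln An [align_isoforms()] result covering every isoform present in
#'   `sequons`.
#' @param sequons Data frame of sequons (`isoform_id`, `asn_position`,
#'   `motif`), typically `rbind` of [scan_sequons()] over the family.
#' @param resolved Optional data frame (`isoform_id`, `asn_position`) of
#'   sites carrying a resolved glycan moiety in the cryo-EM structures.
#' @param resolved_only Seed groups only from resolved sites?
#' @return A `conservation_map`: data frame with columns `group_id`,
#'   `column`, `class`, `isoform_id`, `asn_position`, `motif`, `resolved`.
#'   Groups are a partition of the reported sequons; `n_isoforms` attribute
#'   records the family size used for the `"all"` call.
#' @export
map_conserved_sequons <- function(aln, sequons, resolved = NULL,
                                  resolved_only = FALSE) {
  stopifnot(inherits(aln, "isoform_alignment"))
  if (nrow(sequons) == 0L) {
    out <- data.frame(
      group_id = integer(0), column = integer(0), class = character(0),
      isoform_id = character(0), asn_position = integer(0),
      motif = character(0), resolved = logical(0), stringsAsFactors = FALSE
    )
    attr(out, "n_isoforms") <- length(aln$ids)
    class(out) <- c("conservation_map", "data.frame")
    return(out)
  }
  if (!all(sequons$isoform_id %in% aln$ids)) {
    stop("sequons reference isoforms missing from the alignment")
  }
  sequons$column <- mapply(
    function(id, p) alignment_column(aln, id, p),
    sequons$isoform_id, sequons$asn_position
  )
  sequons$resolved <- FALSE
  if (!is.null(resolved) && nrow(resolved) > 0L) {
    key <- paste(sequons$isoform_id, sequons$asn_position)
    rkey <- paste(resolved$isoform_id, resolved$asn_position)
    sequons$resolved <- key %in% rkey
  }
  seed_cols <- if (resolved_only) {
    unique(sequons$column[sequons$resolved])
  } else {
    unique(sequons$column)
  }
  seed_cols <- sort(seed_cols)
  keep <- sequons[sequons$column %in% seed_cols, , drop = FALSE]
  keep <- keep[order(keep$column, keep$isoform_id, keep$asn_position), ,
    drop = FALSE
  ]
  keep$group_id <- match(keep$column, seed_cols)
  n_iso <- length(aln$ids)
  cls <- vapply(seed_cols, function(col) {
    members <- unique(keep$isoform_id[keep$column == col])
    if (length(members) == 1L) {
      "unique" # a single-member family classes its sites unique, not all
    } else if (length(members) == n_iso) {
      "all"
    } else {
      "subset"
    }
  }, "")
  keep$class <- cls[keep$group_id]
  out <- keep[, c(
    "group_id", "column", "class", "isoform_id", "asn_position",
    "motif", "resolved"
  )]
  rownames(out) <- NULL
  attr(out, "n_isoforms") <- n_iso
  class(out) <- c("conservation_map", "data.frame")
  out
}

#' Summarize a conservation map by site group
#'
#' @param map A [map_conserved_sequons()] result.
#' @return Data frame with one row per group: `group_id`, `column`, `class`,
#'   `n_isoforms` (members), and the member isoform ids collapsed with "+".
#' @export
conservation_summary <- function(map) {
  stopifnot(inherits(map, "conservation_map"))
  if (nrow(map) == 0L) {
    return(data.frame(
      group_id = integer(0), column = integer(0), class = character(0),
      n_isoforms = integer(0), members = character(0),
      stringsAsFactors = FALSE
    ))
  }
  groups <- split(map, map$group_id)
  do.call(rbind, lapply(groups, function(g) {
    data.frame(
      group_id = g$group_id[1L], column = g$column[1L], class = g$class[1L],
      n_isoforms = length(unique(g$isoform_id)),
      members = paste(sort(unique(g$isoform_id)), collapse = "+"),
      stringsAsFactors = FALSE
    )
  }))
}

#' Write a conservation map as CSV
#'
#' Columns: `group_id`, `class`, `isoform`, `asn_position`, `motif`,
#' `resolved`.
#'
#' @param map A [map_conserved_sequons()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_csv <- function(map, path) {
  stopifnot(inherits(map, "conservation_map"))
  out <- data.frame(
    group_id = map$group_id, class = map$class, isoform = map$isoform_id,
    asn_position = map$asn_position, motif = map$motif,
    resolved = map$resolved, stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
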