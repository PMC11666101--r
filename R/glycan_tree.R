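# Linkage-labelled glycan trees.
#
# A glycan tree is a rooted tree of monosaccharides with anomeric
# (alpha/beta) and carbon-position labels on each linkage. The packaged
# default is the representative complex form used for channel-surface
# modeling: core-fucosylated, bi-antennary, with one terminal sialic acid.

MONOSACCHARIDES <- c("GlcNAc", "Man", "Gal", "Fuc", "Neu5Ac")

#' Construct a glycan tree
#'
#' @param nodes Data frame with columns `id` (unique) and `sugar` (one of
#'   GlcNAc, Man, Gal, Fuc, Neu5Ac).
#' @param linkages Data frame with columns `parent`, `child` (node ids),
#'   `anomeric` (`"alpha"`/`"beta"`), `donor` (anomeric carbon of the child,
#'   usually 1, or 2 for Neu5Ac) and `acceptor` (attachment carbon on the
#'   parent). May have zero rows for a single-node tree.
#' @param name Optional tree name.
#' @return A validated `glycan_tree` object.
#' @export
glycan_tree <- function(nodes, linkages, name = "glycan") {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  linkages <- as.data.frame(linkages, stringsAsFactors = FALSE)
  if (nrow(nodes) == 0L) {
    tree <- structure(
      list(nodes = nodes, linkages = linkages, root = NA_character_,
           name = name),
      class = "glycan_tree"
    )
    return(tree)
  }
  stopifnot(all(c("id", "sugar") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop("duplicated node ids")
  unknown <- setdiff(unique(nodes$sugar), MONOSACCHARIDES)
  if (length(unknown) > 0L) {
    stop("unknown monosaccharide(s): ", paste(unknown, collapse = ", "))
  }
  if (nrow(linkages) > 0L) {
    stopifnot(all(
      c("parent", "child", "anomeric", "donor", "acceptor") %in% names(linkages)
    ))
    if (!all(linkages$anomeric %in% c("alpha", "beta"))) {
      stop("anomeric labels must be 'alpha' or 'beta'")
    }
    if (!all(c(linkages$parent, linkages$child) %in% nodes$id)) {
      stop("linkage references unknown node id")
    }
    if (anyDuplicated(linkages$child)) {
      stop("a node has more than one parent")
    }
    linkages$donor <- as.integer(linkages$donor)
    linkages$acceptor <- as.integer(linkages$acceptor)
  }
  children <- if (nrow(linkages)) linkages$child else character(0)
  roots <- setdiff(nodes$id, children)
  if (length(roots) != 1L) {
    stop("tree must have exactly one root (found ", length(roots), ")")
  }
  # connectivity / acyclicity: BFS from root must reach every node once
  seen <- roots
  frontier <- roots
  while (length(frontier) > 0L) {
    nxt <- linkages$child[linkages$parent %in% frontier]
    if (any(nxt %in% seen)) stop("cycle detected in glycan document")
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (length(seen) != nrow(nodes)) {
    stop("glycan document is not connected")
  }
  root_sugar <- nodes$sugar[nodes$id == roots]
  if (root_sugar != "GlcNAc") {
    stop("root of an N-linked tree must be GlcNAc")
  }
  structure(
    list(nodes = nodes, linkages = linkages, root = roots, name = name),
    class = "glycan_tree"
  )
}

#' @export
print.glycan_tree <- function(x, ...) {
  cat(sprintf(
    "<glycan_tree> '%s': %d residues\n", x$name, nrow(x$nodes)
  ))
  if (nrow(x$nodes) > 0L) cat("  ", iupac_condensed(x), "\n")
  invisible(x)
}

#' Parse a glycan tree from its JSON document
#'
#' The schema is an object with `name`, `nodes` (array of `{id, sugar}`) and
#' `linkages` (array of `{parent, child, anomeric, donor, acceptor}`).
#' Documents with cycles, multiple parents or unknown sugars are rejected.
#'
#' @param path Path to a JSON file (or a JSON string).
#' @return A validated [glycan_tree()].
#' @export
parse_glycan_tree <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (!all(c("nodes", "linkages") %in% names(doc))) {
    stop("glycan document must contain 'nodes' and 'linkages'")
  }
  nodes <- as.data.frame(doc$nodes, stringsAsFactors = FALSE)
  linkages <- if (length(doc$linkages) == 0L) {
    data.frame(
      parent = character(0), child = character(0), anomeric = character(0),
      donor = integer(0), acceptor = integer(0), stringsAsFactors = FALSE
    )
  } else {
    as.data.frame(doc$linkages, stringsAsFactors = FALSE)
  }
  glycan_tree(nodes, linkages, name = if (is.null(doc$name)) "glycan" else doc$name)
}

#' Write a glycan tree as JSON
#'
#' @param tree A [glycan_tree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_glycan_tree <- function(tree, path) {
  stopifnot(inherits(tree, "glycan_tree"))
  doc <- list(name = tree$name, nodes = tree$nodes, linkages = tree$linkages)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Monosaccharide composition of a tree
#'
#' @param tree A [glycan_tree()].
#' @return Named integer vector of counts over the closed monosaccharide set;
#'   the counts sum to the node count.
#' @export
glycan_composition <- function(tree) {
  stopifnot(inherits(tree, "glycan_tree"))
  counts <- setNames(integer(length(MONOSACCHARIDES)), MONOSACCHARIDES)
  if (nrow(tree$nodes) > 0L) {
    tab <- table(tree$nodes$sugar)
    counts[names(tab)] <- as.integer(tab)
  }
  counts
}

#' Children of a node
#' @keywords internal
tree_children <- function(tree, id) {
  tree$linkages$child[tree$linkages$parent == id]
}

#' Leaves (out-degree zero nodes) of a tree
#'
#' @param tree A [glycan_tree()].
#' @return Character vector of leaf node ids.
#' @export
glycan_leaves <- function(tree) {
  stopifnot(inherits(tree, "glycan_tree"))
  if (nrow(tree$nodes) == 0L) return(character(0))
  setdiff(tree$nodes$id, unique(tree$linkages$parent))
}

#' IUPAC-condensed text export
#'
#' Writes the tree in the condensed textual convention, e.g.
#' `Neu5Ac(a2-6)Gal(b1-4)GlcNAc(b1-2)Man(a1-3)[...]Man(b1-4)GlcNAc(b1-4)
#' [Fuc(a1-6)]GlcNAc`. Branches are bracketed and ordered by acceptor carbon
#' (descending), the main chain written last, root rightmost.
#'
#' @param tree A [glycan_tree()].
#' @return A single string.
#' @export
iupac_condensed <- function(tree) {
  stopifnot(inherits(tree, "glycan_tree"))
  if (nrow(tree$nodes) == 0L) return("")
  sugar_of <- setNames(tree$nodes$sugar, tree$nodes$id)
  render <- function(id) {
    kids <- tree$linkages[tree$linkages$parent == id, , drop = FALSE]
    if (nrow(kids) == 0L) return(sugar_of[[id]])
    kids <- kids[order(-kids$acceptor), , drop = FALSE]
    parts <- vapply(seq_len(nrow(kids)), function(i) {
      k <- kids[i, ]
      paste0(
        render(k$child),
        "(", substr(k$anomeric, 1, 1), k$donor, "-", k$acceptor, ")"
      )
    }, "")
    # last child (lowest acceptor carbon) continues the main chain; side
    # branches are bracketed immediately before the parent sugar
    main <- parts[length(parts)]
    side <- parts[-length(parts)]
    paste0(
      main,
      paste0(vapply(side, function(s) paste0("[", s, "]"), ""), collapse = ""),
      sugar_of[[id]]
    )
  }
  render(tree$root)
}

#' The packaged representative N-glycan tree
#'
#' Loads the packaged complex-type template: core-fucosylated bi-antennary
#' tree with one terminal sialic acid (Neu5Ac, recorded alpha2-6 by default;
#' the arm assignment and sialic linkage are configurable by editing the
#' JSON). Composition: GlcNAc 4, Man 3, Gal 2, Fuc 1, Neu5Ac 1 (11 residues).
#'
#' @return A [glycan_tree()].
#' @export
default_glycan_tree <- function() {
  path <- system.file("extdata", "glycan_biantennary.json",
    package = "glycoshield"
  )
  if (!nzchar(path)) stop("packaged glycan document not found")
  parse_glycan_tree(path)
}
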