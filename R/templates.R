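# Idealized rigid monosaccharide templates.
#
# Each template is a pyranose-style chair: six ring atoms on a puckered
# hexagon (all ring bonds 1.52 A), plus exocyclic attachment oxygens at
# carbons 2/3/4, the exocyclic C6-O6 arm, and short tail atoms for Neu5Ac.
# Templates are rigid; all conformational freedom downstream is torsional
# (glycosidic phi/psi and omega for 1-6 linkages). One idealized geometry is
# shared by all five sugars (an excluded-volume model does not resolve
# epimers); the anomeric carbon is always named "C1" (standing in for C2 of
# Neu5Ac).

template_cache <- new.env(parent = emptyenv())

#' Idealized heavy-atom template for a monosaccharide
#'
#' @param sugar One of GlcNAc, Man, Gal, Fuc, Neu5Ac.
#' @return List with `coords` (named matrix, Angstrom, local frame) and
#'   `attach`: per acceptor position, the (oxygen, carbon, previous-carbon)
#'   atom names used to place a child residue.
#' @export
monosaccharide_template <- function(sugar) {
  if (!sugar %in% MONOSACCHARIDES) stop("unknown monosaccharide: ", sugar)
  key <- sugar
  if (!is.null(template_cache[[key]])) {
    return(template_cache[[key]])
  }
  r <- 1.435
  zp <- 0.25
  ring_names <- c("C1", "C2", "C3", "C4", "C5", "O5")
  ang <- (seq_len(6) - 1) * 60 * pi / 180
  ring <- cbind(
    r * cos(ang), r * sin(ang), zp * rep_len(c(1, -1), 6)
  )
  rownames(ring) <- ring_names
  sub_dir <- function(k, up) {
    radial <- unit(c(ring[k, 1], ring[k, 2], 0))
    unit(radial * 0.75 + c(0, 0, up * 0.66))
  }
  o2 <- ring["C2", ] + 1.43 * sub_dir("C2", -1)
  o3 <- ring["C3", ] + 1.43 * sub_dir("C3", 1)
  o4 <- ring["C4", ] + 1.43 * sub_dir("C4", -1)
  c6 <- ring["C5", ] + 1.52 * sub_dir("C5", 1)
  o6 <- c6 + 1.43 * unit(c(unit(c(c6[1], c6[2], 0)) * 0.6 + c(0, 0, 0.8)))
  coords <- rbind(ring, O2 = o2, O3 = o3, O4 = o4, C6 = c6, O6 = o6)
  if (sugar == "Neu5Ac") {
    # short glycerol-tail stand-in
    c7 <- c6 + 1.52 * unit(c(unit(c(c6[1], c6[2], 0)) * 0.9 + c(0, 0, 0.45)))
    c8 <- c7 + 1.52 * unit(c(unit(c(c7[1], c7[2], 0)) * 0.8 + c(0, 0, 0.6)))
    coords <- rbind(coords, C7 = c7, C8 = c8)
  }
  tpl <- list(
    sugar = sugar,
    coords = coords,
    attach = list(
      `2` = c("O2", "C2", "C1"),
      `3` = c("O3", "C3", "C2"),
      `4` = c("O4", "C4", "C3"),
      `6` = c("O6", "C6", "C5")
    )
  )
  template_cache[[key]] <- tpl
  tpl
}
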