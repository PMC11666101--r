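# Conservation mapping of sequon sites.

small_family <- function(seed = 9) {
  make_sequence_family(
    member_ids = paste0("m", 1:5), length = 200,
    planted = data.frame(
      column = c(50, 120, 160),
      members = I(list("all", c("m2", "m3"), "m4")),
      motif = c("NGT", "NAS", "NQT")
    ),
    substitution_rate = 0.05, seed = seed
  )
}

test_that("planted conservation classes are recovered", {
  fam <- small_family()
  aln <- align_isoforms(fam$sequences)
  sequons <- do.call(rbind, lapply(fam$sequences, scan_sequons))
  cmap <- map_conserved_sequons(aln, sequons)
  s <- conservation_summary(cmap)
  expect_equal(sum(s$class == "all"), 1L)
  expect_equal(sum(s$class == "subset"), 1L)
  expect_equal(sum(s$class == "unique"), 1L)
  expect_equal(s$members[s$class == "subset"], "m2+m3")
})

test_that("groups form a partition of the considered sequons", {
  fam <- small_family()
  aln <- align_isoforms(fam$sequences)
  sequons <- do.call(rbind, lapply(fam$sequences, scan_sequons))
  cmap <- map_conserved_sequons(aln, sequons)
  key_in <- sort(paste(sequons$isoform_id, sequons$asn_position))
  key_out <- sort(paste(cmap$isoform_id, cmap$asn_position))
  expect_equal(key_out, key_in) # union of groups = all sequons
  expect_false(any(duplicated(key_out))) # pairwise disjoint
})

test_that("input order does not change group classes", {
  fam <- small_family()
  sequons <- do.call(rbind, lapply(fam$sequences, scan_sequons))
  aln1 <- align_isoforms(fam$sequences)
  aln2 <- align_isoforms(rev(fam$sequences))
  c1 <- map_conserved_sequons(aln1, sequons)
  c2 <- map_conserved_sequons(aln2, sequons)
  k1 <- c1[order(c1$isoform_id, c1$asn_position), c("isoform_id", "asn_position", "class")]
  k2 <- c2[order(c2$isoform_id, c2$asn_position), c("isoform_id", "asn_position", "class")]
  rownames(k1) <- rownames(k2) <- NULL
  expect_equal(k1, k2)
})

test_that("a single-member family classes every sequon unique", {
  s <- isoform_sequence("solo", "AAANGTAAAAANASAAA")
  aln <- manual_alignment(list(s))
  cmap <- map_conserved_sequons(aln, scan_sequons(s))
  expect_true(all(cmap$class == "unique"))
})

test_that("resolved-only seeding keeps membership across all isoforms", {
  fam <- small_family()
  aln <- align_isoforms(fam$sequences)
  sequons <- do.call(rbind, lapply(fam$sequences, scan_sequons))
  # resolve the "all" column only in m1: the group must still span 5 members
  truth <- fam$truth[fam$truth$column == 50 & fam$truth$member == "m1", ]
  resolved <- data.frame(isoform_id = "m1", asn_position = truth$asn_position)
  cmap <- map_conserved_sequons(aln, sequons, resolved, resolved_only = TRUE)
  expect_equal(length(unique(cmap$group_id)), 1L)
  expect_equal(sort(unique(cmap$isoform_id)), paste0("m", 1:5))
  expect_true(all(cmap$class == "all"))
})

test_that("sequons outside the alignment are rejected and CSV export works", {
  fam <- small_family()
  aln <- align_isoforms(fam$sequences)
  bad <- data.frame(isoform_id = "m1", asn_position = 10000L, motif = "NGT")
  expect_error(map_conserved_sequons(aln, bad), "outside sequence")
  sequons <- do.call(rbind, lapply(fam$sequences, scan_sequons))
  cmap <- map_conserved_sequons(aln, sequons)
  path <- withr::local_tempfile(fileext = ".csv")
  write_conservation_csv(cmap, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(cmap))
  expect_true(all(c("group_id", "class", "isoform", "asn_position") %in% names(back)))
})
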