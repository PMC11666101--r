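# Synthetic-data generators and packaged tables.

test_that("sequence families are deterministic and honor their plant", {
  planted <- data.frame(
    column = c(30, 70), members = I(list("all", "m3")), motif = c("NGT", "NAS")
  )
  f1 <- make_sequence_family(paste0("m", 1:4), 120, planted, 0.05, seed = 3)
  f2 <- make_sequence_family(paste0("m", 1:4), 120, planted, 0.05, seed = 3)
  expect_identical(
    lapply(f1$sequences, `[[`, "residues"),
    lapply(f2$sequences, `[[`, "residues")
  )
  # every member's sequon set equals its planted truth, nothing else
  for (id in names(f1$sequences)) {
    got <- scan_sequons(f1$sequences[[id]])$asn_position
    want <- f1$truth$asn_position[f1$truth$member == id]
    expect_equal(sort(got), sort(want))
  }
  expect_equal(f1$truth$class[f1$truth$column == 30][1], "all")
  expect_equal(f1$truth$class[f1$truth$column == 70][1], "unique")
})

test_that("zero substitution rate leaves members identical outside plants", {
  planted <- data.frame(
    column = 40, members = I(list("m1")), motif = "NGT"
  )
  f <- make_sequence_family(c("m1", "m2"), 100, planted, 0, seed = 4)
  a <- strsplit(f$sequences$m1$residues, "")[[1]]
  b <- strsplit(f$sequences$m2$residues, "")[[1]]
  diffs <- which(a != b)
  expect_true(all(diffs >= 40 & diffs <= 42))
})

test_that("colliding plants are rejected as infeasible", {
  planted <- data.frame(
    column = c(40, 41), members = I(list("m1", "m1")), motif = c("NGT", "NAS")
  )
  expect_error(
    make_sequence_family(c("m1", "m2"), 100, planted, 0, seed = 1),
    "infeasible plant"
  )
})

test_that("the synthetic NaV family carries the printed site architecture", {
  fam <- cached_family()
  iso <- nav_isoforms()
  for (i in seq_len(nrow(iso))) {
    expect_equal(
      nchar(fam$sequences[[iso$isoform_id[i]]]$residues), iso$length[i]
    )
  }
  # text-named positions
  sites15 <- fam$sites[fam$sites$isoform_id == "NaV1.5", ]
  expect_true(all(c(283, 288, 291, 318, 328, 1365, 1374, 1380, 1388) %in%
    sites15$asn_position))
  sites11 <- fam$sites[fam$sites$isoform_id == "NaV1.1", ]
  expect_true(all(c(338, 1378, 1392) %in% sites11$asn_position))
  expect_true(819 %in% fam$sites$asn_position[fam$sites$isoform_id == "NaV1.8"])
  # wild-type residues required by the packaged variant table
  s11 <- fam$sequences[["NaV1.1"]]$residues
  expect_equal(substr(s11, 340, 340), "S")
  expect_equal(substr(s11, 1393, 1394), "HT")
  s15 <- fam$sequences[["NaV1.5"]]$residues
  expect_equal(substr(s15, 320, 320), "T")
  expect_equal(substr(s15, 1382, 1382), "S")
  expect_equal(substr(fam$sequences[["NaV1.6"]]$residues, 1360, 1360), "T")
  # every planted site is a scanned sequon and vice versa
  for (id in iso$isoform_id) {
    got <- scan_sequons(fam$sequences[[id]])$asn_position
    want <- fam$sites$asn_position[fam$sites$isoform_id == id]
    expect_equal(sort(got), sort(want))
  }
  # resolved table positions are sequons in their sequences
  res <- fam$resolved
  for (r in seq_len(nrow(res))) {
    got <- scan_sequons(fam$sequences[[res$isoform_id[r]]])$asn_position
    expect_true(res$asn_position[r] %in% got)
  }
  # region annotations stay within their sequences
  for (r in seq_len(nrow(fam$regions))) {
    len <- nchar(fam$sequences[[fam$regions$isoform_id[r]]]$residues)
    expect_lte(fam$regions$end[r], len)
    expect_gte(fam$regions$start[r], 1)
  }
})

test_that("toy channels plant detectable loop glycosites", {
  toy <- make_toy_channel()
  seq <- isoform_sequence("toy", attr(toy, "sequence"))
  found <- scan_sequons(seq)$asn_position
  expect_equal(sort(found), sort(attr(toy, "glycosites")))
  none <- make_toy_channel(sites_per_loop = 0)
  expect_equal(length(attr(none, "glycosites")), 0L)
  expect_equal(nrow(scan_sequons(isoform_sequence("t", attr(none, "sequence")))), 0L)
  # helices above the minimum separation only
  expect_error(make_toy_channel(bundle_radius = 2), "overlap")
  # structure round-trips through PDB
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(toy, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(toy$atoms))
  expect_equal(back$atoms$resno, toy$atoms$resno)
})

test_that("toy complexes construct their designated footprints", {
  cx <- make_toy_complex(n_alpha = 30, footprint_start = 10, footprint_len = 8)
  fp <- extract_interface(cx, "A", "B", cutoff = 5)
  expect_equal(fp$residues, 10:17)
  expect_error(make_toy_complex(n_alpha = 10, footprint_start = 8, footprint_len = 8),
    "infeasible")
})

test_that("packaged study tables load and validate", {
  tabs <- load_paper_tables()
  v11 <- tabs$variants[tabs$variants$isoform_id == "NaV1.1", ]
  expect_equal(sum(v11$type == "missense"), 7L)
  expect_equal(sum(v11$type == "frameshift"), 3L)
  expect_equal(sum(tabs$variants$isoform_id == "NaV1.5"), 2L)
  expect_equal(sum(tabs$variants$isoform_id == "NaV1.6"), 1L)
  expect_equal(sum(tabs$membrane$upper_pct), 100, tolerance = 0.1)
  expect_equal(sum(tabs$membrane$inner_pct), 100, tolerance = 0.1)
  expect_s3_class(tabs$glycan_tree, "glycan_tree")
  expect_equal(sum(glycan_composition(tabs$glycan_tree)), 11L)
  expect_true(all(tabs$resolved_sites$isoform_id %in% nav_isoforms()$isoform_id))
  expect_false("NaV1.9" %in% tabs$resolved_sites$isoform_id) # no structure
})
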