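# Variant classification against N-glycosylation sequons.

toy_seq <- function() {
  # sequons at 3 (NGS), 10 (NHT), 18 (NAT)
  isoform_sequence("toy", "AANGSAAAANHTAAAAANATAAAA")
}

test_that("disruption mechanisms are assigned correctly", {
  s <- toy_seq()
  expect_equal(classify_variant(s, "N", 3, "K")$mechanism, "N-loss")
  expect_equal(classify_variant(s, "S", 5, "F")$mechanism, "ST-loss")
  expect_equal(classify_variant(s, "H", 11, "P")$mechanism, "X-to-proline")
  eff <- classify_variant(s, "T", 12, "I")
  expect_equal(eff$class, "disrupting")
  expect_equal(eff$affected_sequon, 10L)
})

test_that("motif-preserving and distant substitutions are silent", {
  s <- toy_seq()
  # S <-> T at N+2 preserves the motif
  expect_equal(classify_variant(s, "S", 5, "T")$class, "silent")
  expect_equal(classify_variant(s, "T", 12, "S")$class, "silent")
  # >= 3 residues from any sequon N
  expect_equal(classify_variant(s, "A", 23, "W")$class, "silent")
  # X substitution that is not proline is silent
  expect_equal(classify_variant(s, "G", 4, "V")$class, "silent")
})

test_that("creating variants and disrupt+create overlaps are reported", {
  s <- isoform_sequence("toy", "AAAGTAAAA")
  eff <- classify_variant(s, "A", 3, "N") # creates NGT at 3
  expect_equal(eff$class, "creating")
  expect_equal(eff$created_sequon, 3L)
  # one substitution can kill one sequon and create another: disrupting wins
  s2 <- isoform_sequence("toy", "NGSAT")
  eff2 <- classify_variant(s2, "S", 3, "N")
  expect_equal(eff2$class, "disrupting")
  expect_equal(eff2$affected_sequon, 1L)
  expect_equal(eff2$created_sequon, 3L)
})

test_that("wild-residue mismatches and bad input are hard errors", {
  s <- toy_seq()
  expect_error(classify_variant(s, "Q", 3, "K"), "mismatch")
  expect_error(classify_variant(s, "N", 999, "K"), "outside")
  expect_error(classify_variant(s, "N", 3, "N"), "identical")
})

test_that("frameshift and nonsense variants are classed structural", {
  s <- toy_seq()
  expect_equal(classify_variant(s, "N", 3, NA, type = "frameshift")$class, "structural")
  expect_equal(classify_variant(s, "N", 3, NA, type = "nonsense")$class, "structural")
  parsed <- parse_hgvs_p(c("S340F", "N1392fs", "W10*"))
  expect_equal(parsed$type, c("missense", "frameshift", "nonsense"))
  expect_equal(parsed$position, c(340L, 1392L, 10L))
  expect_error(parse_hgvs_p("not-a-variant"), "cannot parse")
})

test_that("classification agrees with the mutate-and-rescan oracle everywhere", {
  s <- toy_seq()
  sq <- scan_sequons(s)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (n in sq$asn_position) {
    for (off in 0:2) {
      pos <- n + off
      wild <- substr(s$residues, pos, pos)
      for (mut in setdiff(aas, wild)) {
        got <- classify_variant(s, wild, pos, mut)$class
        want <- oracle_variant_class(s$residues, pos, mut)
        expect_equal(got, want, info = sprintf("%s%d%s", wild, pos, mut))
      }
    }
  }
})

test_that("variant reports aggregate per-isoform disruption counts", {
  s <- toy_seq()
  v <- data.frame(
    isoform_id = "toy", wild = c("S", "A", "N"), position = c(5L, 23L, 3L),
    mutant = c("F", "W", "K"), type = "missense",
    phenotype = c("p1", "p2", "p3"), stringsAsFactors = FALSE
  )
  rep <- build_variant_report(list(s), v)
  expect_equal(nrow(rep), 3L)
  expect_equal(unname(attr(rep, "disrupting_counts")[["toy"]]), 2L)
  empty <- build_variant_report(list(s), v[0, ])
  expect_equal(nrow(empty), 0L)
})

test_that("variant CSV reader handles hgvs and benign flags", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "isoform,hgvs_p,phenotype,source,clinvar_class",
    "toy,S5F,thing,lit,Pathogenic",
    "toy,N3K,thing,lit,Likely Benign"
  ), path)
  v <- read_variant_csv(path)
  expect_equal(v$position, c(5L, 3L))
  expect_equal(v$flagged_benign, c(FALSE, TRUE))
})
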