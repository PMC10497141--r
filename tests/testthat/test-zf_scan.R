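make_ci <- function(p12 = "EA", x2 = "AA", x13 = strrep("G", 13)) {
  paste0("C", x2, "C", x13, "C", p12, "C")
}

test_that("exact spacing patterns are detected with correct geometry", {
  ci <- paste0("C", "AA", "C", strrep("G", 13), "C", "KK", "C")
  hit <- scan_zinc_fingers(ci, kinds = "CI")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$start, 0L)
  expect_equal(hit$end, 21L)
  expect_equal(unlist(hit[, c("s1", "s2", "s3")], use.names = FALSE),
               c(2L, 13L, 2L))

  cii <- paste0("C", "GEGEG", "C", strrep("A", 9), "C", "NL", "C")
  hit2 <- scan_zinc_fingers(cii, kinds = "CII")
  expect_equal(nrow(hit2), 1L)
  expect_equal(unlist(hit2[, c("s1", "s2", "s3")], use.names = FALSE),
               c(5L, 9L, 2L))

  expect_equal(nrow(scan_zinc_fingers(strrep("MKLV", 10))), 0L)
})

test_that("overlapping fingers of one kind are all reported, sorted", {
  # cysteines at 0,3,6,17,20,23 support CI starts at both 0 and 3
  chars <- rep("G", 24)
  chars[c(1, 4, 7, 18, 21, 24)] <- "C"
  seq <- paste0(chars, collapse = "")
  hits <- scan_zinc_fingers(seq, kinds = "CI")
  expect_equal(hits$start, c(0L, 3L))
})

test_that("input X never matches an anchor but passes through spacers", {
  ci <- make_ci()
  expect_equal(nrow(scan_zinc_fingers(ci, kinds = "CI")), 1L)
  x_anchor <- sub("^C", "X", ci)
  expect_equal(nrow(scan_zinc_fingers(x_anchor, kinds = "CI")), 0L)
  x_spacer <- paste0("C", "XX", "C", strrep("X", 13), "C", "XX", "C")
  expect_equal(nrow(scan_zinc_fingers(x_spacer, kinds = "CI")), 1L)
})

test_that("tolerant mode accepts +/-1 on the long spacer only when asked", {
  ci14 <- paste0("C", "AA", "C", strrep("G", 14), "C", "KK", "C")
  expect_equal(nrow(scan_zinc_fingers(ci14, kinds = "CI")), 0L)
  tol <- scan_zinc_fingers(ci14, kinds = "CI", tolerant = TRUE)
  expect_equal(nrow(tol), 1L)
  expect_equal(tol$s2, 14L)
})

test_that("scanner agrees with the brute-force window oracle", {
  set.seed(101)
  for (i in 1:150) {
    seq <- random_seq(200, c_rich = TRUE)
    for (kind in c("CI", "CII", "CHC2")) {
      hits <- scan_zinc_fingers(seq, kinds = kind)
      expect_identical(hits$start, bf_scan_fingers(seq, kind),
                       label = paste(kind, "seq", i))
    }
  }
})

test_that("reported fingers re-match their own definition", {
  set.seed(7)
  cfg <- default_config()$zinc_fingers
  for (i in 1:40) {
    seq <- random_seq(300, c_rich = TRUE)
    hits <- scan_zinc_fingers(seq, kinds = c("CI", "CII", "CHC2"))
    for (r in seq_len(nrow(hits))) {
      h <- hits[r, ]
      def <- cfg[[h$kind]]
      anchors <- substring(seq, c(h$a1, h$a2, h$a3, h$a4) + 1,
                           c(h$a1, h$a2, h$a3, h$a4) + 1)
      expect_equal(anchors, def$anchors)
      expect_equal(h$end - h$start, 4L + sum(def$spacers))
    }
  }
})

test_that("DBD assembly pairs CI with the nearest following CII in range", {
  # CI at 10, CII at 35 (gap 4)
  seq <- paste0(strrep("G", 10), make_ci(p12 = "EA"), "KK", "GG",
                paste0("C", "KYEGA", "C", strrep("A", 9), "C", "GG", "C"),
                strrep("G", 10))
  fingers <- scan_zinc_fingers(seq)
  dbds <- assemble_dbds(fingers, seq)
  expect_equal(nrow(dbds), 1L)
  expect_equal(dbds$start, 10L)
  expect_equal(dbds$p_box, "EACKK")
  expect_equal(dbds$d_box, "KYEGA")
  expect_equal(dbds$ordinal, "ONLY")

  # orphan CI: no CII within the gap
  lone <- paste0(strrep("G", 10), make_ci(), strrep("G", 80))
  fg <- scan_zinc_fingers(lone)
  d0 <- assemble_dbds(fg, lone)
  expect_equal(nrow(d0), 0L)
  expect_equal(nrow(attr(d0, "orphans")), 1L)
})

test_that("synthetic group-A receptors yield the canonical P-boxes", {
  out <- make_sequence(synth_params(seed = 5))
  fg <- scan_zinc_fingers(out$record$residues)
  dbds <- assemble_dbds(fg, out$record$residues)
  expect_equal(nrow(dbds), 2L)
  expect_equal(dbds$p_box, c("EACKK", "EGCKG"))
  expect_equal(dbds$ordinal, c("FIRST", "SECOND"))
  # the middle P-box residue is the fourth cysteine of CI
  expect_equal(substr(dbds$p_box, 3, 3), c("C", "C"))
  expect_equal(dbds$ci_a4 - dbds$ci_a3, c(3L, 3L))
  # and a B1-style receptor yields the molluscan first P-box
  b1 <- make_sequence(synth_params(group = "B", pbox1 = "LPCKS",
                                   pbox2 = "EGCKK", seed = 6))
  db <- assemble_dbds(scan_zinc_fingers(b1$record$residues),
                      b1$record$residues)
  expect_equal(db$p_box[1], "LPCKS")
})

test_that("P-box extraction errors on a truncated DBD", {
  seq <- paste0(make_ci(), "K")  # ends one residue into the P-box tail
  fake_dbd <- data.frame(ci_a3 = 17L, cii_a1 = 0L)
  expect_error(extract_pbox(fake_dbd, seq), "partial DBD")
})

test_that("no CHC2 motif occurs in synthetic two-DBD receptors", {
  panel <- make_panel(2, seed = 13)
  pos <- panel$records[grepl("^(A|B|C)", panel$records$id), ]
  for (i in seq_len(nrow(pos))) {
    expect_equal(nrow(scan_zinc_fingers(pos$residues[i], kinds = "CHC2")),
                 0L)
  }
})
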