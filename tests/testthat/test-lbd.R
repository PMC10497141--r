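ti_example <- "FAKGGGGFGGLGGGDQGGLL"

test_that("residue classes partition the amino-acid alphabet", {
  rc <- residue_classes()
  expect_setequal(unlist(rc), aa_alphabet())
  expect_equal(sum(lengths(rc)), 20L)
})

test_that("Ti consensus matches instantiated strings and spans 20 residues", {
  hits <- scan_ti(ti_example)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 0L)
  expect_equal(hits$end - hits$start, 20L)
  expect_equal(hits$sequence, ti_example)
  # violating the first fixed position kills the match
  expect_equal(nrow(scan_ti(sub("^F", "A", ti_example))), 0L)
})

test_that("every fixed Ti position rejects a disallowed residue", {
  allowed <- list(c("F","W","Y"), c("A","S","I"), c("K","R","E","G"),
                  NULL, NULL, NULL, NULL, c("F","L"), NULL, NULL,
                  c("L","V","I"), NULL, NULL, NULL, c("D","S"),
                  c("Q","K"), NULL, NULL, c("L","V"), c("L","I","F"))
  for (k in seq_along(allowed)) {
    if (is.null(allowed[[k]])) next
    bad <- setdiff(aa_alphabet(), allowed[[k]])[1]
    mutated <- ti_example
    substr(mutated, k, k) <- bad
    expect_equal(nrow(scan_ti(mutated)), 0L, label = paste("position", k))
  }
})

test_that("Ti scanning agrees with the brute-force window oracle", {
  set.seed(31)
  for (i in 1:60) {
    # splice Ti-like fragments into random backgrounds
    seq <- paste0(random_seq(40), ti_example,
                  random_seq(15), ti_example, random_seq(25))
    expect_identical(scan_ti(seq)$start, bf_scan_ti(seq))
    rnd <- random_seq(200)
    expect_identical(scan_ti(rnd)$start, bf_scan_ti(rnd))
    expect_identical(scan_ti(rnd, search_start = 50)$start,
                     bf_scan_ti(rnd, from = 50))
  }
})

test_that("LBD detection is Ti-based, independent of AF2", {
  typical <- make_sequence(synth_params(architecture = "TYPICAL_NR",
                                        group = NA, seed = 41))
  expect_true(detect_lbd(typical$record$residues))
  expect_false(detect_lbd(strrep("G", 100)))
  # A. avenae-style group C: Ti present, no AF2 embedded
  avenae <- make_sequence(synth_params(group = "C", pbox1 = "DGCKS",
                                       pbox2 = "KSCSE", af2 = NA,
                                       seed = 42))
  expect_true(detect_lbd(avenae$record$residues))
  expect_null(scan_af2(avenae$record$residues, group_hint = "C",
                       from_pos = avenae$truth$lbd_start))
})

test_that("AF2 variants match their consensus and prefer the C-terminus", {
  expect_equal(scan_af2(paste0(strrep("G", 30), "LLDELL"),
                        group_hint = "A")$variant, "A")
  hitb <- scan_af2(paste0(strrep("G", 30), "IVTKVR"), group_hint = "B")
  expect_equal(hitb$variant, "B")
  expect_equal(hitb$sequence, "IVTKVR")
  hitc <- scan_af2(paste0(strrep("G", 30), "GGLLVI"), group_hint = "C")
  expect_equal(hitc$variant, "C_CBRENNERI")
  # two general matches: the later one wins
  two <- paste0("LLDELL", strrep("G", 20), "VVAEII", "GG")
  expect_equal(scan_af2(two)$start, 26L)
})

test_that("dimer class profile implements the discriminator logic", {
  cmap <- c(E5 = 0, ED42 = 1, E50 = 2, KR55 = 3, R62 = 4, HRK90 = 5,
            RK93 = 6)
  p1 <- dimer_class_profile("EGE-GGK", cmap)
  expect_equal(p1$call, "CLASS_I")
  expect_false(p1$markers[["KR55"]])
  expect_true(p1$markers[["E50"]])

  p2 <- dimer_class_profile("GDERRHG", cmap)
  expect_equal(p2$call, "CLASS_II")

  p3 <- dimer_class_profile("-------", cmap)
  expect_equal(p3$call, "NONE")
  expect_false(any(p3$markers))

  expect_equal(dimer_class_profile("EEEKRHK", cmap)$call, "AMBIGUOUS")
  expect_error(dimer_class_profile("EGE", cmap), "beyond")
  expect_error(dimer_class_profile("EGE-GGK", cmap[-7]), "RK93")
})

test_that("class-configured synthetic LBDs recover their class call", {
  cmap <- default_config()$column_map
  for (cls in c("CLASS_I", "CLASS_II")) {
    out <- make_sequence(synth_params(class_markers = cls, seed = 51))
    row <- substr(out$record$residues, out$truth$lbd_start + 1,
                  out$truth$lbd_end)
    prof <- dimer_class_profile(row, cmap)
    expect_equal(prof$call, cls)
    if (cls == "CLASS_I") {
      expect_true(prof$markers[["E50"]])
      expect_true(prof$markers[["RK93"]])
      expect_false(prof$markers[["KR55"]])
    }
  }
})
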