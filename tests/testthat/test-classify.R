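dbds_from <- function(p1, p2) {
  data.frame(p_box = c(p1, p2), start = c(0, 100))
}

test_that("P-P module restores the anchor cysteines for display", {
  expect_equal(pp_module(dbds_from("EACKK", "EGCKG"))$rendered,
               "CEACKK-CEGCKG")
  expect_equal(pp_module(dbds_from("LPCKS", "EGCKK"))$rendered,
               "CLPCKS-CEGCKK")
  expect_equal(pp_module(dbds_from("EACKS", "EGCKG"))$rendered,
               "CEACKS-CEGCKG")
  expect_error(pp_module(dbds_from("EACKK", "EGCKG")[1, ]), "two DBDs")
})

test_that("the four printed signatures classify exactly at distance 0", {
  cases <- list(c("CEACKK-CEGCKG", "A"), c("CEACKK-CEACKG", "A"),
                c("CLPCKS-CEGCKK", "B"), c("CEACKS-CEGCKG", "B"))
  for (cs in cases) {
    call <- assign_group(cs[1])
    expect_equal(call$group, cs[2])
    expect_equal(call$distance, 0L)
    expect_equal(call$matched_signature, cs[1])
  }
})

test_that("near-miss, taxon-gated and tied modules route correctly", {
  # one mismatch from the canonical group-A signature
  near <- assign_group("CEACKK-CEGCKA")
  expect_equal(near$group, "A")
  expect_equal(near$distance, 1L)
  # far from everything: group C only under the Nematoda gate
  far <- "CAAAAA-CAAAAA"  # hand-checked: >= 2 mismatches to all signatures
  expect_equal(assign_group(far, nematoda = TRUE)$group, "C")
  expect_equal(assign_group(far, nematoda = FALSE)$group, "UNCLASSIFIED")
  # equidistant between the two group-A signatures -> unclassifiable
  tie <- assign_group("CEACKK-CEECKG")
  expect_equal(tie$group, "UNCLASSIFIED")
  expect_equal(tie$distance, 1L)
})

test_that("P-P distance is a metric on rendered modules", {
  set.seed(61)
  rand_pp <- function() {
    box <- function() {
      b <- sample(aa_alphabet(), 5, replace = TRUE)
      b[3] <- "C"
      paste0(b, collapse = "")
    }
    paste0("C", box(), "-C", box())
  }
  pd <- nr2dbd:::pp_distance
  for (i in 1:30) {
    a <- rand_pp(); b <- rand_pp(); c <- rand_pp()
    expect_equal(pd(a, a), 0)
    expect_equal(pd(a, b), pd(b, a))
    expect_gte(pd(a, c) + pd(c, b), pd(a, b))
  }
})

test_that("generated groups are re-assigned with distance 0", {
  panel <- make_panel(2, seed = 71)
  rep <- annotate_sequences(panel$records,
                            nematoda = grepl("^C_", panel$records$id))
  pos <- merge(rep, panel$truth[, c("seq_id", "group")], by = "seq_id")
  pos <- pos[!is.na(pos$group.y), ]
  expect_equal(pos$group.x, pos$group.y)
  ab <- pos[pos$group.y %in% c("A", "B"), ]
  expect_true(all(ab$group_distance == 0L))
})

test_that("nomenclature names render and re-parse bijectively", {
  expect_equal(assign_name("Bc", "A", 1, "a")$rendered, "Bc2DBD-NRA1a")
  expect_equal(assign_name("Pa", "B", 1)$rendered, "Pa2DBD-NRB1")
  expect_equal(assign_name("Aca", "B", 3)$rendered, "Aca2DBD-NRB3")
  expect_equal(assign_name("Pa", "B", 1, suppress_number = TRUE)$rendered,
               "Pa2DBD-NRB")
  expect_error(assign_name("Sm", list(group = "UNCLASSIFIED"), 1),
               "cannot name")
  expect_error(assign_name("toolong", "A", 1), "1-4 letters")

  set.seed(81)
  for (i in 1:25) {
    code <- paste0(sample(LETTERS, 1),
                   paste0(sample(letters, sample(0:3, 1)), collapse = ""))
    nm <- assign_name(code, sample(c("A", "B", "C"), 1),
                      sample.int(9, 1),
                      if (runif(1) < 0.5) sample(letters, 1) else NULL)
    back <- parse_name(nm$rendered)
    expect_equal(back$species_code, nm$species_code)
    expect_equal(back$group_letter, nm$group_letter)
    expect_equal(back$gene_number, nm$gene_number)
    expect_equal(back$variant_letter, nm$variant_letter)
  }
})

test_that("gene numbering follows subgroup order with variant letters", {
  one <- number_genes(c(m1 = "sg"))
  expect_equal(one$gene_number, 1L)
  expect_true(is.na(one$variant_letter))

  twin <- number_genes(c(m1 = "sg", m2 = "sg"))
  expect_equal(twin$gene_number, c(1L, 1L))
  expect_equal(twin$variant_letter, c("a", "b"))

  three <- number_genes(c(x = "s1", y = "s2", z = "s3"))
  expect_equal(three$gene_number, 1:3)
  expect_true(all(is.na(three$variant_letter)))

  mixed <- number_genes(c(a = "s1", b = "s2", c = "s1", d = "s3"))
  expect_equal(mixed$gene_number, c(1L, 2L, 1L, 3L))
  expect_equal(mixed$variant_letter, c("a", NA, "b", NA))
})
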