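# Seeded generator of synthetic receptor proteins with ground truth.
# Sequences are assembled left to right from the motif grammar itself:
# AB (optionally ending in an NTSS) + DBD1 + linker + DBD2 + CTE
# (pre-Grip + G-box + conserved fifth residue) + hinge + LBD (Ti, class
# markers, AF2). Filler residues are drawn from the neutral class minus C
# and H so that no spurious zinc-finger anchors can arise; this is a
# deliberate simplification relative to real sequences.

synth_filler_alphabet <- function() setdiff(residue_classes()$neutral,
                                            c("C", "H"))

filler <- function(n) {
  if (n <= 0L) return("")
  paste0(sample(synth_filler_alphabet(), n, replace = TRUE), collapse = "")
}

# Random instantiation of a degenerate consensus: fixed positions pick one
# allowed residue, wildcards draw from the neutral filler alphabet.
instantiate_consensus <- function(pattern) {
  pos <- parse_consensus(pattern)
  paste0(vapply(pos, function(p) {
    if (is.null(p)) sample(synth_filler_alphabet(), 1L)
    else if (length(p) == 1L) p
    else sample(p, 1L)
  }, character(1)), collapse = "")
}

#' Parameters for the synthetic-sequence generator
#'
#' Collects every dial of [make_sequence()] with defaults matching the
#' canonical group-A tandem-DBD receptor: P-P module EACKK/EGCKG, an
#' inter-DBD linker drawn uniformly from 17-22 residues, a 5-residue
#' pre-Grip followed by a group-A G-box and the conserved `H` five residues
#' downstream, a Ti-bearing LBD with class I marker residues, and an AF2-AD
#' core at the C-terminus.
#'
#' @param architecture `"TWO_DBD_NR"`, `"TYPICAL_NR"`, `"DBD_ONLY"`,
#'   `"LBD_ONLY"` or `"NOT_NR"`.
#' @param group `"A"`, `"B"`, `"C"` or `NA` (drives variant defaults).
#' @param pbox1,pbox2 5-letter P-boxes; position 3 must be `C`.
#' @param dbox1,dbox2 5-letter D-boxes.
#' @param linker_len residues between the DBDs; `NULL` = uniform in 17-22.
#' @param intra_gap residues between CI end and CII start within one DBD
#'   (the first two are the P-box tail).
#' @param pre_grip_len residues between DBD end and G-box; `NULL` = 5
#'   (8 for group C).
#' @param gbox literal G-box to embed, or `NULL` to instantiate the group's
#'   variant consensus.
#' @param post_gbox_fifth residue placed five positions after the G-box;
#'   `NULL` = `"H"` for group A, filler otherwise.
#' @param ntss `NULL` or one of `"TREMATODE_A1"`, `"CESTODE_A1"`, `"A2_A3"`:
#'   embed that signature at the 3' end of the A/B domain.
#' @param ti embed a Ti signature in the LBD (default `TRUE`).
#' @param af2 `NULL`/`NA` for none, or `"GENERAL"`, `"A"`, `"B"`,
#'   `"C_CBRENNERI"`; `NULL` picks the group's variant.
#' @param class_markers `"CLASS_I"`, `"CLASS_II"` or `"none"`.
#' @param ab_len,hinge_len,lbd_len segment lengths (LBD must cover the
#'   default marker columns and a C-terminal AF2).
#' @param chc2 embed a CHC2 zinc finger (decoy feature; only sensible with
#'   `architecture = "NOT_NR"`).
#' @param seed optional integer; fixing it makes [make_sequence()]
#'   deterministic.
#' @return a parameter list of class `synth_params`.
#' @export
synth_params <- function(architecture = "TWO_DBD_NR", group = "A",
                         pbox1 = "EACKK", pbox2 = "EGCKG",
                         dbox1 = "KYEGA", dbox2 = "NTKDA",
                         linker_len = NULL, intra_gap = 10L,
                         pre_grip_len = NULL, gbox = NULL,
                         post_gbox_fifth = NULL, ntss = NULL,
                         ti = TRUE, af2 = NULL, class_markers = "CLASS_I",
                         ab_len = 40L, hinge_len = 20L, lbd_len = 120L,
                         chc2 = FALSE, seed = NULL) {
  p <- as.list(environment())
  class(p) <- c("synth_params", "list")
  p
}

validate_pbox <- function(pbox, which) {
  if (nchar(pbox) != 5L || substr(pbox, 3, 3) != "C") {
    stop(which, " must be 5 residues with 'C' at position 3: ", pbox,
         call. = FALSE)
  }
}

ci_core <- function(pbox) {
  # C-X2-C-X13-C-<p1 p2>-C ; P-box positions 4,5 follow the finger
  paste0("C", filler(2), "C", filler(13), "C",
         substr(pbox, 1, 2), "C")
}

cii_core <- function(dbox) {
  paste0("C", dbox, "C", filler(9), "C", filler(2), "C")
}

# DBD segment: CI core + P-box tail + remaining intra-finger filler + CII.
dbd_segment <- function(pbox, dbox, intra_gap) {
  stopifnot(intra_gap >= 2L)
  paste0(ci_core(pbox), substr(pbox, 4, 5), filler(intra_gap - 2L),
         cii_core(dbox))
}

default_gbox_variant <- function(group) {
  if (is.null(group) || is.na(group)) return("GENERAL")
  switch(as.character(group),
         A = "A_VARIANT", B = "B_VARIANT", C = "C_AAVENAE", "GENERAL")
}

default_af2_variant <- function(group) {
  if (is.null(group) || is.na(group)) return("GENERAL")
  switch(as.character(group), A = "A", B = "B", C = "C_CBRENNERI", "GENERAL")
}

# LBD layout constants (0-based offsets from LBD start).
synth_ti_offset <- function() 10L

#' Generate one synthetic receptor sequence with ground truth
#'
#' Assembles a protein according to `params` and returns both the sequence
#' record and a truth row holding every realized parameter and the 0-based
#' half-open coordinates of every embedded motif. With a fixed
#' `params$seed` the output is deterministic.
#'
#' @param params a [synth_params()] list.
#' @return list with `record` (one-row data.frame: `id`, `description`,
#'   `residues`) and `truth` (one-row data.frame of realized values).
#' @export
#' @examples
#' out <- make_sequence(synth_params(seed = 1))
#' out$truth$linker_len
make_sequence <- function(params) {
  stopifnot(inherits(params, "synth_params") || is.list(params))
  p <- params
  if (!is.null(p$seed)) set.seed(p$seed)
  cfg <- default_config()
  truth <- list(seq_id = if (!is.null(p$id)) p$id else "synth",
                architecture = p$architecture,
                group = if (is.null(p$group)) NA_character_ else
                  as.character(p$group),
                pbox1 = NA_character_, dbox1 = NA_character_,
                pbox2 = NA_character_, dbox2 = NA_character_,
                linker_len = NA_integer_, pre_grip_len = NA_integer_,
                gbox = NA_character_, gbox_variant = NA_character_,
                post_gbox_fifth = NA_character_,
                ntss_pattern = NA_character_, ntss_start = NA_integer_,
                ntss_end = NA_integer_,
                ti = FALSE, ti_start = NA_integer_,
                af2 = NA_character_, af2_variant = NA_character_,
                af2_start = NA_integer_, class_call = NA_character_,
                dbd1_start = NA_integer_, dbd1_end = NA_integer_,
                dbd2_start = NA_integer_, dbd2_end = NA_integer_,
                gbox_start = NA_integer_, lbd_start = NA_integer_,
                lbd_end = NA_integer_, seq_len = NA_integer_)

  if (identical(p$architecture, "NOT_NR")) {
    residues <- if (isTRUE(p$chc2)) {
      paste0(filler(60L),
             paste0("C", filler(6), "C", filler(9), "H", filler(2), "C"),
             filler(60L))
    } else {
      paste0(sample(aa_alphabet(), 300L, replace = TRUE), collapse = "")
    }
    truth$seq_len <- nchar(residues)
    return(finish_sequence(residues, truth))
  }

  has_dbd <- p$architecture %in% c("TWO_DBD_NR", "TYPICAL_NR", "DBD_ONLY")
  two_dbd <- identical(p$architecture, "TWO_DBD_NR")
  has_lbd <- p$architecture %in% c("TWO_DBD_NR", "TYPICAL_NR", "LBD_ONLY")

  parts <- character()
  pos <- 0L
  push <- function(s) {
    parts[[length(parts) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }

  # A/B domain, optionally ending in an NTSS
  if (!is.null(p$ntss) && !is.na(p$ntss) && has_dbd) {
    inst <- instantiate_consensus(cfg$ntss[[p$ntss]])
    stopifnot(p$ab_len >= nchar(inst))
    push(filler(p$ab_len - nchar(inst)))
    truth$ntss_pattern <- p$ntss
    truth$ntss_start <- pos
    push(inst)
    truth$ntss_end <- pos
  } else {
    push(filler(p$ab_len))
  }

  if (has_dbd) {
    validate_pbox(p$pbox1, "pbox1")
    truth$dbd1_start <- pos
    push(dbd_segment(p$pbox1, p$dbox1, p$intra_gap))
    truth$dbd1_end <- pos
    truth$pbox1 <- p$pbox1
    truth$dbox1 <- p$dbox1
  }

  if (two_dbd) {
    validate_pbox(p$pbox2, "pbox2")
    linker <- if (is.null(p$linker_len)) sample(17:22, 1L) else
      as.integer(p$linker_len)
    stopifnot(linker >= 0L)
    push(filler(linker))
    truth$linker_len <- linker
    truth$dbd2_start <- pos
    push(dbd_segment(p$pbox2, p$dbox2, p$intra_gap))
    truth$dbd2_end <- pos
    truth$pbox2 <- p$pbox2
    truth$dbox2 <- p$dbox2
  }

  # C-terminal extension of the (last) DBD: pre-Grip + G-box + fifth residue
  if (has_dbd) {
    pre <- if (!is.null(p$pre_grip_len)) as.integer(p$pre_grip_len)
    else if (identical(p$group, "C")) 8L else 5L
    gvariant <- default_gbox_variant(p$group)
    gseq <- if (!is.null(p$gbox)) p$gbox else
      instantiate_consensus(cfg$gbox[[gvariant]])
    fifth <- if (!is.null(p$post_gbox_fifth)) p$post_gbox_fifth
    else if (identical(p$group, "A")) "H" else filler(1L)
    push(filler(pre))
    truth$pre_grip_len <- pre
    truth$gbox_start <- pos
    truth$gbox <- gseq
    truth$gbox_variant <- if (!is.null(p$gbox)) "CUSTOM" else gvariant
    push(gseq)
    push(filler(4L))
    truth$post_gbox_fifth <- fifth
    push(fifth)
  }

  if (has_lbd) {
    push(filler(p$hinge_len))
    truth$lbd_start <- pos
    lbd <- build_lbd(p, cfg, truth)
    truth <- lbd$truth
    truth$lbd_start <- pos
    if (truth$ti) truth$ti_start <- pos + synth_ti_offset()
    if (!is.na(truth$af2_variant)) truth$af2_start <- pos + p$lbd_len - 6L
    push(lbd$segment)
    truth$lbd_end <- pos
  } else {
    push(filler(10L))  # short C-terminal tail
  }

  residues <- paste0(parts, collapse = "")
  truth$seq_len <- nchar(residues)
  finish_sequence(residues, truth)
}

# LBD segment of length p$lbd_len: neutral filler overwritten with the Ti
# instance, the class marker residues, and a C-terminal AF2 instance.
build_lbd <- function(p, cfg, truth) {
  stopifnot(p$lbd_len >= 100L)
  chars <- strsplit(filler(p$lbd_len), "")[[1]]
  if (isTRUE(p$ti)) {
    inst <- strsplit(instantiate_consensus(cfg$ti), "")[[1]]
    chars[synth_ti_offset() + seq_along(inst)] <- inst
    truth$ti <- TRUE
  }
  cmap <- cfg$column_map
  cm <- p$class_markers
  if (identical(cm, "CLASS_I")) {
    chars[cmap[["E5"]] + 1L] <- "E"
    chars[cmap[["E50"]] + 1L] <- "E"
    chars[cmap[["RK93"]] + 1L] <- sample(c("K", "R"), 1L)
    truth$class_call <- "CLASS_I"
  } else if (identical(cm, "CLASS_II")) {
    chars[cmap[["ED42"]] + 1L] <- sample(c("E", "D"), 1L)
    chars[cmap[["E50"]] + 1L] <- "E"
    chars[cmap[["R62"]] + 1L] <- "R"
    chars[cmap[["HRK90"]] + 1L] <- sample(c("H", "R", "K"), 1L)
    truth$class_call <- "CLASS_II"
  } else {
    truth$class_call <- "NONE"
  }
  af2v <- if (is.null(p$af2)) default_af2_variant(p$group) else p$af2
  if (!is.null(af2v) && !is.na(af2v)) {
    inst <- strsplit(instantiate_consensus(cfg$af2[[af2v]]), "")[[1]]
    chars[(p$lbd_len - 6L) + seq_along(inst)] <- inst
    truth$af2 <- paste0(inst, collapse = "")
    truth$af2_variant <- af2v
  }
  list(segment = paste0(chars, collapse = ""), truth = truth)
}

finish_sequence <- function(residues, truth) {
  record <- data.frame(id = truth$seq_id, description = "synthetic",
                       residues = residues, stringsAsFactors = FALSE)
  list(record = record,
       truth = as.data.frame(truth, stringsAsFactors = FALSE))
}

panel_templates <- function() {
  list(
    A1 = synth_params(group = "A", pbox1 = "EACKK", pbox2 = "EGCKG",
                      ntss = "TREMATODE_A1"),
    A2 = synth_params(group = "A", pbox1 = "EACKK", pbox2 = "EACKG",
                      ntss = "A2_A3"),
    B1 = synth_params(group = "B", pbox1 = "LPCKS", pbox2 = "EGCKK"),
    B2 = synth_params(group = "B", pbox1 = "EACKS", pbox2 = "EGCKG"),
    C  = synth_params(group = "C", pbox1 = "DGCKS", pbox2 = "KSCSE"),
    decoy_typical = synth_params(architecture = "TYPICAL_NR", group = NA,
                                 pbox1 = "EACKA"),
    decoy_lbd_only = synth_params(architecture = "LBD_ONLY", group = NA),
    decoy_chc2 = synth_params(architecture = "NOT_NR", group = NA,
                              chc2 = TRUE),
    decoy_random = synth_params(architecture = "NOT_NR", group = NA)
  )
}

#' Generate a seeded synthetic panel covering all templates
#'
#' Emits `n_per_template` independently fillered copies of each of nine
#' templates: five two-DBD positives covering the five known P-P module
#' situations (group A canonical and rotifer variants, group B canonical and
#' echinoderm variants, and a variable group-C stand-in), plus four decoys
#' (single-DBD typical receptor, LBD-only, a CHC2-finger protein, and a
#' random protein). The group-C P-P module is a synthetic stand-in: the real
#' nematode module is highly variable with no consensus.
#'
#' @param n_per_template copies of each template (default 1; a panel is then
#'   9 records).
#' @param seed integer RNG seed; fixed seed means identical output.
#' @return list with `records` (data.frame of sequences) and `truth`
#'   (data.frame aligned row-for-row with `records`).
#' @export
#' @examples
#' panel <- make_panel(1, seed = 42)
#' nrow(panel$records)
make_panel <- function(n_per_template = 1L, seed = 1L) {
  stopifnot(n_per_template >= 1L)
  set.seed(seed)
  templates <- panel_templates()
  recs <- list()
  truths <- list()
  for (nm in names(templates)) {
    for (i in seq_len(n_per_template)) {
      p <- templates[[nm]]
      p$id <- sprintf("%s_%03d", nm, i)
      p$seed <- NULL  # draw from the panel RNG stream
      out <- make_sequence(p)
      out$truth$template <- nm
      recs[[length(recs) + 1L]] <- out$record
      truths[[length(truths) + 1L]] <- out$truth
    }
  }
  list(records = do.call(rbind, recs), truth = do.call(rbind, truths))
}
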