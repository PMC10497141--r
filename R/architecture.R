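# Modular architecture classification, inter-DBD linker measurement, and
# annotation of the A/B domain (NTSS) and the C-terminal extension
# (G-box / pre-Grip / T-box). Coordinates 0-based, half-open.

architecture_levels <- function() {
  c("TYPICAL_NR", "DBD_ONLY", "LBD_ONLY", "TWO_DBD_NR", "NOT_NR")
}

#' Classify the modular architecture of a receptor candidate
#'
#' Maps DBD and LBD detection results onto the four canonical receptor
#' architectures plus a rejection class: one DBD with an LBD is a typical
#' receptor; a DBD without LBD or an LBD without DBD are the atypical
#' single-module forms; two DBDs plus an LBD is the tandem-DBD receptor
#' (2DBD-NR); neither module means the sequence is not a nuclear receptor.
#' More than two DBDs is classified `TWO_DBD_NR` from the first two, with a
#' warning (the extra domains are flagged in the pipeline report).
#'
#' @param dbds data.frame from [assemble_dbds()].
#' @param lbd_detected logical from [detect_lbd()].
#' @return one of `"TYPICAL_NR"`, `"DBD_ONLY"`, `"LBD_ONLY"`, `"TWO_DBD_NR"`,
#'   `"NOT_NR"`.
#' @export
classify_architecture <- function(dbds, lbd_detected) {
  stopifnot(is.data.frame(dbds), is.logical(lbd_detected))
  n <- nrow(dbds)
  if (n > 2L) {
    warning("sequence has ", n, " DBDs; classifying as TWO_DBD_NR from the ",
            "first two (MULTI_DBD)", call. = FALSE)
    n <- 2L
  }
  if (n == 0L) {
    if (lbd_detected) "LBD_ONLY" else "NOT_NR"
  } else if (!lbd_detected) {
    "DBD_ONLY"
  } else if (n == 1L) {
    "TYPICAL_NR"
  } else {
    "TWO_DBD_NR"
  }
}

#' Measure the inter-DBD linker
#'
#' Number of residues strictly between two DBDs: `dbd2$start - dbd1$end`.
#' In tandem-DBD receptors this linker is characteristically short
#' (17-22 residues).
#'
#' @param dbd1,dbd2 single-row DBD data.frames, ordered by position.
#' @return non-negative integer.
#' @export
measure_linker <- function(dbd1, dbd2) {
  stopifnot(nrow(dbd1) == 1L, nrow(dbd2) == 1L)
  if (dbd1$end > dbd2$start) stop("DBDs overlap: cannot measure linker",
                                  call. = FALSE)
  as.integer(dbd2$start - dbd1$end)
}

#' Scan the C-terminal extension for the G-box
#'
#' Searches the window following the (second) DBD for the Grip-box, a short
#' minor-groove binding motif with general consensus `RXGRZP` (X one of
#' F/R/G, Z hydrophobic). Group-specific variants are tried before the
#' general consensus when a group hint is given: `RXGRQ(P/S)` for group A,
#' `KXGR(P/H)` for group B (five residues) and the literal `RDRRGP` for the
#' Aphelenchus avenae group-C receptors. The leftmost hit wins.
#'
#' @param residues amino-acid string.
#' @param cte_start 0-based end of the last DBD (start of the CTE).
#' @param group_hint `"A"`, `"B"`, `"C"` or `NULL`.
#' @param window number of residues after `cte_start` in which the match may
#'   start (default 30).
#' @param strict_z if `TRUE` (default) the Z position of the general
#'   consensus is restricted to the hydrophobic class, else any residue.
#' @param patterns named G-box consensus strings, from the config.
#' @return one-row data.frame (`variant`, `start`, `end`, `sequence`,
#'   `pre_grip_len`, `fifth_after`) or `NULL` when nothing matches.
#'   `pre_grip_len` is `start - cte_start`; `fifth_after` is the fifth
#'   residue after the motif (`NA` if the sequence ends first).
#' @export
scan_gbox <- function(residues, cte_start, group_hint = NULL, window = 30L,
                      strict_z = TRUE,
                      patterns = default_config()$gbox) {
  stopifnot(is.character(residues), length(residues) == 1L, cte_start >= 0L)
  if (!strict_z) {
    patterns$GENERAL <- "R[FRG]GRxP"
  }
  order <- names(patterns)
  if (!is.null(group_hint) && is.na(group_hint)) group_hint <- NULL
  if (!is.null(group_hint)) {
    hint_variant <- switch(as.character(group_hint),
                           A = "A_VARIANT", B = "B_VARIANT", C = "C_AAVENAE",
                           NULL)
    if (!is.null(hint_variant))
      order <- c(hint_variant, setdiff("GENERAL", hint_variant))
    else
      order <- "GENERAL"
  } else {
    order <- c("GENERAL", "A_VARIANT", "B_VARIANT", "C_AAVENAE")
  }
  for (variant in order) {
    pat <- patterns[[variant]]
    len <- consensus_length(pat)
    starts <- match_consensus(residues, pat, from = cte_start,
                              to = cte_start + window)
    starts <- starts[starts + len <= nchar(residues)]
    if (length(starts)) {
      s <- min(starts)
      fifth_pos <- s + len + 4L  # 0-based index of 5th residue after the box
      return(data.frame(
        variant = variant, start = s, end = s + len,
        sequence = substr(residues, s + 1L, s + len),
        pre_grip_len = s - cte_start,
        fifth_after = if (fifth_pos < nchar(residues))
          substr(residues, fifth_pos + 1L, fifth_pos + 1L) else NA_character_,
        stringsAsFactors = FALSE))
    }
  }
  NULL
}

#' Is a T-box present before the G-box?
#'
#' The reference T-box (human NGFI-B) spans 12 residues between the DBD and
#' the G-box. A pre-Grip stretch of at least 12 residues is therefore scored
#' as T-box-compatible; tandem-DBD receptors have pre-Grip lengths of 5
#' (groups A/B) or 8 (group C), i.e. no conserved T-box.
#'
#' @param gbox_hit one-row data.frame from [scan_gbox()].
#' @param min_len T-box length threshold (default 12).
#' @return logical.
#' @export
tbox_present <- function(gbox_hit, min_len = 12L) {
  stopifnot(is.data.frame(gbox_hit), nrow(gbox_hit) == 1L)
  gbox_hit$pre_grip_len >= min_len
}

#' Scan the A/B domain for N-terminal signature sequences
#'
#' Matches the three clade-specific NTSS consensus patterns of parasitic
#' platyhelminth tandem-DBD receptors against the region upstream of the
#' first DBD: `CNLGxKDRRP` (trematode A1), `TNDVTAMKEKTP` (cestode A1) and
#' `(S/T)PExAFxQYQxR(M/S)EGQx` (A2/A3). All hits fully contained in
#' `[0, ab_end)` are returned.
#'
#' @param residues amino-acid string.
#' @param ab_end 0-based start of the first DBD.
#' @param patterns named NTSS consensus strings, from the config.
#' @return data.frame with columns `pattern_name`, `start`, `end`,
#'   `sequence` (zero rows if none).
#' @export
scan_ntss <- function(residues, ab_end,
                      patterns = default_config()$ntss) {
  stopifnot(is.character(residues), length(residues) == 1L, ab_end >= 0L)
  rows <- list()
  for (nm in names(patterns)) {
    len <- consensus_length(patterns[[nm]])
    starts <- match_consensus(residues, patterns[[nm]], from = 0L, to = ab_end)
    starts <- starts[starts + len <= ab_end]
    for (s in starts) {
      rows[[length(rows) + 1L]] <- data.frame(
        pattern_name = nm, start = s, end = s + len,
        sequence = substr(residues, s + 1L, s + len),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(pattern_name = character(), start = integer(),
                      end = integer(), sequence = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$start, out$pattern_name), , drop = FALSE]
}
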