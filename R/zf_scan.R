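# C4 zinc-finger scanning and DBD assembly. Coordinates are 0-based,
# half-open throughout: a finger spanning [start, end) has its four anchor
# residues at a1 < a2 < a3 < a4 with end == a4 + 1.

zf_kinds <- c("CI", "CII", "CHC2")

empty_fingers <- function() {
  data.frame(kind = character(), start = integer(), end = integer(),
             a1 = integer(), a2 = integer(), a3 = integer(), a4 = integer(),
             s1 = integer(), s2 = integer(), s3 = integer(),
             stringsAsFactors = FALSE)
}

#' Scan a protein sequence for C4 zinc-finger motifs
#'
#' Finds every occurrence of the exact anchor spacings
#' CI = C-X2-C-X13-C-X2-C, CII = C-X5-C-X9-C-X2-C and
#' CHC2 = C-X6-C-X9-H-X2-C (third anchor histidine). Anchors must be literal
#' `C`/`H`; spacer positions match any residue (including `X`). Overlapping
#' matches of the same kind are all reported.
#'
#' @param residues amino-acid string (one sequence).
#' @param kinds subset of `c("CI", "CII", "CHC2")`.
#' @param tolerant if `TRUE`, additionally allow +/-1 on the long middle
#'   spacer (13 for CI, 9 for CII/CHC2), accommodating the rare divergent
#'   fingers seen outside the canonical geometry. Off by default.
#' @param patterns anchor/spacer definitions, from the config.
#' @return data.frame with one row per finger: `kind`, `start`, `end`
#'   (0-based, half-open), anchor positions `a1`..`a4` and realized spacers
#'   `s1`..`s3`, sorted by `start` then `kind`.
#' @export
#' @examples
#' scan_zinc_fingers("MCAACGGGGGGGGGGGGGCKKCM", kinds = "CI")
scan_zinc_fingers <- function(residues, kinds = c("CI", "CII"),
                              tolerant = FALSE,
                              patterns = default_config()$zinc_fingers) {
  stopifnot(is.character(residues), length(residues) == 1L,
            all(kinds %in% zf_kinds))
  rows <- list()
  for (kind in kinds) {
    def <- patterns[[kind]]
    spacer_sets <- list(def$spacers)
    if (tolerant) {
      for (d in c(-1L, 1L)) {
        sp <- def$spacers
        sp[2] <- sp[2] + d
        spacer_sets[[length(spacer_sets) + 1L]] <- sp
      }
    }
    for (sp in spacer_sets) {
      rx <- paste0("(?=", def$anchors[1],
                   ".{", sp[1], "}", def$anchors[2],
                   ".{", sp[2], "}", def$anchors[3],
                   ".{", sp[3], "}", def$anchors[4], ")")
      m <- gregexpr(rx, residues, perl = TRUE)[[1]]
      if (m[1] == -1L) next
      starts <- as.integer(m) - 1L
      a1 <- starts
      a2 <- a1 + sp[1] + 1L
      a3 <- a2 + sp[2] + 1L
      a4 <- a3 + sp[3] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, start = starts, end = a4 + 1L,
        a1 = a1, a2 = a2, a3 = a3, a4 = a4,
        s1 = sp[1], s2 = sp[2], s3 = sp[3], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_fingers())
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_dbds <- function() {
  data.frame(start = integer(), end = integer(), ordinal = character(),
             p_box = character(), d_box = character(),
             ci_start = integer(), ci_end = integer(),
             ci_a3 = integer(), ci_a4 = integer(),
             cii_start = integer(), cii_end = integer(),
             cii_a1 = integer(), cii_a2 = integer(),
             stringsAsFactors = FALSE)
}

#' Assemble zinc fingers into DNA-binding domains
#'
#' Pairs fingers greedily left to right: each CI is joined to the nearest
#' following unused CII whose start lies within `max_gap` residues of the
#' CI's end. Each finger is used at most once. The DBD spans from the CI
#' start to the CII end; the P-box is the five residues following the CI's
#' third cysteine (so its middle residue is the fourth cysteine) and the
#' D-box is the five residues between the CII's first two cysteines.
#'
#' @param fingers output of [scan_zinc_fingers()] on the same sequence.
#' @param residues the scanned sequence.
#' @param max_gap maximum CII.start - CI.end (default 30).
#' @return data.frame of DBDs (0-based half-open `start`/`end`, `ordinal` in
#'   `FIRST`/`SECOND`/`ONLY`/`EXTRA`, `p_box`, `d_box`, and component finger
#'   coordinates). Unpaired fingers are attached as attribute `"orphans"`.
#' @export
assemble_dbds <- function(fingers, residues, max_gap = 30L) {
  stopifnot(is.data.frame(fingers))
  cis <- fingers[fingers$kind == "CI", , drop = FALSE]
  ciis <- fingers[fingers$kind == "CII", , drop = FALSE]
  used_cii <- rep(FALSE, nrow(ciis))
  rows <- list()
  if (nrow(cis)) cis <- cis[order(cis$start), , drop = FALSE]
  for (i in seq_len(nrow(cis))) {
    ci <- cis[i, ]
    cand <- which(!used_cii & ciis$start >= ci$end &
                    ciis$start - ci$end <= max_gap)
    if (!length(cand)) next
    j <- cand[which.min(ciis$start[cand])]
    used_cii[j] <- TRUE
    cii <- ciis[j, ]
    rows[[length(rows) + 1L]] <- data.frame(
      start = ci$start, end = cii$end, ordinal = NA_character_,
      p_box = extract_box(residues, ci$a3 + 1L, 5L, "P-box"),
      d_box = extract_box(residues, cii$a1 + 1L, 5L, "D-box"),
      ci_start = ci$start, ci_end = ci$end, ci_a3 = ci$a3, ci_a4 = ci$a4,
      cii_start = cii$start, cii_end = cii$end,
      cii_a1 = cii$a1, cii_a2 = cii$a2, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty_dbds()
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$ordinal <- if (nrow(out) == 1L) "ONLY" else
    c("FIRST", "SECOND", rep("EXTRA", max(0L, nrow(out) - 2L)))[seq_len(nrow(out))]
  orphan_ci <- if (nrow(cis)) cis[!cis$start %in% out$ci_start, , drop = FALSE] else cis
  orphan_cii <- ciis[!used_cii, , drop = FALSE]
  attr(out, "orphans") <- rbind(orphan_ci, orphan_cii)
  out
}

# 0-based slice of `len` residues starting at `from0`; errors if truncated.
extract_box <- function(residues, from0, len, what) {
  if (from0 + len > nchar(residues)) {
    stop("partial DBD: sequence ends before the ", what,
         " (needs residues ", from0, "..", from0 + len - 1L, ")",
         call. = FALSE)
  }
  substr(residues, from0 + 1L, from0 + len)
}

#' Extract the P-box or D-box from an assembled DBD
#'
#' The P-box is the five residues following the third cysteine of the first
#' zinc finger (CI); under the canonical CI geometry its third residue is the
#' fourth cysteine. The D-box is the five residues between the first two
#' cysteines of the second zinc finger (C-X5-C).
#'
#' @param dbd one row of the data.frame returned by [assemble_dbds()].
#' @param residues the sequence the DBD was assembled from.
#' @return 5-letter character scalar.
#' @export
extract_pbox <- function(dbd, residues) {
  stopifnot(is.data.frame(dbd), nrow(dbd) == 1L)
  extract_box(residues, dbd$ci_a3 + 1L, 5L, "P-box")
}

#' @rdname extract_pbox
#' @export
extract_dbox <- function(dbd, residues) {
  stopifnot(is.data.frame(dbd), nrow(dbd) == 1L)
  extract_box(residues, dbd$cii_a1 + 1L, 5L, "D-box")
}
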