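# Ligand-binding-domain signatures: the 20-residue Ti motif (LBD detection
# proxy), the C-terminal AF2-AD core, and the class I / class II
# dimerization-residue profile scored on an aligned LBD row.

#' Scan for the 20-residue LBD signature (Ti)
#'
#' The Ti motif lies between helices H3 and H5 of the receptor LBD and is the
#' family-wide LBD-specific signature. Its degenerate consensus is
#' `(F/W/Y)(A/S/I)(K/R/E/G)xxxx(F/L)xx(L/V/I)xxx(D/S)(Q/K)xx(L/V)(L/I/F)`.
#' All matching 20-residue windows starting at or after `search_start` are
#' reported left to right.
#'
#' @param residues amino-acid string.
#' @param search_start 0-based scan origin (end of the last DBD, or 0 for
#'   LBD-only candidates).
#' @param pattern consensus string, from the config.
#' @return data.frame with columns `start`, `end` (= start + 20), `sequence`.
#' @export
#' @examples
#' scan_ti("FAKGGGGFGGLGGGDQGGLL")
scan_ti <- function(residues, search_start = 0L,
                    pattern = default_config()$ti) {
  stopifnot(is.character(residues), length(residues) == 1L,
            search_start >= 0L)
  len <- consensus_length(pattern)
  starts <- match_consensus(residues, pattern, from = search_start)
  starts <- starts[starts + len <= nchar(residues)]
  data.frame(start = starts, end = starts + len,
             sequence = substr(rep(residues, length(starts)),
                               starts + 1L, starts + len),
             stringsAsFactors = FALSE)
}

#' Detect an LBD by the presence of a Ti signature
#'
#' The Ti motif is the only computable LBD-wide signature in this grammar, so
#' LBD presence is operationalized as "at least one Ti hit downstream of the
#' last DBD". The AF2-AD core is deliberately not required: group-C
#' receptors of Aphelenchus avenae carry a Ti but no AF2.
#'
#' @inheritParams scan_ti
#' @return logical.
#' @export
detect_lbd <- function(residues, search_start = 0L,
                       pattern = default_config()$ti) {
  nrow(scan_ti(residues, search_start, pattern)) > 0L
}

#' Locate the AF2-AD core
#'
#' The AF2 activation-function core sits at the C-terminus of the LBD with
#' general consensus Phi-Phi-x-E-Phi-Phi (Phi hydrophobic). Group variants:
#' `PhiPhix(E/Q/R)PhiPhi` (A), `PhiPhix(E/K)Phi-h` with h hydrophilic (B),
#' and `xxPhiPhiPhiPhi` (Caenorhabditis brenneri group C). When a group hint
#' is given its variant is tried first, falling back to the general
#' consensus. Because the motif is C-terminal, ties are resolved by taking
#' the hit nearest the C-terminus.
#'
#' @param residues amino-acid string.
#' @param from_pos 0-based scan origin.
#' @param group_hint `"A"`, `"B"`, `"C"` or `NULL`.
#' @param patterns named AF2 consensus strings, from the config.
#' @return one-row data.frame (`variant`, `start`, `end`, `sequence`) or
#'   `NULL` when nothing matches.
#' @export
scan_af2 <- function(residues, from_pos = 0L, group_hint = NULL,
                     patterns = default_config()$af2) {
  stopifnot(is.character(residues), length(residues) == 1L,
            from_pos <= nchar(residues))
  order <- "GENERAL"
  if (!is.null(group_hint) && is.na(group_hint)) group_hint <- NULL
  if (!is.null(group_hint)) {
    hint_variant <- switch(as.character(group_hint),
                           A = "A", B = "B", C = "C_CBRENNERI", NULL)
    if (!is.null(hint_variant)) order <- c(hint_variant, "GENERAL")
  }
  for (variant in unique(order)) {
    pat <- patterns[[variant]]
    len <- consensus_length(pat)
    starts <- match_consensus(residues, pat, from = from_pos)
    starts <- starts[starts + len <= nchar(residues)]
    if (length(starts)) {
      s <- max(starts)  # nearest the C-terminus
      return(data.frame(variant = variant, start = s, end = s + len,
                        sequence = substr(residues, s + 1L, s + len),
                        stringsAsFactors = FALSE))
    }
  }
  NULL
}

dimer_marker_sets <- function() {
  list(E5 = "E", ED42 = c("E", "D"), E50 = "E", KR55 = c("K", "R"),
       R62 = "R", HRK90 = c("H", "R", "K"), RK93 = c("R", "K"))
}

#' Score class I / class II dimerization residues on an aligned LBD row
#'
#' Receptor LBDs fall into two dimerization classes defined by conserved
#' salt-bridge residues (numbering after the reference LBD alignment with
#' variable inserts deleted): class I carries E5, E50, KR55 and RK93 and
#' homodimerizes; class II carries ED42, E50, R62 and HRK90 and
#' heterodimerizes with RXR. RK93 is strictly conserved in class I and R62
#' in class II, so the call uses those discriminators: `CLASS_I` if RK93 is
#' present and R62 absent, `CLASS_II` for the converse, `AMBIGUOUS` if both,
#' `NONE` if neither. Tandem-DBD receptors type as class I through E50 +
#' RK93 even though they lack KR55.
#'
#' @param aligned_lbd_row one row of an LBD alignment (gaps `-`).
#' @param column_map named integer vector mapping the marker labels `E5`,
#'   `ED42`, `E50`, `KR55`, `R62`, `HRK90`, `RK93` to 0-based alignment
#'   columns. The reference columns depend on the alignment, so the map is
#'   supplied by the caller; [default_config()] ships one for the synthetic
#'   generator's LBD layout.
#' @return list with `markers` (named logical vector of marker presence) and
#'   `call` (`"CLASS_I"`, `"CLASS_II"`, `"AMBIGUOUS"` or `"NONE"`).
#' @export
dimer_class_profile <- function(aligned_lbd_row, column_map) {
  stopifnot(is.character(aligned_lbd_row), length(aligned_lbd_row) == 1L)
  sets <- dimer_marker_sets()
  missing <- setdiff(names(sets), names(column_map))
  if (length(missing)) {
    stop("column_map lacks marker column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  n <- nchar(aligned_lbd_row)
  markers <- vapply(names(sets), function(lab) {
    col <- as.integer(column_map[[lab]])
    if (col >= n) stop("column ", col, " for marker ", lab,
                       " is beyond the aligned row (length ", n, ")",
                       call. = FALSE)
    substr(aligned_lbd_row, col + 1L, col + 1L) %in% sets[[lab]]
  }, logical(1))
  call <- if (markers[["RK93"]] && !markers[["R62"]]) "CLASS_I"
  else if (markers[["R62"]] && !markers[["RK93"]]) "CLASS_II"
  else if (markers[["RK93"]] && markers[["R62"]]) "AMBIGUOUS"
  else "NONE"
  list(markers = markers, call = call)
}
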