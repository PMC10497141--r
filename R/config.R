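# Motif constants and tunable thresholds, bundled into a single config list so
# that divergent sequences can be accommodated by editing a YAML file rather
# than code. Scanners take their patterns/thresholds as arguments defaulting
# to these values.

#' Amino-acid alphabets and physicochemical residue classes
#'
#' The twenty standard residues partition into three side-chain classes:
#' hydrophilic (RKDENQ), neutral (SGHTAP) and hydrophobic (YVMCLFIW). The
#' classes drive the degenerate positions of the G-box ("Z" hydrophobic), the
#' AF2-AD core (Phi hydrophobic, h hydrophilic) and related consensus motifs.
#'
#' @return `residue_classes()` returns a list with character-vector elements
#'   `hydrophilic`, `neutral`, `hydrophobic`; `aa_alphabet()` returns the 20
#'   standard one-letter codes.
#' @export
#' @examples
#' sort(unlist(residue_classes())) # partitions the 20-letter alphabet
residue_classes <- function() {
  list(
    hydrophilic = c("R", "K", "D", "E", "N", "Q"),
    neutral     = c("S", "G", "H", "T", "A", "P"),
    hydrophobic = c("Y", "V", "M", "C", "L", "F", "I", "W")
  )
}

#' @rdname residue_classes
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

# Residues allowed on input: the 20 standard letters plus ambiguity 'X'.
aa_input_alphabet <- function() c(aa_alphabet(), "X")

#' Default configuration for the annotation pipeline
#'
#' Collects every motif signature and scanner tolerance in one editable list:
#' zinc-finger spacer patterns, P-P module group signatures, G-box variants,
#' NTSS patterns, Ti and AF2 consensus patterns, class I/II marker residue
#' sets, alignment parameters, and the default alignment column map used for
#' synthetic LBD rows.
#'
#' Degenerate consensus patterns are written in a compact string form: a bare
#' letter is a literal residue, `x` matches any residue, and `[KR]` matches
#' one residue from the bracketed set. An input `X` only ever matches `x`
#' positions.
#'
#' @param path optional YAML file whose entries override the defaults
#'   (top-level names are merged shallowly; nested lists are replaced).
#' @return a nested list of class `nr2dbd_config`.
#' @export
#' @examples
#' cfg <- default_config()
#' names(cfg)
default_config <- function() {
  rc <- residue_classes()
  phi <- paste0(rc$hydrophobic, collapse = "")
  hyd <- paste0(rc$hydrophilic, collapse = "")
  cfg <- list(
    zinc_fingers = list(
      CI   = list(anchors = c("C", "C", "C", "C"), spacers = c(2, 13, 2)),
      CII  = list(anchors = c("C", "C", "C", "C"), spacers = c(5, 9, 2)),
      CHC2 = list(anchors = c("C", "C", "H", "C"), spacers = c(6, 9, 2))
    ),
    # +/-1 on the long CI/CII spacers, off by default
    spacer_tolerance = FALSE,
    max_inter_finger_gap = 30,
    pp_signatures = list(
      A = c("CEACKK-CEGCKG", "CEACKK-CEACKG"),
      B = c("CLPCKS-CEGCKK", "CEACKS-CEGCKG")
    ),
    max_mismatch = 1,
    gbox = list(
      GENERAL   = paste0("R[FRG]GR[", phi, "]P"),
      A_VARIANT = "R[FRG]GRQ[PS]",
      B_VARIANT = "K[FRG]GR[PH]",
      C_AAVENAE = "RDRRGP"
    ),
    gbox_strict_z = TRUE,
    cte_window = 30,
    tbox_min_len = 12,
    ntss = list(
      TREMATODE_A1 = "CNLGxKDRRP",
      CESTODE_A1   = "TNDVTAMKEKTP",
      A2_A3        = "[ST]PExAFxQYQxR[MS]EGQx"
    ),
    ti = "[FWY][ASI][KREG]xxxx[FL]xx[LVI]xxx[DS][QK]xx[LV][LIF]",
    af2 = list(
      GENERAL     = paste0("[", phi, "][", phi, "]xE[", phi, "][", phi, "]"),
      A           = paste0("[", phi, "][", phi, "]x[EQR][", phi, "][", phi, "]"),
      B           = paste0("[", phi, "][", phi, "]x[EK][", phi, "][", hyd, "]"),
      C_CBRENNERI = paste0("xx[", phi, "][", phi, "][", phi, "][", phi, "]")
    ),
    class_markers = list(
      class_I  = list(E5 = "E", E50 = "E", KR55 = c("K", "R"), RK93 = c("R", "K")),
      class_II = list(ED42 = c("E", "D"), E50 = "E", R62 = "R",
                      HRK90 = c("H", "R", "K"))
    ),
    # default column map for synthetic LBD rows (0-based offsets from LBD
    # start); real alignments need a user-supplied map
    column_map = c(E5 = 4, ED42 = 41, E50 = 49, KR55 = 54, R62 = 61,
                   HRK90 = 89, RK93 = 92),
    alignment = list(substitution_matrix = "BLOSUM62",
                     gap_open = 10, gap_extend = 1)
  )
  class(cfg) <- c("nr2dbd_config", "list")
  cfg
}

#' @rdname default_config
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (nm in names(user)) cfg[[nm]] <- user[[nm]]
  # YAML reads the column map as a list; coerce back
  if (is.list(cfg$column_map)) cfg$column_map <- unlist(cfg$column_map)
  class(cfg) <- c("nr2dbd_config", "list")
  cfg
}

#' @rdname default_config
#' @param config a config list to serialize.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$column_map <- as.list(x$column_map)
  yaml::write_yaml(x, path)
  invisible(path)
}

# ---- degenerate consensus mini-language ------------------------------------

# Parse "C[KR]xx[FL]" into a list of per-position allowed character vectors
# (NULL = any residue). Validated against the one-letter alphabet.
parse_consensus <- function(pattern) {
  chars <- strsplit(pattern, "", fixed = TRUE)[[1]]
  out <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      out[length(out) + 1L] <- list(NULL)  # NULL = any residue
      i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      set <- character()
      while (j <= length(chars) && chars[j] != "]") {
        set <- c(set, chars[j])
        j <- j + 1L
      }
      if (j > length(chars)) stop("unterminated '[' in consensus: ", pattern)
      out[[length(out) + 1L]] <- set
      i <- j + 1L
    } else {
      if (!ch %in% aa_alphabet())
        stop("invalid consensus character '", ch, "' in: ", pattern)
      out[[length(out) + 1L]] <- ch
      i <- i + 1L
    }
  }
  out
}

consensus_length <- function(pattern) length(parse_consensus(pattern))

# Translate a parsed consensus into a PCRE fragment. Fixed positions are
# literal classes (so an input 'X' never satisfies them); 'x' positions match
# any residue including 'X'.
consensus_regex <- function(pattern) {
  pos <- parse_consensus(pattern)
  paste(vapply(pos, function(p) {
    if (is.null(p)) "." else paste0("[", paste0(p, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# All 0-based match starts of a degenerate consensus within residues,
# overlapping matches included. from/to bound the match START (half-open).
match_consensus <- function(residues, pattern, from = 0L,
                            to = nchar(residues)) {
  rx <- paste0("(?=", consensus_regex(pattern), ")")
  m <- gregexpr(rx, residues, perl = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  starts <- as.integer(m) - 1L
  starts[starts >= from & starts < to]
}
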