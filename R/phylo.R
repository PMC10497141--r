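# Distance-based corroboration of group assignments: pairwise global
# alignment of concatenated DBD regions, a p-distance matrix, and a
# neighbor-joining tree. This is a desk-scale sanity check on the rule-based
# classifier, not publication phylogenetics.

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Pairwise global alignment of two protein sequences
#'
#' Optimal global (Needleman-Wunsch) alignment under an affine gap penalty:
#' a gap of length L costs `gap_open + L * gap_extend`. Defaults: BLOSUM62,
#' gap open 10, gap extend 1.
#'
#' @param a,b non-empty amino-acid strings.
#' @param substitution_matrix a scoring matrix or the name of one shipped
#'   with Biostrings (default `"BLOSUM62"`).
#' @param gap_open,gap_extend non-negative gap penalties.
#' @return list with `score`, `aligned_a`, `aligned_b` (gapped strings) and
#'   `identity` (matching residue pairs / alignment columns).
#' @export
#' @examples
#' pairwise_align("ACDE", "ACDE")$identity
pairwise_align <- function(a, b, substitution_matrix = "BLOSUM62",
                           gap_open = 10, gap_extend = 1) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) stop("cannot align an empty sequence",
                                     call. = FALSE)
  if (is.character(substitution_matrix) &&
      identical(substitution_matrix, "BLOSUM62")) {
    substitution_matrix <- blosum62()
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = substitution_matrix,
    gapOpening = gap_open, gapExtension = gap_extend, type = "global")
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  ca <- strsplit(al_a, "")[[1]]
  cb <- strsplit(al_b, "")[[1]]
  cols <- !(ca == "-" & cb == "-")  # pairwise: no double gaps, kept for form
  identity <- sum(ca == cb & ca != "-") / sum(cols)
  list(score = Biostrings::score(pa), aligned_a = al_a, aligned_b = al_b,
       identity = identity)
}

#' Distance matrix over concatenated DBD regions
#'
#' For each sequence the two DBD spans are detected
#' ([scan_zinc_fingers()] + [assemble_dbds()]), concatenated
#' (first DBD then second), globally aligned pairwise, and converted to a
#' p-distance `1 - fraction identity`.
#'
#' @param records data.frame with columns `id` and `residues` (as from
#'   [read_fasta()]); every record must contain two detectable DBDs.
#' @param config configuration list, see [default_config()].
#' @return symmetric numeric matrix with zero diagonal, labelled by `id`.
#' @export
dbd_distance_matrix <- function(records, config = default_config()) {
  stopifnot(is.data.frame(records),
            all(c("id", "residues") %in% names(records)))
  spans <- character(nrow(records))
  bad <- character()
  for (i in seq_len(nrow(records))) {
    fg <- scan_zinc_fingers(records$residues[i],
                            tolerant = isTRUE(config$spacer_tolerance),
                            patterns = config$zinc_fingers)
    dbds <- assemble_dbds(fg, records$residues[i],
                          max_gap = config$max_inter_finger_gap)
    if (nrow(dbds) < 2L) {
      bad <- c(bad, records$id[i])
      next
    }
    spans[i] <- paste0(
      substr(records$residues[i], dbds$start[1] + 1L, dbds$end[1]),
      substr(records$residues[i], dbds$start[2] + 1L, dbds$end[2]))
  }
  if (length(bad)) {
    stop("record(s) lack two detectable DBDs: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- nrow(records)
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  al <- config$alignment
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      pid <- pairwise_align(spans[i], spans[j],
                            substitution_matrix = al$substitution_matrix,
                            gap_open = al$gap_open,
                            gap_extend = al$gap_extend)$identity
      d[i, j] <- d[j, i] <- 1 - pid
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration (consistent on additive
#' matrices). Negative branch lengths, which NJ can produce on non-additive
#' input, are clamped to zero with a message.
#'
#' @param dm symmetric labelled distance matrix with at least 3 taxa.
#' @return an unrooted `phylo` tree (see [ape::nj()]); write it with
#'   [ape::write.tree()].
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 taxa",
                          call. = FALSE)
  tree <- ape::nj(dm)
  neg <- tree$edge.length < 0
  if (any(neg)) {
    message("nj_tree: clamping ", sum(neg),
            " negative branch length(s) to 0")
    tree$edge.length[neg] <- 0
  }
  tree
}
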