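# Independent brute-force oracles used to cross-check the scanners and the
# aligner. These deliberately avoid regular expressions and dynamic
# programming: fingers and Ti are checked position by position at every
# window, and alignments are enumerated exhaustively.

# Character-by-character C4 finger matcher. Returns 0-based starts.
bf_scan_fingers <- function(residues, kind) {
  spec <- switch(kind,
                 CI   = list(anchors = c("C", "C", "C", "C"),
                             spacers = c(2, 13, 2)),
                 CII  = list(anchors = c("C", "C", "C", "C"),
                             spacers = c(5, 9, 2)),
                 CHC2 = list(anchors = c("C", "C", "H", "C"),
                             spacers = c(6, 9, 2)))
  chars <- strsplit(residues, "")[[1]]
  len <- 4 + sum(spec$spacers)
  hits <- integer(0)
  for (s in seq_len(max(0, length(chars) - len + 1))) {
    pos <- s
    ok <- TRUE
    for (k in 1:4) {
      if (chars[pos] != spec$anchors[k]) { ok <- FALSE; break }
      if (k < 4) pos <- pos + spec$spacers[k] + 1
    }
    if (ok) hits <- c(hits, s - 1L)
  }
  hits
}

# Position-wise Ti matcher over every 20-residue window (0-based starts).
bf_scan_ti <- function(residues, from = 0L) {
  allowed <- list(c("F", "W", "Y"), c("A", "S", "I"), c("K", "R", "E", "G"),
                  NULL, NULL, NULL, NULL, c("F", "L"), NULL, NULL,
                  c("L", "V", "I"), NULL, NULL, NULL, c("D", "S"),
                  c("Q", "K"), NULL, NULL, c("L", "V"), c("L", "I", "F"))
  chars <- strsplit(residues, "")[[1]]
  hits <- integer(0)
  for (s in seq_len(max(0, length(chars) - 19))) {
    if (s - 1L < from) next
    ok <- TRUE
    for (k in 1:20) {
      a <- allowed[[k]]
      if (!is.null(a) && !chars[s + k - 1] %in% a) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, s - 1L)
  }
  hits
}

# Exhaustive optimal global alignment score under affine gaps (gap of
# length L costs open + L * ext). Enumerates every alignment; feasible for
# sequences of length <= 6.
bf_align_score <- function(a, b, sub, open = 10, ext = 1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  score_alignment <- function(ops) {
    i <- 0L; j <- 0L; sc <- 0
    runs <- rle(ops)
    for (r in seq_along(runs$values)) {
      op <- runs$values[r]; n <- runs$lengths[r]
      if (op == "M") {
        for (k in seq_len(n)) sc <- sc + sub[ca[i + k], cb[j + k]]
        i <- i + n; j <- j + n
      } else {
        sc <- sc - (open + ext * n)
        if (op == "D") i <- i + n else j <- j + n
      }
    }
    sc
  }
  best <- -Inf
  recurse <- function(i, j, ops) {
    if (i == length(ca) && j == length(cb)) {
      best <<- max(best, score_alignment(ops))
      return(invisible())
    }
    if (i < length(ca) && j < length(cb)) recurse(i + 1, j + 1, c(ops, "M"))
    if (i < length(ca)) recurse(i + 1, j, c(ops, "D"))
    if (j < length(cb)) recurse(i, j + 1, c(ops, "I"))
  }
  recurse(0L, 0L, character(0))
  best
}

blosum62_test <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# Random sequence; c_rich boosts cysteine frequency so finger-shaped
# patterns actually occur at testable rates.
random_seq <- function(n, c_rich = FALSE) {
  ab <- aa_alphabet()
  prob <- rep(1, length(ab))
  if (c_rich) prob[ab == "C"] <- 8
  paste0(sample(ab, n, replace = TRUE, prob = prob), collapse = "")
}

# Panel for clade-recovery tests: one base sequence per group, with copies
# derived by substituting a few neutral residues inside the DBD spans
# (neutral-for-neutral swaps can never create or destroy an anchor), so
# within-group distances are small and the A/B split is identifiable.
make_group_tree_panel <- function(seed, n_per_group = 4, n_mut = 6) {
  set.seed(seed)
  base <- list(
    A = make_sequence(synth_params()),
    B = make_sequence(synth_params(group = "B", pbox1 = "LPCKS",
                                   pbox2 = "EGCKK")))
  neutral <- c("S", "G", "T", "A", "P")
  recs <- list()
  for (g in names(base)) {
    t <- base[[g]]$truth
    s0 <- base[[g]]$record$residues
    span <- (t$dbd1_start + 1):t$dbd2_end  # 1-based DBD region
    for (i in seq_len(n_per_group)) {
      chars <- strsplit(s0, "")[[1]]
      targets <- sample(span[chars[span] %in% neutral], n_mut)
      for (p in targets) chars[p] <- sample(setdiff(neutral, chars[p]), 1)
      recs[[length(recs) + 1]] <- data.frame(
        id = paste0(g, i), description = "synthetic",
        residues = paste0(chars, collapse = ""),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, recs)
}

# TRUE iff the A-leaves/B-leaves bipartition occurs in the tree.
has_ab_split <- function(tree, a_leaves, b_leaves) {
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  sets <- lapply(parts, function(p) sort(labs[p]))
  any(vapply(sets, identical, logical(1), sort(a_leaves))) ||
    any(vapply(sets, identical, logical(1), sort(b_leaves)))
}
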