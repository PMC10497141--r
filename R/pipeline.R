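# End-to-end annotation: scan each sequence with every detector and emit one
# report row per record. The command-line wrapper in inst/cli/nr2dbd is a
# thin shell over these functions.

#' Annotate protein sequences with the tandem-DBD receptor motif grammar
#'
#' For each record: scans CI/CII zinc fingers, assembles DBDs, detects the
#' LBD via the Ti signature, classifies the modular architecture, and — for
#' two-DBD receptors — measures the inter-DBD linker, builds the P-P module,
#' assigns group A/B/C, scans the C-terminal extension for the G-box
#' (pre-Grip length, T-box call), scans the A/B domain for NTSS hits, and
#' locates the AF2-AD core. If `lbd_rows` and a column map are supplied the
#' class I/II dimerization profile is scored as well.
#'
#' @param records data.frame with columns `id` and `residues` (see
#'   [read_fasta()]).
#' @param config configuration list, see [default_config()].
#' @param nematoda taxon gate for group C: a logical scalar, a named logical
#'   vector (by `id`), or an unnamed logical vector aligned with `records`.
#' @param lbd_rows optional named character vector (by `id`) of aligned LBD
#'   rows for [dimer_class_profile()]; scored with `config$column_map`.
#' @return data.frame with one row per record. The leading columns follow
#'   the fixed report order (see [write_report()]); extra columns
#'   (`gbox_variant`, `af2_variant`, `group_distance`, `multi_dbd`,
#'   `ti_start`) carry detail used by round-trip tests. Spans are rendered
#'   `"start-end"`, 0-based half-open.
#' @export
#' @examples
#' panel <- make_panel(1, seed = 7)
#' rep <- annotate_sequences(panel$records)
#' table(rep$architecture)
annotate_sequences <- function(records, config = default_config(),
                               nematoda = FALSE, lbd_rows = NULL) {
  stopifnot(is.data.frame(records),
            all(c("id", "residues") %in% names(records)))
  if (nrow(records) == 0L) {
    tmpl <- annotate_one("x", "A", default_config())[0, , drop = FALSE]
    return(tmpl)
  }
  rows <- lapply(seq_len(nrow(records)), function(i) {
    gate <- if (!is.null(names(nematoda))) {
      isTRUE(unname(nematoda[records$id[i]]))
    } else if (length(nematoda) == nrow(records)) {
      isTRUE(nematoda[i])
    } else isTRUE(nematoda)
    lrow <- if (!is.null(lbd_rows)) unname(lbd_rows[records$id[i]]) else NULL
    annotate_one(records$id[i], records$residues[i], config, gate, lrow)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

annotate_one <- function(id, residues, config, nematoda = FALSE,
                         lbd_row = NULL) {
  validate_residues(residues, id)
  fingers <- scan_zinc_fingers(residues, kinds = c("CI", "CII"),
                               tolerant = isTRUE(config$spacer_tolerance),
                               patterns = config$zinc_fingers)
  dbds <- assemble_dbds(fingers, residues,
                        max_gap = config$max_inter_finger_gap)
  n_dbds <- nrow(dbds)
  multi <- n_dbds > 2L
  lbd_from <- if (n_dbds > 0L) max(dbds$end) else 0L
  lbd <- detect_lbd(residues, lbd_from, pattern = config$ti)
  arch <- classify_architecture(dbds, lbd)  # warns on >2 DBDs

  rep <- list(seq_id = id, architecture = arch, n_dbds = n_dbds,
              linker_len = NA_integer_, pbox1 = NA_character_,
              dbox1 = NA_character_, pbox2 = NA_character_,
              dbox2 = NA_character_, pp_module = NA_character_,
              group = NA_character_, gbox = NA_character_,
              pre_grip_len = NA_integer_, tbox_present = NA,
              ti_span = NA_character_, af2 = NA_character_,
              ntss = NA_character_, nr_class = NA_character_,
              gbox_variant = NA_character_, af2_variant = NA_character_,
              group_distance = NA_integer_, multi_dbd = multi,
              ti_start = NA_integer_)

  group_hint <- NULL
  if (n_dbds >= 1L) {
    rep$pbox1 <- dbds$p_box[1]
    rep$dbox1 <- dbds$d_box[1]
  }
  if (n_dbds >= 2L) {
    d1 <- dbds[1, ]
    d2 <- dbds[2, ]
    rep$pbox2 <- d2$p_box
    rep$dbox2 <- d2$d_box
    rep$linker_len <- measure_linker(d1, d2)
    ppm <- pp_module(dbds)
    rep$pp_module <- ppm$rendered
    call <- assign_group(ppm, max_mismatch = config$max_mismatch,
                         nematoda = nematoda,
                         signatures = config$pp_signatures)
    rep$group <- call$group
    rep$group_distance <- call$distance
    if (call$group %in% c("A", "B", "C")) group_hint <- call$group
  }

  if (n_dbds >= 1L) {
    cte_start <- if (n_dbds >= 2L) dbds$end[2] else dbds$end[1]
    gb <- scan_gbox(residues, cte_start, group_hint = group_hint,
                    window = config$cte_window,
                    strict_z = isTRUE(config$gbox_strict_z),
                    patterns = config$gbox)
    if (!is.null(gb)) {
      rep$gbox <- gb$sequence
      rep$gbox_variant <- gb$variant
      rep$pre_grip_len <- gb$pre_grip_len
      rep$tbox_present <- tbox_present(gb, min_len = config$tbox_min_len)
    }
    ntss <- scan_ntss(residues, ab_end = dbds$start[1],
                      patterns = config$ntss)
    if (nrow(ntss)) {
      rep$ntss <- paste(sprintf("%s@%d", ntss$pattern_name, ntss$start),
                        collapse = ";")
    }
  }

  if (lbd) {
    ti <- scan_ti(residues, lbd_from, pattern = config$ti)
    rep$ti_span <- sprintf("%d-%d", ti$start[1], ti$end[1])
    rep$ti_start <- ti$start[1]
    af2 <- scan_af2(residues, from_pos = ti$end[1],
                    group_hint = group_hint, patterns = config$af2)
    if (!is.null(af2)) {
      rep$af2 <- af2$sequence
      rep$af2_variant <- af2$variant
    }
  }

  if (!is.null(lbd_row) && !is.na(lbd_row)) {
    rep$nr_class <- dimer_class_profile(lbd_row, config$column_map)$call
  }

  as.data.frame(rep, stringsAsFactors = FALSE)
}

#' Run the scan pipeline over a FASTA file
#'
#' Reads `fasta_in`, annotates every record and writes the report. A summary
#' line (count per architecture class) goes to standard error. Finding zero
#' tandem-DBD receptors is not an error.
#'
#' @param fasta_in input FASTA path.
#' @param out_tsv,out_json optional output paths.
#' @inheritParams annotate_sequences
#' @return the report data.frame, invisibly.
#' @export
scan_fasta <- function(fasta_in, config = default_config(),
                       out_tsv = NULL, out_json = NULL, nematoda = FALSE) {
  records <- read_fasta(fasta_in)
  rep <- annotate_sequences(records, config, nematoda = nematoda)
  counts <- table(factor(rep$architecture, levels = architecture_levels()))
  message("scanned ", nrow(rep), " sequence(s): ",
          paste(sprintf("%s=%d", names(counts), counts), collapse = " "))
  if (!is.null(out_tsv)) write_report(rep, out_tsv, "tsv")
  if (!is.null(out_json)) write_report(rep, out_json, "json")
  invisible(rep)
}

#' Name classified records from a scan report
#'
#' Applies the nomenclature to every record with a group call: within each
#' (species, group) stratum, genes are numbered by subgroup identity in
#' report order (or in the leaf order of `tree` when given) and variants get
#' lowercase letters. Records with group `UNCLASSIFIED` or no group are
#' returned in the `skipped` component rather than failing the run.
#'
#' @param report data.frame from [annotate_sequences()].
#' @param species_codes named character vector mapping `seq_id` to a 1-4
#'   letter species prefix.
#' @param subgroups optional named character vector mapping `seq_id` to a
#'   subgroup identity; defaults to the P-P module string, so sequences with
#'   identical modules become variants of one gene.
#' @param tree optional `phylo` object whose tip order overrides report
#'   order.
#' @return list with `names` (data.frame: `seq_id`, `name`) and `skipped`
#'   (character vector of unclassifiable ids).
#' @export
name_records <- function(report, species_codes, subgroups = NULL,
                         tree = NULL) {
  stopifnot(is.data.frame(report), !is.null(names(species_codes)))
  ok <- !is.na(report$group) & report$group %in% c("A", "B", "C")
  skipped <- report$seq_id[!ok]
  rep <- report[ok, , drop = FALSE]
  if (!is.null(tree)) {
    ord <- match(tree$tip.label, rep$seq_id)
    ord <- c(ord[!is.na(ord)], setdiff(seq_len(nrow(rep)), ord))
    rep <- rep[ord, , drop = FALSE]
  }
  sg <- if (!is.null(subgroups)) unname(subgroups[rep$seq_id]) else
    rep$pp_module
  code <- unname(species_codes[rep$seq_id])
  if (anyNA(code)) {
    stop("no species code for: ",
         paste(rep$seq_id[is.na(code)], collapse = ", "), call. = FALSE)
  }
  out <- list()
  for (stratum in unique(paste(code, rep$group))) {
    idx <- which(paste(code, rep$group) == stratum)
    num <- number_genes(sg[idx], members = rep$seq_id[idx])
    for (k in seq_along(idx)) {
      i <- idx[k]
      nm <- assign_name(code[i], rep$group[i], num$gene_number[k],
                        variant_letter = num$variant_letter[k])
      out[[length(out) + 1L]] <- data.frame(seq_id = rep$seq_id[i],
                                            name = nm$rendered,
                                            stringsAsFactors = FALSE)
    }
  }
  names_df <- if (length(out)) do.call(rbind, out) else
    data.frame(seq_id = character(), name = character(),
               stringsAsFactors = FALSE)
  list(names = names_df, skipped = skipped)
}

#' Build a neighbor-joining tree from a FASTA of two-DBD receptors
#'
#' Convenience wrapper: [read_fasta()] + [dbd_distance_matrix()] +
#' [nj_tree()], optionally writing newick.
#'
#' @param fasta_in input FASTA path; every record needs two detectable DBDs
#'   and at least three records are required.
#' @param out_newick optional output path.
#' @inheritParams annotate_sequences
#' @return the `phylo` tree, invisibly.
#' @export
tree_fasta <- function(fasta_in, config = default_config(),
                       out_newick = NULL) {
  records <- read_fasta(fasta_in)
  dm <- dbd_distance_matrix(records, config)
  tree <- nj_tree(dm)
  if (!is.null(out_newick)) ape::write.tree(tree, out_newick)
  invisible(tree)
}
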