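# P-P module assembly, group assignment from the paired P-box signature, and
# rule-based nomenclature.

#' Build the P-P module of a tandem-DBD receptor
#'
#' The P-P module is the ordered pair of P-boxes from the first and second
#' DBD, rendered with the preceding anchor cysteines restored
#' (e.g. `"CEACKK-CEGCKG"`). It is the group-diagnostic signature of the
#' tandem-DBD receptor family.
#'
#' @param dbds data.frame from [assemble_dbds()] with at least two rows
#'   (the first two, in sequence order, are used).
#' @return list with `first`, `second` (5-letter P-boxes) and `rendered`
#'   (13-character display string).
#' @export
pp_module <- function(dbds) {
  stopifnot(is.data.frame(dbds))
  if (nrow(dbds) < 2L) stop("P-P module requires two DBDs; got ", nrow(dbds),
                            call. = FALSE)
  first <- dbds$p_box[1]
  second <- dbds$p_box[2]
  list(first = first, second = second,
       rendered = paste0("C", first, "-C", second))
}

pp_boxes <- function(rendered) {
  # "CEACKK-CEGCKG" -> c("EACKK", "EGCKG")
  if (nchar(rendered) != 13L || substr(rendered, 7, 7) != "-")
    stop("malformed P-P module string: ", rendered, call. = FALSE)
  c(substr(rendered, 2, 6), substr(rendered, 9, 13))
}

# Hamming distance between two P-P modules over the 10 P-box positions
# (the invariant anchor cysteines contribute zero).
pp_distance <- function(a, b) {
  pa <- strsplit(paste0(pp_boxes(a), collapse = ""), "")[[1]]
  pb <- strsplit(paste0(pp_boxes(b), collapse = ""), "")[[1]]
  sum(pa != pb)
}

#' Assign a tandem-DBD receptor to group A, B or C from its P-P module
#'
#' Exact matches to the four diagnostic signatures
#' (`CEACKK-CEGCKG`, `CEACKK-CEACKG` for group A; `CLPCKS-CEGCKK`,
#' `CEACKS-CEGCKG` for group B) classify directly with distance 0.
#' Otherwise the nearest signature by Hamming distance over the ten P-box
#' positions wins if it is within `max_mismatch`; a tie between signatures
#' leaves the sequence `UNCLASSIFIED`. Beyond the tolerance, sequences
#' flagged as Nematoda fall into group C (whose P-P module is highly
#' variable and defined phylogenetically, not by signature); everything
#' else is `UNCLASSIFIED`.
#'
#' @param ppm list from [pp_module()] or a rendered string.
#' @param max_mismatch mismatch tolerance for nearest-signature fallback
#'   (default 1).
#' @param nematoda logical; is the sequence from a nematode?
#' @param signatures group signature table, from the config.
#' @return list with `group` (`"A"`, `"B"`, `"C"` or `"UNCLASSIFIED"`),
#'   `matched_signature` (or `NA`) and `distance` (mismatches to the nearest
#'   signature).
#' @export
#' @examples
#' assign_group("CEACKK-CEGCKG")
assign_group <- function(ppm, max_mismatch = 1L, nematoda = FALSE,
                         signatures = default_config()$pp_signatures) {
  rendered <- if (is.list(ppm)) ppm$rendered else ppm
  stopifnot(is.character(rendered), length(rendered) == 1L)
  sig_tab <- data.frame(
    group = rep(names(signatures), lengths(signatures)),
    signature = unlist(signatures, use.names = FALSE),
    stringsAsFactors = FALSE)
  sig_tab$distance <- vapply(sig_tab$signature, pp_distance, numeric(1),
                             a = rendered)
  dmin <- min(sig_tab$distance)
  nearest <- sig_tab[sig_tab$distance == dmin, , drop = FALSE]
  if (dmin <= max_mismatch && nrow(nearest) == 1L) {
    return(list(group = nearest$group, matched_signature = nearest$signature,
                distance = as.integer(dmin)))
  }
  if (dmin <= max_mismatch && nrow(nearest) > 1L) {
    return(list(group = "UNCLASSIFIED", matched_signature = NA_character_,
                distance = as.integer(dmin)))
  }
  list(group = if (nematoda) "C" else "UNCLASSIFIED",
       matched_signature = NA_character_, distance = as.integer(dmin))
}

#' Construct a nomenclature name
#'
#' Renders names of the form
#' `<species code>2DBD-NR<group letter><gene number><variant letter>`, e.g.
#' `"Bc2DBD-NRA1a"`: groups are capital letters, individual genes Arabic
#' numerals, and gene variants a trailing lowercase letter.
#'
#' @param species_code 1-4 letter species prefix (e.g. `"Sm"`).
#' @param group group letter `"A"`, `"B"` or `"C"`, or a group-call list
#'   from [assign_group()]. `UNCLASSIFIED` is an error: such sequences
#'   cannot be named.
#' @param gene_number positive integer.
#' @param variant_letter optional single lowercase letter.
#' @param suppress_number omit the gene numeral (some single-gene groups are
#'   written without one, e.g. `"Pa2DBD-NRB"`). Default `FALSE`: the numeral
#'   is always emitted.
#' @return list with the components and `rendered`.
#' @export
#' @examples
#' assign_name("Bc", "A", 1, "a")$rendered
assign_name <- function(species_code, group, gene_number,
                        variant_letter = NULL, suppress_number = FALSE) {
  if (is.list(group)) group <- group$group
  if (!group %in% c("A", "B", "C")) {
    stop("cannot name a sequence with group '", group, "'", call. = FALSE)
  }
  if (!grepl("^[A-Za-z]{1,4}$", species_code)) {
    stop("species_code must be 1-4 letters: ", species_code, call. = FALSE)
  }
  gene_number <- as.integer(gene_number)
  stopifnot(!is.na(gene_number), gene_number >= 1L)
  if (!is.null(variant_letter) && !is.na(variant_letter)) {
    stopifnot(grepl("^[a-z]$", variant_letter))
  } else {
    variant_letter <- NULL
  }
  rendered <- paste0(species_code, "2DBD-NR", group,
                     if (!suppress_number) gene_number,
                     variant_letter)
  list(species_code = species_code, group_letter = group,
       gene_number = gene_number,
       variant_letter = if (is.null(variant_letter)) NA_character_
       else variant_letter,
       rendered = rendered)
}

#' @rdname assign_name
#' @param name rendered name to parse back into its components.
#' @export
parse_name <- function(name) {
  m <- regmatches(name,
                  regexec("^([A-Za-z]{1,4})2DBD-NR([ABC])([0-9]+)([a-z]?)$",
                          name))[[1]]
  if (!length(m)) stop("not a valid nomenclature name: ", name, call. = FALSE)
  list(species_code = m[2], group_letter = m[3],
       gene_number = as.integer(m[4]),
       variant_letter = if (nzchar(m[5])) m[5] else NA_character_,
       rendered = name)
}

#' Number genes and variants within one species and group
#'
#' Members of one group in one species are numbered by subgroup identity in
#' the supplied order (clade order from a tree, else any documented
#' ordering): distinct subgroups get successive gene numbers starting at 1;
#' members sharing a subgroup get the same number plus variant letters
#' `a`, `b`, `c`, ... in input order. A subgroup with a single member gets
#' no variant letter.
#'
#' @param subgroups character vector of subgroup identities, one per member,
#'   in the desired order.
#' @param members optional member labels (default
#'   `names(subgroups)` or positional labels).
#' @return data.frame with columns `member`, `subgroup`, `gene_number`,
#'   `variant_letter`.
#' @export
#' @examples
#' number_genes(c(x = "sg1", y = "sg1", z = "sg2"))
number_genes <- function(subgroups, members = NULL) {
  stopifnot(length(subgroups) >= 1L)
  if (is.null(members)) {
    members <- if (!is.null(names(subgroups))) names(subgroups)
    else paste0("member", seq_along(subgroups))
  }
  stopifnot(length(members) == length(subgroups))
  ids <- unique(subgroups)
  num <- match(subgroups, ids)
  counts <- table(factor(subgroups, levels = ids))
  variant <- character(length(subgroups))
  for (sg in ids) {
    idx <- which(subgroups == sg)
    variant[idx] <- if (length(idx) == 1L) NA_character_
    else letters[seq_along(idx)]
  }
  data.frame(member = unname(members), subgroup = unname(subgroups),
             gene_number = as.integer(num), variant_letter = variant,
             stringsAsFactors = FALSE)
}
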