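# FASTA and report I/O. A sequence set is a plain data.frame with columns
# id, description, residues; annotation reports are data.frames with a fixed
# column order so TSV output is stable across runs.

#' Read and write protein FASTA
#'
#' `read_fasta()` parses a plain protein FASTA file into a data.frame of
#' sequence records. Residues are uppercased, a single terminal stop (`*`) is
#' stripped, and every remaining character must be one of the 20 standard
#' amino-acid letters or `X`. Record ids (first whitespace-delimited token of
#' the header) must be unique within a file.
#'
#' @param path file path.
#' @return `read_fasta()`: a data.frame with character columns `id`,
#'   `description` (rest of the header, possibly `""`) and `residues`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">s1 demo", "MKCW"), tf)
#' read_fasta(tf)
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(ids)) {
    stop("duplicate record id(s) in '", path, "': ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  residues <- toupper(as.character(set))
  residues <- sub("\\*$", "", residues)
  for (i in seq_along(residues)) validate_residues(residues[i], ids[i])
  data.frame(id = ids, description = desc, residues = unname(residues),
             stringsAsFactors = FALSE)
}

# Errors with record id and 1-based offending position.
validate_residues <- function(residues, id) {
  if (!nzchar(residues)) stop("record '", id, "' has an empty sequence",
                              call. = FALSE)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% aa_input_alphabet())
  if (length(bad)) {
    stop("record '", id, "': illegal residue '", chars[bad[1]],
         "' at position ", bad[1], call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname read_fasta
#' @param records data.frame with columns `id`, `description`, `residues`.
#' @param width line-wrap width for sequence lines.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records),
            all(c("id", "residues") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- ifelse(nzchar(desc), paste(records$id, desc), records$id)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# Fixed column order of the tabular annotation report.
report_columns <- function() {
  c("seq_id", "architecture", "n_dbds", "linker_len",
    "pbox1", "dbox1", "pbox2", "dbox2", "pp_module", "group",
    "gbox", "pre_grip_len", "tbox_present", "ti_span", "af2", "ntss",
    "nr_class")
}

#' Write and re-read annotation reports
#'
#' Serializes annotation reports (one row per sequence, see
#' [annotate_sequences()]) as TSV or JSON with a fixed column order:
#' `r paste(report_columns(), collapse = ", ")`. `read_report()` restores the
#' same fields, so a write/read round trip is lossless.
#'
#' @param reports report data.frame; extra columns beyond the fixed set are
#'   dropped on write.
#' @param path output (input) file path.
#' @param format `"tsv"` or `"json"`.
#' @return `write_report()` returns `path` invisibly; `read_report()` returns
#'   the report data.frame.
#' @export
write_report <- function(reports, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(reports))
  cols <- report_columns()
  out <- data.frame(matrix(NA, nrow = nrow(reports), ncol = length(cols)),
                    stringsAsFactors = FALSE)
  names(out) <- cols
  for (cl in intersect(cols, names(reports))) out[[cl]] <- reports[[cl]]
  out <- coerce_report_types(out)
  ok <- tryCatch({
    if (format == "tsv") {
      utils::write.table(out, path, sep = "\t", quote = FALSE,
                         row.names = FALSE, na = "NA")
    } else {
      jsonlite::write_json(out, path, dataframe = "rows", na = "null",
                           auto_unbox = TRUE, digits = NA)
    }
    TRUE
  }, error = function(e) stop("cannot write report to '", path, "': ",
                              conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "tsv") {
    out <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE, na.strings = "NA",
                             colClasses = "character")
  } else {
    out <- jsonlite::fromJSON(path)
    if (length(out) == 0L) {
      out <- data.frame(matrix(nrow = 0, ncol = length(report_columns())))
      names(out) <- report_columns()
    }
    out <- as.data.frame(out, stringsAsFactors = FALSE)
  }
  coerce_report_types(out)
}

coerce_report_types <- function(df) {
  int_cols <- c("n_dbds", "linker_len", "pre_grip_len")
  chr_cols <- setdiff(report_columns(), c(int_cols, "tbox_present"))
  for (cl in intersect(int_cols, names(df))) df[[cl]] <- as.integer(df[[cl]])
  for (cl in intersect(chr_cols, names(df))) df[[cl]] <- as.character(df[[cl]])
  if ("tbox_present" %in% names(df))
    df$tbox_present <- as.logical(df$tbox_present)
  df[, intersect(report_columns(), names(df)), drop = FALSE]
}
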