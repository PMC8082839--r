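#' Read a FASTA sequence database
#'
#' Reads a multi-record FASTA file into the tabular form used throughout the
#' pipeline. Sequence IDs (`sid`) are consecutive integers assigned by order
#' of appearance starting at 0; residues are uppercased. Ambiguity codes
#' (N etc.) are retained here and excluded later, at candidate generation.
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return A tibble with columns `sid` (integer, 0-based), `accession`
#'   (first whitespace-delimited token of the header) and `seq`.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgtACGT", ">s2", "TTTTAAAA"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("cannot read FASTA file: ", path))
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0) abort("no sequences in FASTA file")
  first <- nonblank[1]
  if (!startsWith(trimws(lines[first]), ">"))
    abort(paste0("malformed FASTA header at line ", first,
                 ": expected '>' before sequence data"))
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort("no sequences in FASTA file")
  seqs <- toupper(as.character(set))
  empty <- which(!nzchar(seqs))
  if (length(empty) > 0)
    abort(paste0("empty sequence body for record ", empty[1],
                 " ('", names(set)[empty[1]], "')"))
  acc <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  tibble(sid = seq_along(seqs) - 1L, accession = unname(acc),
         seq = unname(seqs))
}

#' Write sequence records as FASTA
#'
#' @param records A tibble with `accession` and `seq` columns (as returned
#'   by [read_fasta()] or [generate_db()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(all(c("accession", "seq") %in% names(records)))
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$accession
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Serialize and parse pipeline rows
#'
#' The pipeline's intermediate tables have a canonical one-line text form:
#' fields are concatenated with `'+'`, and a sidset field (a set of sequence
#' IDs) is itself concatenated with `'-'`. `serialize_row()` and
#' [parse_row()] are mutual inverses on delimiter-free fields.
#'
#' @param fields A list of fields: character scalars are used verbatim;
#'   numeric vectors are treated as sidsets and joined with `'-'`.
#' @return A single string.
#' @export
#' @examples
#' serialize_row(list("*TCT", c(4, 5)))  # "*TCT+4-5"
#' serialize_row(list("GCT", 3))         # "GCT+3"
serialize_row <- function(fields) {
  stopifnot(is.list(fields), length(fields) > 0)
  txt <- vapply(fields, function(f) {
    if (is.numeric(f)) {
      paste(format(f, trim = TRUE, scientific = FALSE), collapse = "-")
    } else {
      f <- as.character(f)
      stopifnot(length(f) == 1)
      if (grepl("+", f, fixed = TRUE))
        abort("field contains the '+' delimiter")
      f
    }
  }, character(1))
  paste(txt, collapse = "+")
}

#' @rdname serialize_row
#' @param row A serialized row string.
#' @return `parse_row()`: a character vector of fields (use
#'   [parse_sidset()] on sidset fields).
#' @export
parse_row <- function(row) {
  stopifnot(is.character(row), length(row) == 1)
  strsplit(row, "+", fixed = TRUE)[[1]]
}

#' @rdname serialize_row
#' @param field A `'-'`-joined sidset field.
#' @return `parse_sidset()`: an integer vector.
#' @export
parse_sidset <- function(field) {
  as.integer(strsplit(field, "-", fixed = TRUE)[[1]])
}

#' Write the ranked primer-pair table
#'
#' Writes the result of [run_pair_step()] (or [tidy()] on a
#' `primer_design`) as a tab-separated table with a fixed column order.
#' Numeric columns are printed with fixed precision, so identical inputs
#' give byte-identical files.
#'
#' @param results A pair-result tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(results, path) {
  cols <- c("sid", "accession", "rank", "forward_primer", "reverse_primer",
            "fp_pos", "rp_pos", "product_size", "fp_tm", "rp_tm",
            "fp_gc", "rp_gc", "penalty")
  if (!"accession" %in% names(results)) results$accession <- NA_character_
  missing_cols <- setdiff(cols, names(results))
  if (length(missing_cols) > 0)
    abort(paste0("pair table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  out <- results[, cols]
  for (cc in c("fp_tm", "rp_tm", "fp_gc", "rp_gc", "penalty"))
    out[[cc]] <- sprintf("%.4f", out[[cc]])
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out) > 0) {
    body <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
    writeLines(body, con)
  }
  invisible(path)
}
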