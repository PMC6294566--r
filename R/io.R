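#' Read DNA sequences from FASTA
#'
#' Reads a (multi-)FASTA file, uppercases, strips whitespace, and validates
#' the strict ACGT alphabet. `U` is rejected with an explicit RNA message;
#' any other non-ACGT character is rejected naming the record and position.
#' Record order is preserved.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences (names from FASTA headers,
#'   first whitespace-delimited token).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e),
                                           call. = FALSE))
  if (length(set) == 0L)
    stop("empty FASTA: ", path, call. = FALSE)
  seqs <- as.character(set)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  out <- vapply(seq_along(seqs), function(i) {
    tryCatch(validate_dna(seqs[[i]], paste0("record ", i, " ('", ids[i], "')")),
             error = function(e) stop(conditionMessage(e), call. = FALSE))
  }, character(1))
  names(out) <- ids
  out
}

#' Write DNA sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output path.
#' @param width Line-wrap width. Default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60) {
  seqs <- vapply(seqs, validate_dna, character(1))
  set <- Biostrings::DNAStringSet(seqs)
  names(set) <- names(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

report_table <- function(x) {
  if (is.data.frame(x)) return(x)
  if (inherits(x, "ring_design")) return(x$candidates)
  if (inherits(x, "screen_report")) return(x$per_fragment)
  stop("cannot serialise object of class ", paste(class(x), collapse = "/"),
       call. = FALSE)
}

report_header <- function(x) {
  hdr <- c(paste0("ringforge v",
                  as.character(utils::packageVersion("ringforge"))))
  if (inherits(x, "ring_design")) {
    r <- x$rules
    hdr <- c(hdr,
             sprintf("ring_len=%d total_conc_uM=%g temperature_C=%g open_threshold_uM=%g",
                     x$ring_len, x$total_conc, x$temperature,
                     x$open_threshold),
             sprintf("rules: d=%d..%d dG_ceiling=%g tm=%g..%g splint_arm=%d",
                     r$d_min, r$d_max, r$dG_ceiling, r$tm_floor,
                     r$tm_ceiling, r$splint_arm))
    if (!is.null(x$note)) hdr <- c(hdr, paste0("note: ", x$note))
  }
  if (inherits(x, "screen_report"))
    hdr <- c(hdr,
             sprintf("n=%d positive=%d fraction=%.4f tm_floor=%g dG_ceiling=%g",
                     x$n_fragments, x$n_positive, x$fraction_positive,
                     x$thresholds$tm_floor, x$thresholds$dG_ceiling))
  hdr
}

#' Write a design or screen report
#'
#' TSV output carries the configuration in `#`-prefixed header comment
#' lines followed by a deterministic column order; JSON output serialises
#' the full object. Identical input and configuration produce
#' byte-identical files.
#'
#' @param x A `ring_design`, `screen_report`, or plain data.frame.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- report_table(x)
    con <- file(path, open = "wt")
    on.exit(close(con))
    writeLines(paste0("# ", report_header(x)), con)
    writeLines(paste(names(tab), collapse = "\t"), con)
    if (nrow(tab) > 0L) {
      body <- do.call(paste, c(lapply(tab, function(col) {
        if (is.numeric(col) && !is.integer(col)) sprintf("%.6g", col)
        else as.character(col)
      }), sep = "\t"))
      writeLines(body, con)
    }
  } else {
    obj <- if (is.data.frame(x)) list(table = x) else unclass(x)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  }
  invisible(path)
}

#' Read a report written as JSON back into a list
#'
#' @param path Path written by [write_report()] with `format = "json"`.
#' @return A list mirroring the serialised object.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
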