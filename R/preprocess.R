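# Read quality control: mean-Phred and length filtering before the
# translated search.

#' Read / write FASTQ with Phred+33 qualities
#'
#' Thin wrappers around Biostrings FASTQ I/O returning
#' `QualityScaledDNAStringSet`s.
#'
#' @param path FASTQ file (plain or gzip).
#' @param reads A `QualityScaledDNAStringSet` (or `DNAStringSet` with a
#'   `qualities` attribute).
#' @return `read_fastq`: a `QualityScaledDNAStringSet`; `write_fastq`:
#'   the path, invisibly.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stopf("FASTQ not found: %s", path)
  validate_fastq(path)
  withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path,
                                                quality.scoring = "phred"),
      error = function(e) stopf("malformed FASTQ '%s': %s", path,
                                conditionMessage(e))),
    # the reader always emits this housekeeping note; not user-actionable
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

# Structural check (the Biostrings reader silently pads truncated
# records); errors name the offending record index.
validate_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) %% 4L != 0L)
    stopf("malformed FASTQ '%s': truncated record %d", path,
          length(lines) %/% 4L + 1L)
  if (!length(lines)) return(invisible(TRUE))
  rec <- matrix(lines, nrow = 4L)
  bad <- which(!startsWith(rec[1L, ], "@") | !startsWith(rec[3L, ], "+") |
               nchar(rec[2L, ]) != nchar(rec[4L, ]))
  if (length(bad))
    stopf("malformed FASTQ '%s': record %d", path, bad[1L])
  invisible(TRUE)
}

#' @rdname read_fastq
#' @export
write_fastq <- function(reads, path) {
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}

mean_phred <- function(reads) {
  ql <- methods::as(Biostrings::quality(reads), "IntegerList")
  s <- sum(ql)
  w <- Biostrings::width(reads)
  ifelse(w > 0L, s / w, 0)
}

#' Quality-filter reads
#'
#' Retains reads whose arithmetic mean Phred score is at least
#' `min_mean_q` AND whose length is at least `min_len` (both thresholds
#' inclusive, as stated).  Read order is preserved; filtering is
#' idempotent.
#'
#' @param reads A `QualityScaledDNAStringSet` or a FASTQ path.
#' @param min_mean_q Minimum mean Phred score (default 20).
#' @param min_len Minimum read length in bp (default 70).
#' @param out Optional FASTQ path for the retained reads.
#' @return The retained reads, with attribute `qc_report` (data.frame
#'   `n_in`, `n_out`).
#' @export
filter_reads <- function(reads, min_mean_q = 20, min_len = 70, out = NULL) {
  if (is_string(reads)) reads <- read_fastq(reads)
  n_in <- length(reads)
  if (n_in == 0L) {
    keep <- reads
  } else {
    ok <- Biostrings::width(reads) >= min_len & mean_phred(reads) >= min_mean_q
    keep <- reads[ok]
  }
  attr(keep, "qc_report") <- data.frame(n_in = n_in, n_out = length(keep))
  if (!is.null(out)) write_fastq(keep, out)
  keep
}

#' @rdname filter_reads
#' @export
qc_report <- function(reads) attr(reads, "qc_report")
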