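# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Plain TSV I/O with stable column types; all tables in the package go
# through these so that written artifacts round-trip bit-exactly.
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = colClasses, check.names = FALSE)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# Benjamini-Hochberg within a family; NA-safe (NAs stay NA, are not counted).
bh_adjust <- function(p) p.adjust(p, method = "BH")
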