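# Translated homology search: six-frame translation, Smith-Waterman local
# alignment (blastx-style scoring) and top-hit read assignment against the
# pathofunction reference database, with decoy absorption.

the <- new.env(parent = emptyenv())

#' BLOSUM62 scoring matrix extended with selenocysteine
#'
#' The standard BLOSUM62 matrix (with B, Z, X and `*`) extended by a row
#' and column for selenocysteine (U): U matches U (+4, as cysteine
#' against itself) and mismatches every other residue (-4).
#'
#' @return Integer matrix with dimnames over the residue alphabet.
#' @export
blosum62u <- function() {
  if (!is.null(the$blosum62u)) return(the$blosum62u)
  env <- new.env()
  data("BLOSUM62", package = "Biostrings", envir = env)
  m <- env$BLOSUM62
  u <- matrix(-4L, nrow(m) + 1L, ncol(m) + 1L,
              dimnames = list(c(rownames(m), "U"), c(colnames(m), "U")))
  u[rownames(m), colnames(m)] <- m
  u["U", "U"] <- 4L
  storage.mode(u) <- "integer"
  the$blosum62u <- u
  u
}

#' Translate a read in all six frames
#'
#' Frames +1..+3 read the sequence as given, frames -1..-3 its reverse
#' complement, under translation table 11.  Stop codons appear as `*`;
#' codons containing N translate to `X`.
#'
#' @param read A nucleotide string, `DNAString`, or `DNAStringSet`
#'   (then a list of 6-frame character vectors per read is returned).
#' @return Character vector of 6 amino-acid strings, named
#'   `+1,+2,+3,-1,-2,-3` (or a list of such vectors).
#' @examples
#' translate_six_frames("ATGGCC")[["+1"]]  # "MA"
#' @export
translate_six_frames <- function(read) {
  single <- !methods::is(read, "DNAStringSet")
  dna <- if (single) Biostrings::DNAStringSet(as.character(read)) else read
  frames <- six_frames_set(dna)
  out <- lapply(seq_along(dna), function(i)
    setNames(vapply(frames, function(f) f[i], character(1)),
             c("+1", "+2", "+3", "-1", "-2", "-3")))
  if (single) out[[1L]] else out
}

# DNAStringSet -> list of 6 character vectors (one per frame), vectorized.
six_frames_set <- function(dna) {
  gc11 <- Biostrings::getGeneticCode("11")
  rc <- Biostrings::reverseComplement(dna)
  one_frame <- function(x, off) {
    w <- Biostrings::width(x)
    keep_w <- pmax(w - off, 0L)
    aa_len <- keep_w %/% 3L
    st <- pmin(off + 1L, w + 1L)
    sub <- Biostrings::subseq(x, start = st, width = aa_len * 3L)
    as.character(suppressWarnings(
      Biostrings::translate(sub, genetic.code = gc11,
                            if.fuzzy.codon = "X", no.init.codon = TRUE)))
  }
  c(lapply(0:2, function(o) unname(one_frame(dna, o))),
    lapply(0:2, function(o) unname(one_frame(rc, o))))
}

#' Optimal local alignment of amino-acid sequences
#'
#' Smith-Waterman alignment with affine gaps (a gap of length k costs
#' `gap_open + k * gap_ext`, the blastx convention).  Identity is the
#' fraction of identical residue pairs over alignment columns, gaps
#' counted as columns; `positives` is the analogous fraction of
#' positive-scoring pairs.
#'
#' @param query,subject Amino-acid strings (vectors are recycled
#'   pairwise against `subject`).
#' @param matrix Scoring matrix (default [blosum62u()]).
#' @param gap_open,gap_ext Gap opening / extension costs (blastx
#'   defaults 11 / 1).
#' @return data.frame with `score`, `identity`, `positives`, `aln_len`.
#' @export
align_local <- function(query, subject, matrix = blosum62u(),
                        gap_open = 11, gap_ext = 1) {
  stopifnot(all(nzchar(query)), all(nzchar(subject)))
  .sw_align_cpp(query, subject, matrix, rownames(matrix), gap_open, gap_ext)
}

#' Assign reads to reference genes by translated top-hit search
#'
#' Each read is aligned in all six frames against every reference
#' (including decoys); the single best alignment is the read's top hit,
#' recorded only if the alignment spans at least `min_aln` amino acids at
#' `min_ident` percent similarity or better.  Ties are broken by highest
#' identity, then longest alignment, then lexicographically smallest
#' `ref_id`, making the output deterministic.  Reads whose top hit is a
#' decoy are recorded with `decoy = TRUE` and must be excluded from
#' counting -- the decoys exist to absorb reads from related genes that
#' would otherwise inflate pathway counts.
#'
#' A k-mer seed prefilter (`prefilter = TRUE`, exact amino-acid
#' `seed_k`-mers shared between a frame and a reference) restricts the
#' alignment to plausible candidates; `prefilter = FALSE` aligns every
#' read against every reference.
#'
#' @param reads `QualityScaledDNAStringSet` / `DNAStringSet` / FASTQ path.
#' @param refdb A `pathofun_refdb`.
#' @param min_aln Minimum alignment length in amino acids (default 20).
#' @param min_ident Minimum percent similarity of the top hit (default
#'   70); compared with `>=`.
#' @param metric Similarity measure for the threshold: `"identity"`
#'   (percent identical columns, blastx pident semantics; default) or
#'   `"positives"` (percent positive-scoring columns).
#' @param matrix,gap_open,gap_ext Alignment scoring, see [align_local()].
#' @param prefilter,seed_k Seed heuristic controls (exact amino-acid k-mer seeds; default k = 6).
#' @return data.frame of hit records: `read_id`, `ref_id`, `pident`,
#'   `positives`, `length` (aa), `score`, `frame`, `decoy`,
#'   `gene_symbol`, `genus`, `pathway`; at most one row per read.
#' @export
assign_top_hits <- function(reads, refdb, min_aln = 20, min_ident = 70,
                            metric = c("identity", "positives"),
                            matrix = blosum62u(), gap_open = 11, gap_ext = 1,
                            prefilter = TRUE, seed_k = 6L) {
  metric <- match.arg(metric)
  stopifnot(inherits(refdb, "pathofun_refdb"))
  if (nrow(refdb$meta) == 0L) stopf("empty reference database")
  if (is_string(reads)) reads <- read_fastq(reads)
  if (methods::is(reads, "QualityScaledDNAStringSet"))
    reads <- methods::as(reads, "DNAStringSet")
  if (length(reads) == 0L)
    return(empty_hits())

  # refs in lexicographic ref_id order so the C++ index tie-break equals
  # the documented lexicographic rule
  ord <- order(refdb$meta$ref_id, method = "radix")
  meta <- refdb$meta[ord, , drop = FALSE]
  ref_seq <- as.character(refdb$seq[meta$ref_id])

  frames <- six_frames_set(reads)

  res <- .top_hit_cpp(frames, unname(ref_seq), matrix,
                      rownames(matrix), gap_open, gap_ext,
                      isTRUE(prefilter), as.integer(seed_k))
  if (length(res$read) == 0L) return(empty_hits())
  sim <- if (metric == "identity") res$identity else res$positives
  keep <- res$aln_len >= min_aln & sim >= min_ident
  idx <- which(keep)
  hits <- data.frame(
    read_id = names(reads)[res$read[idx]],
    ref_id = meta$ref_id[res$ref[idx]],
    pident = res$identity[idx],
    positives = res$positives[idx],
    length = res$aln_len[idx],
    score = res$score[idx],
    frame = res$frame[idx],
    decoy = meta$decoy[res$ref[idx]],
    gene_symbol = meta$gene_symbol[res$ref[idx]],
    genus = meta$genus[res$ref[idx]],
    pathway = meta$pathway[res$ref[idx]],
    stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(read_id = character(), ref_id = character(),
             pident = numeric(), positives = numeric(),
             length = integer(), score = numeric(), frame = integer(),
             decoy = logical(), gene_symbol = character(),
             genus = character(), pathway = character(),
             stringsAsFactors = FALSE)
}

#' Write / read hit tables (BLAST outfmt-6-like TSV)
#'
#' Column contract: `read_id`, `ref_id`, `pident`, `positives`, `length`,
#' `score`, `frame`, `decoy`, `gene_symbol`, `genus`, `pathway`
#' (tab-separated, header line).  `read_hits` also accepts a plain
#' 12-column outfmt-6 file from an external aligner (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore); in
#' that case reference annotations are joined from `refdb`.
#'
#' @param hits Hit table from [assign_top_hits()].
#' @param path TSV path.
#' @param refdb Optional `pathofun_refdb` for annotating external tables.
#' @return `write_hits`: path invisibly; `read_hits`: hit data.frame.
#' @export
write_hits <- function(hits, path) write_tsv(hits, path)

#' @rdname write_hits
#' @export
read_hits <- function(path, refdb = NULL) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "read_id\t")) return(read_tsv(path))
  raw <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 12L) stopf("not an outfmt-6 table: %s", path)
  if (is.null(refdb)) stopf("refdb required to annotate an outfmt-6 table")
  m <- refdb$meta[match(raw[[2L]], refdb$meta$ref_id), ]
  if (anyNA(m$ref_id)) stopf("outfmt-6 subject ids missing from refdb")
  data.frame(read_id = raw[[1L]], ref_id = raw[[2L]], pident = raw[[3L]],
             positives = NA_real_, length = raw[[4L]], score = raw[[12L]],
             frame = NA_integer_, decoy = m$decoy,
             gene_symbol = m$gene_symbol, genus = m$genus,
             pathway = m$pathway, stringsAsFactors = FALSE)
}
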