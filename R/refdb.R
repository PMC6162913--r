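# Reference-database construction: pathway definitions, profile-score
# cutoff selection with phylogenetic audit, bai operon synteny detection,
# and assembly of the searchable reference set (true positives + decoys +
# housekeeping genes).

#' Pathway definitions for the quantified pathofunctions
#'
#' Returns the gene sets that define each pathofunction together with the
#' presence rule applied during quantification: all member genes of a
#' pathway must be detected for the pathway to be called present, except
#' for the nine-gene bai operon where the cutoff is four genes.  The three
#' single-copy housekeeping genes (rplB, recA, pyrG) form the
#' normalization "pathway" `HKG`.
#'
#' @param bai_min_genes Minimum number of distinct bai genes required for
#'   bai operon presence (default 4).
#' @return A data.frame with columns `pathway_id`, `members` (list column
#'   of gene symbols) and `min_genes_present`.
#' @examples
#' pathway_defs()
#' @export
pathway_defs <- function(bai_min_genes = 4L) {
  bai <- paste0("bai", LETTERS[1:9])
  defs <- data.frame(
    pathway_id = c("cutCD", "cntAB", "grdH", "baiA-I", "dsrAB", "HKG"),
    min_genes_present = c(2L, 2L, 1L, as.integer(bai_min_genes), 2L, 3L),
    stringsAsFactors = FALSE
  )
  defs$members <- list(
    c("cutC", "cutD"), c("cntA", "cntB"), "grdH", bai,
    c("dsrA", "dsrB"), c("rplB", "recA", "pyrG")
  )
  bad <- defs$min_genes_present < 1L |
    defs$min_genes_present > lengths(defs$members)
  if (any(bad)) stopf("invalid min_genes_present for %s",
                      paste(defs$pathway_id[bad], collapse = ", "))
  defs[, c("pathway_id", "members", "min_genes_present")]
}

#' Housekeeping gene symbols used for normalization
#' @return Character vector `c("rplB", "recA", "pyrG")`.
#' @export
hkg_symbols <- function() c("rplB", "recA", "pyrG")

# Map gene symbol -> pathway_id (first matching definition).
symbol_pathway_map <- function(pathways = pathway_defs()) {
  map <- rep(pathways$pathway_id, lengths(pathways$members))
  names(map) <- unlist(pathways$members)
  map
}

#' Select true-positive candidate genes at a profile-score cutoff
#'
#' Candidate sequences from a profile (HMM) screen are admitted with
#' score above 100 and model coverage of at least 80%; among the admitted
#' candidates, true
#' positives are separated from related-but-distinct genes by a score
#' cutoff.  When no `manual_cutoff` is given the cutoff is placed at the
#' midpoint of the largest gap in the descending score sequence (the
#' "steep score drop").  When a phylogenetic tree of the candidates is
#' supplied the function also reports each candidate's cophenetic distance
#' to the top-scoring sequence, so that the expected monotone relationship
#' between falling score and growing phylogenetic distance can be audited.
#' Rejected candidates are returned for inclusion in the search database
#' as decoys, where they absorb reads from related genes and prevent
#' false-positive counts.
#'
#' @param candidates data.frame with columns `seq_id`, `hmm_score`,
#'   `coverage` (fraction of the model covered, in \[0,1\]).
#' @param tree Optional `phylo` object (or newick string / file path)
#'   whose tips cover all candidate ids; used for the distance audit.
#' @param top_seed Optional id of the top-scoring sequence used as the
#'   audit anchor; defaults to the highest-scoring candidate.
#' @param manual_cutoff Optional score cutoff overriding the automatic
#'   gap-based choice; acceptance is strict (`score > cutoff`).
#' @return List of class `pathofun_cutoff` with elements `cutoff`,
#'   `accepted` (seq ids), `rejected_decoys` (seq ids), and `audit`
#'   (data.frame of seq_id, hmm_score, distance_to_top, accepted).
#' @export
select_true_positives <- function(candidates, tree = NULL, top_seed = NULL,
                                  manual_cutoff = NULL) {
  req <- c("seq_id", "hmm_score", "coverage")
  if (!all(req %in% names(candidates)))
    stopf("candidates must have columns %s", paste(req, collapse = ", "))
  if (nrow(candidates) == 0L) stopf("no candidates supplied")
  if (anyDuplicated(candidates$seq_id))
    stopf("duplicate seq_id in candidate screen")
  if (!all(is.finite(candidates$hmm_score)))
    stopf("non-finite hmm_score")
  bad <- candidates$hmm_score <= 100 | candidates$coverage < 0.80
  if (any(bad))
    stopf("candidate(s) below admission thresholds (score > 100, coverage >= 0.80): %s",
          paste(candidates$seq_id[bad], collapse = ", "))

  ord <- order(-candidates$hmm_score, candidates$seq_id)
  cand <- candidates[ord, , drop = FALSE]

  if (is.null(manual_cutoff)) {
    if (nrow(cand) < 2L)
      stopf("fewer than 2 candidates: no score gap definable, supply manual_cutoff")
    s <- cand$hmm_score
    gaps <- s[-length(s)] - s[-1L]
    k <- which.max(gaps)  # ties: gap nearest the top of the score list
    cutoff <- (s[k] + s[k + 1L]) / 2
  } else {
    cutoff <- manual_cutoff
  }
  acc <- cand$hmm_score > cutoff

  dist_to_top <- rep(NA_real_, nrow(cand))
  if (!is.null(tree)) {
    tree <- as_phylo(tree)
    missing_tips <- setdiff(cand$seq_id, tree$tip.label)
    if (length(missing_tips))
      stopf("candidate id(s) missing from tree: %s",
            paste(missing_tips, collapse = ", "))
    anchor <- top_seed %||% cand$seq_id[1L]
    if (!anchor %in% tree$tip.label)
      stopf("top_seed '%s' missing from tree", anchor)
    cd <- ape::cophenetic.phylo(tree)
    dist_to_top <- cd[anchor, cand$seq_id]
  }

  structure(list(
    cutoff = cutoff,
    accepted = cand$seq_id[acc],
    rejected_decoys = cand$seq_id[!acc],
    audit = data.frame(seq_id = cand$seq_id, hmm_score = cand$hmm_score,
                       distance_to_top = as.numeric(dist_to_top),
                       accepted = acc, stringsAsFactors = FALSE)
  ), class = "pathofun_cutoff")
}

#' @export
print.pathofun_cutoff <- function(x, ...) {
  cat(sprintf("profile-score cutoff: %.6g (%d accepted, %d decoys)\n",
              x$cutoff, length(x$accepted), length(x$rejected_decoys)))
  invisible(x)
}

as_phylo <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (is_string(tree)) {
    if (file.exists(tree)) return(ape::read.tree(tree))
    return(ape::read.tree(text = tree))
  }
  stopf("tree must be a phylo object, newick string or file path")
}

#' Tip-to-tip (cophenetic) distance on a phylogenetic tree
#'
#' Sum of branch lengths along the unique path between two tips.
#'
#' @param tree A `phylo` object, newick string or file path.
#' @param tip_a,tip_b Tip labels.
#' @return Nonnegative numeric distance; 0 when `tip_a == tip_b`.
#' @examples
#' cophenetic_distance("((A:1,B:2):3,C:4);", "A", "B")  # 3
#' @export
cophenetic_distance <- function(tree, tip_a, tip_b) {
  tree <- as_phylo(tree)
  for (tip in c(tip_a, tip_b))
    if (!tip %in% tree$tip.label) stopf("tip '%s' not in tree", tip)
  if (tip_a == tip_b) return(0)
  cd <- ape::cophenetic.phylo(tree)
  unname(cd[tip_a, tip_b])
}

#' Detect bai operons by gene synteny
#'
#' Scans a genome annotation for runs of bai genes in which consecutive
#' bai genes are separated by at most `max_separation` locus positions; a
#' run counting at least `min_genes` distinct bai gene symbols qualifies
#' the genome as a bai operon carrier.  Paralogous repeats of one symbol
#' do not inflate the count, and interleaved non-bai genes are irrelevant
#' beyond their contribution to locus separation.
#'
#' @param genome data.frame with columns `locus_index` (integer rank in
#'   annotation order) and `gene_symbol`; or an object from
#'   [make_genomes()].
#' @param bai_symbols Gene symbols of the operon (default baiA..baiI).
#' @param min_genes Minimum distinct symbols per qualifying run.
#' @param max_separation Maximum locus-index separation between
#'   consecutive bai genes within a run.
#' @return data.frame of runs (`start_locus`, `end_locus`, `n_records`,
#'   `n_symbols`, `symbols`, `qualifies`), with attribute `carrier`
#'   (logical: any qualifying run).
#' @export
find_bai_operons <- function(genome, bai_symbols = paste0("bai", LETTERS[1:9]),
                             min_genes = 4L, max_separation = 10L) {
  ann <- if (is.data.frame(genome)) genome else genome$annotation
  if (!all(c("locus_index", "gene_symbol") %in% names(ann)))
    stopf("annotation needs locus_index and gene_symbol columns")
  ann <- ann[order(ann$locus_index), , drop = FALSE]
  if (is.unsorted(ann$locus_index, strictly = TRUE))
    stopf("locus_index must be strictly increasing")
  bai <- ann[ann$gene_symbol %in% bai_symbols, , drop = FALSE]
  empty <- data.frame(start_locus = integer(), end_locus = integer(),
                      n_records = integer(), n_symbols = integer(),
                      symbols = character(), qualifies = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(bai) == 0L) {
    attr(empty, "carrier") <- FALSE
    return(empty)
  }
  gap <- c(0L, diff(bai$locus_index))
  run_id <- cumsum(gap > max_separation)
  runs <- lapply(split(seq_len(nrow(bai)), run_id), function(i) {
    syms <- sort(unique(bai$gene_symbol[i]))
    data.frame(start_locus = min(bai$locus_index[i]),
               end_locus = max(bai$locus_index[i]),
               n_records = length(i), n_symbols = length(syms),
               symbols = paste(syms, collapse = ","),
               qualifies = length(syms) >= min_genes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, runs)
  rownames(out) <- NULL
  attr(out, "carrier") <- any(out$qualifies)
  out
}

#' @rdname find_bai_operons
#' @export
is_bai_carrier <- function(genome, ...) {
  isTRUE(attr(find_bai_operons(genome, ...), "carrier"))
}

#' Assemble the searchable pathofunction reference database
#'
#' Combines accepted pathway genes, below-cutoff decoys and the
#' housekeeping genes of all genomes into one protein reference set.
#' Decoy sequences never contribute to counts downstream; they are kept
#' only to absorb reads from related genes.  The per-symbol median
#' reference length (over non-decoy sequences) used for gene-length
#' correction is computed here and stored with the database.
#'
#' @param genes data.frame with columns `ref_id`, `genome_id`, `genus`,
#'   `gene_symbol`, `sequence` (amino acids) and optionally `decoy`
#'   (logical, default FALSE).
#' @param pathways Pathway definitions, see [pathway_defs()].
#' @return Object of class `pathofun_refdb`: list with `seq`
#'   (named `AAStringSet`), `meta` (data.frame) and `median_len`
#'   (named numeric, per non-decoy gene symbol).
#' @export
assemble_reference_db <- function(genes, pathways = pathway_defs()) {
  req <- c("ref_id", "genome_id", "genus", "gene_symbol", "sequence")
  if (!all(req %in% names(genes)))
    stopf("genes must have columns %s", paste(req, collapse = ", "))
  if (anyDuplicated(genes$ref_id))
    stopf("duplicate ref_id: %s",
          paste(unique(genes$ref_id[duplicated(genes$ref_id)]), collapse = ", "))
  if (any(!nzchar(genes$sequence))) stopf("empty protein sequence")
  genes$decoy <- as.logical(genes$decoy %||% FALSE)
  genes$decoy[is.na(genes$decoy)] <- FALSE

  map <- symbol_pathway_map(pathways)
  genes$pathway <- unname(map[genes$gene_symbol])
  orphan <- is.na(genes$pathway) & !genes$decoy
  if (any(orphan)) {
    warnf("gene symbol(s) not in any pathway definition, marked decoy: %s",
          paste(unique(genes$gene_symbol[orphan]), collapse = ", "))
    genes$decoy[orphan] <- TRUE
  }
  genes$pathway[is.na(genes$pathway)] <- "decoy"
  genes$length_aa <- nchar(genes$sequence)

  meta <- genes[order(genes$ref_id),
                c("ref_id", "genome_id", "genus", "gene_symbol", "pathway",
                  "decoy", "length_aa")]
  rownames(meta) <- NULL
  seq <- Biostrings::AAStringSet(setNames(genes$sequence[order(genes$ref_id)],
                                          meta$ref_id))
  true_pos <- meta[!meta$decoy, , drop = FALSE]
  median_len <- vapply(split(true_pos$length_aa, true_pos$gene_symbol),
                       median, numeric(1))

  structure(list(seq = seq, meta = meta, median_len = median_len,
                 pathways = pathways),
            class = "pathofun_refdb")
}

#' @export
print.pathofun_refdb <- function(x, ...) {
  cat(sprintf("pathofunction reference database: %d sequences (%d decoys), %d gene symbols\n",
              nrow(x$meta), sum(x$meta$decoy),
              length(unique(x$meta$gene_symbol))))
  invisible(x)
}

#' Write / read a reference database (protein FASTA + metadata TSV)
#'
#' @param db A `pathofun_refdb`.
#' @param dir Output directory (created if needed); files are
#'   `reference.faa` and `reference_meta.tsv`.
#' @return `write_refdb` the directory, invisibly; `read_refdb` the
#'   reconstructed `pathofun_refdb` (bit-exact metadata round trip).
#' @export
write_refdb <- function(db, dir) {
  stopifnot(inherits(db, "pathofun_refdb"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Biostrings::writeXStringSet(db$seq, file.path(dir, "reference.faa"))
  write_tsv(db$meta, file.path(dir, "reference_meta.tsv"))
  invisible(dir)
}

#' @rdname write_refdb
#' @export
read_refdb <- function(dir) {
  seq <- Biostrings::readAAStringSet(file.path(dir, "reference.faa"))
  meta <- read_tsv(file.path(dir, "reference_meta.tsv"),
                   colClasses = c(ref_id = "character",
                                  genome_id = "character",
                                  genus = "character",
                                  gene_symbol = "character",
                                  pathway = "character",
                                  decoy = "logical",
                                  length_aa = "integer"))
  genes <- data.frame(ref_id = meta$ref_id, genome_id = meta$genome_id,
                      genus = meta$genus, gene_symbol = meta$gene_symbol,
                      sequence = as.character(seq[meta$ref_id]),
                      decoy = meta$decoy, stringsAsFactors = FALSE)
  suppressWarnings(assemble_reference_db(genes))
}
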