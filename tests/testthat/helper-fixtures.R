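# Shared fixtures and independent oracles used across test files.
# Fixtures are generated in code (seeded) -- nothing is read from disk.

# Session-cached template database (construction is seeded and costs a
# few seconds; every test sees the identical object).
fixtures <- new.env()

get_templates <- function() {
  if (is.null(fixtures$templates)) fixtures$templates <- gene_templates()
  fixtures$templates
}

get_refdb <- function() {
  if (is.null(fixtures$refdb))
    fixtures$refdb <- template_refdb(get_templates())
  fixtures$refdb
}

# A tiny hand-sized reference database with controllable lengths.
toy_refdb <- function() {
  aa <- function(n, ch = "A") strrep(ch, n)
  genes <- data.frame(
    ref_id = c("cutC_1", "cutC_2", "cutD_1", "rplB_1", "recA_1", "pyrG_1",
               paste0("bai", LETTERS[1:9], "_1")),
    genome_id = "g1", genus = "GenusA",
    gene_symbol = c("cutC", "cutC", "cutD", "rplB", "recA", "pyrG",
                    paste0("bai", LETTERS[1:9])),
    sequence = c(aa(400), aa(600), aa(300), aa(300), aa(400), aa(500),
                 rep(aa(250), 9)),
    decoy = FALSE, stringsAsFactors = FALSE)
  assemble_reference_db(genes)
}

# Build a hit table with a prescribed number of non-decoy reads per
# (gene symbol, genus).
toy_hits <- function(counts, genus = "GenusA", sample_id = NULL) {
  rows <- list()
  for (sym in names(counts)) {
    n <- counts[[sym]]
    if (n == 0) next
    rows[[sym]] <- data.frame(
      read_id = sprintf("%s_r%04d", sym, seq_len(n)),
      ref_id = paste0(sym, "_1"), pident = 100, positives = 100,
      length = 30L, score = 150, frame = 1L, decoy = FALSE,
      gene_symbol = sym, genus = genus, pathway = NA_character_,
      stringsAsFactors = FALSE)
  }
  h <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
       else data.frame(read_id = character(), ref_id = character(),
                       pident = numeric(), positives = numeric(),
                       length = integer(), score = numeric(),
                       frame = integer(), decoy = logical(),
                       gene_symbol = character(), genus = character(),
                       pathway = character(), stringsAsFactors = FALSE)
  if (!is.null(sample_id)) h$sample_id <- rep(sample_id, nrow(h))
  h
}

# Independent cophenetic oracle: enumerate the tip-to-root paths on the
# edge table and sum branch lengths to the most recent common ancestor.
coph_oracle <- function(tree, a, b) {
  ia <- match(a, tree$tip.label)
  ib <- match(b, tree$tip.label)
  path_to_root <- function(node) {
    out <- numeric(0); names(out) <- character(0)
    while (TRUE) {
      row <- which(tree$edge[, 2] == node)
      if (!length(row)) break
      out[as.character(tree$edge[row, 1])] <- tree$edge.length[row]
      node <- tree$edge[row, 1]
    }
    out
  }
  pa <- path_to_root(ia); pb <- path_to_root(ib)
  if (ia == ib) return(0)
  anc <- intersect(names(pa), names(pb))
  mrca <- anc[1L]  # paths are ordered tip -> root; first shared is MRCA
  da <- sum(pa[seq_len(match(mrca, names(pa)))])
  db <- sum(pb[seq_len(match(mrca, names(pb)))])
  da + db
}

# Brute-force AUC: count concordant positive/negative pairs.
auc_oracle <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  pos <- scores[y == 1L]; neg <- scores[y == 0L]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + if (p > n) 1 else if (p == n) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Exhaustive top-hit oracle via Biostrings::pairwiseAlignment (an
# independent Smith-Waterman implementation): all reads x all refs x all
# frames, same scoring and tie-break rules.
tophit_oracle <- function(reads, refdb, min_aln = 20, min_ident = 70,
                          gap_open = 11, gap_ext = 1) {
  m <- blosum62u()
  ord <- order(refdb$meta$ref_id, method = "radix")
  meta <- refdb$meta[ord, , drop = FALSE]
  refs <- as.character(refdb$seq[meta$ref_id])
  frames <- lapply(translate_six_frames(
    methods::as(reads, "DNAStringSet")), unname)
  n <- length(reads)
  sc <- array(-Inf, c(n, length(refs), 6))
  idt <- array(NA_real_, c(n, length(refs), 6))
  len <- array(NA_integer_, c(n, length(refs), 6))
  for (f in seq_len(6)) {
    qs <- vapply(frames, `[`, character(1), f)
    ok <- nzchar(qs)
    if (!any(ok)) next
    for (r in seq_along(refs)) {
      aln <- Biostrings::pairwiseAlignment(
        qs[ok], refs[r], type = "local", substitutionMatrix = m,
        gapOpening = gap_open, gapExtension = gap_ext)
      sc[ok, r, f] <- Biostrings::score(aln)
      idt[ok, r, f] <- Biostrings::pid(aln, "PID1")
      len[ok, r, f] <- nchar(as.character(Biostrings::alignedPattern(aln)))
    }
  }
  out <- list()
  for (i in seq_len(n)) {
    best <- NULL
    for (f in seq_len(6)) for (r in seq_along(refs)) {
      if (sc[i, r, f] <= 0) next
      cand <- list(ref = r, score = sc[i, r, f], ident = idt[i, r, f],
                   len = len[i, r, f])
      if (is.null(best) || cand$score > best$score ||
          (cand$score == best$score && (cand$ident > best$ident ||
           (cand$ident == best$ident && (cand$len > best$len ||
            (cand$len == best$len && r < best$ref))))))
        best <- cand
    }
    if (is.null(best)) next
    if (best$len >= min_aln && best$ident >= min_ident)
      out[[length(out) + 1L]] <- data.frame(
        read_id = names(reads)[i], ref_id = meta$ref_id[best$ref],
        score = best$score, decoy = meta$decoy[best$ref],
        gene_symbol = meta$gene_symbol[best$ref], stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

# Brute-force co-occurrence network oracle: plain loops over pairs and
# datasets, cor.test for rho/p, p.adjust within dataset.
network_oracle <- function(tables, rho_thr = 0.35, p_thr = 0.05,
                           q_thr = 0.05, min_ds = 3L) {
  entities <- sort(unique(unlist(lapply(tables, function(t)
    setdiff(names(t), "sample_id")))))
  pair_support <- list()
  for (d in names(tables)) {
    tab <- tables[[d]]
    res <- list()
    for (i in seq_along(entities)) for (j in seq_along(entities)) {
      if (i >= j) next
      a <- entities[i]; b <- entities[j]
      if (!a %in% names(tab) || !b %in% names(tab)) next
      if (all(is.na(tab[[a]])) || all(is.na(tab[[b]]))) next
      if (sd(tab[[a]]) == 0 || sd(tab[[b]]) == 0) next
      ct <- suppressWarnings(stats::cor.test(tab[[a]], tab[[b]],
                                             method = "spearman",
                                             exact = FALSE))
      res[[paste(a, b)]] <- c(rho = unname(ct$estimate), p = ct$p.value)
    }
    if (!length(res)) next
    ps <- vapply(res, `[[`, numeric(1), "p")
    qs <- stats::p.adjust(ps, "BH")
    for (k in names(res)) {
      ok <- res[[k]]["rho"] > rho_thr && res[[k]]["p"] < p_thr &&
        qs[k] < q_thr
      if (ok) pair_support[[k]] <- (pair_support[[k]] %||% 0L) + 1L
    }
  }
  kept <- names(pair_support)[unlist(pair_support) >= min_ds]
  data.frame(pair = sort(kept),
             width = unlist(pair_support)[sort(kept)],
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Manual FASTQ record builder (bypasses the package writer so reader and
# writer are tested against each other).
fastq_lines <- function(ids, seqs, quals) {
  as.vector(rbind(paste0("@", ids), seqs, "+", quals))
}

make_reads <- function(seqs, quals, ids = sprintf("r%03d", seq_along(seqs))) {
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(stats::setNames(seqs, ids)),
    Biostrings::PhredQuality(quals))
}

phred_string <- function(q, len) strrep(rawToChar(as.raw(q + 33L)), len)
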