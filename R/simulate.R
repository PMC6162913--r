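# Synthetic community / read simulator.  Generates genomes that each carry
# exactly one copy of the three housekeeping genes, a controllable fraction
# of genomes carrying pathofunction genes (bai carriers in a synteny-valid
# run), and matched DNA/RNA read sets with controllable expression ratios,
# Phred qualities and base errors -- so every downstream stage has ground
# truth.  All outputs are byte-deterministic under the seed.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Template protein lengths (aa), in the range of the real gene families.
TEMPLATE_LEN <- c(
  cutC = 850, cutD = 290, cntA = 375, cntB = 300, grdH = 440,
  baiA = 249, baiB = 210, baiC = 320, baiD = 330, baiE = 200,
  baiF = 270, baiG = 290, baiH = 310, baiI = 230,
  dsrA = 437, dsrB = 380, rplB = 273, recA = 350, pyrG = 545
)

random_protein <- function(len) paste(sample(AA20, len, replace = TRUE),
                                      collapse = "")

#' Synthetic protein templates for all pathway and housekeeping genes
#'
#' Deterministic (seeded) random amino-acid sequences, one per gene
#' symbol, used as the ancestors from which simulated genomes and the
#' reference database derive their sequences.  The grdH template ends in
#' selenocysteine (U), mirroring the selenoprotein nature of betaine
#' reductase; references are stored with the U retained.  A grdH-related
#' decoy template (`grdB_like`, a diverged copy) is provided for decoy
#' absorption experiments.
#'
#' @param seed Integer seed controlling template generation.
#' @return Named character vector of protein sequences, with attribute
#'   `decoys` (named character vector of decoy templates).
#' @export
gene_templates <- function(seed = 20L) {
  withr_seed <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.Random.seed_restore(withr_seed), add = TRUE)
  tpl <- vapply(TEMPLATE_LEN, random_protein, character(1))
  substr(tpl["grdH"], TEMPLATE_LEN["grdH"], TEMPLATE_LEN["grdH"]) <- "U"
  decoys <- c(grdB_like = mutate_protein(tpl[["grdH"]], 0.35),
              baiA_like = mutate_protein(tpl[["baiA"]], 0.35))
  attr(tpl, "decoys") <- decoys
  tpl
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Mutate a protein sequence to a target amino-acid divergence
#'
#' Substitutes `round(divergence * nchar)` positions with uniformly drawn
#' different residues (uses the current RNG stream).
#'
#' @param seq Amino-acid string.
#' @param divergence Fraction of positions to substitute, in \[0,1\].
#' @return Mutated amino-acid string.
#' @export
mutate_protein <- function(seq, divergence) {
  stopifnot(divergence >= 0, divergence <= 1)
  n <- nchar(seq)
  k <- round(divergence * n)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  for (p in pos) {
    alt <- AA20[AA20 != chars[p]]
    chars[p] <- alt[sample.int(length(alt), 1L)]
  }
  paste(chars, collapse = "")
}

# AA -> synonymous codons under translation table 11 (bacterial);
# selenocysteine is encoded by TGA.
codon_table11 <- function() {
  gc <- Biostrings::getGeneticCode("11")
  by_aa <- split(names(gc), unname(gc))
  by_aa$U <- "TGA"
  by_aa
}

#' Back-translate a protein to nucleotides (table 11, uniform codons)
#'
#' Synonymous codons are chosen uniformly at random from the current RNG
#' stream; codon usage bias is deliberately absent because the search
#' stage operates on translated reads.
#'
#' @param aa Amino-acid string (selenocysteine U encoded as TGA).
#' @return Nucleotide string of length `3 * nchar(aa)`.
#' @export
back_translate <- function(aa) {
  tab <- codon_table11()
  chars <- strsplit(aa, "", fixed = TRUE)[[1L]]
  codons <- vapply(chars, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) stopf("cannot back-translate residue '%s'", a)
    opts[sample.int(length(opts), 1L)]
  }, character(1))
  paste(codons, collapse = "")
}

#' Specify a synthetic community
#'
#' Bundles the parameters of one simulated community: genome number and
#' genus labels, per-pathway carrier fractions, genome relative
#' abundances, read number/length, per-pathway RNA expression multipliers,
#' sequencing error and quality parameters, and the seed.
#'
#' @param n_genomes Number of genomes in the community.
#' @param genus Genus label per genome (recycled); defaults to cycling
#'   over six synthetic genus names.
#' @param carrier_fraction Named vector: fraction of genomes carrying each
#'   pathway (names from [pathway_defs()]), e.g. `c(cutCD = 0.1)`.
#' @param abundance Genome relative abundances (normalized to sum 1);
#'   `NULL` for uniform.
#' @param carriers Optional named list pathway -> integer genome indices,
#'   overriding the seeded random carrier draw (used to pin ground truth).
#' @param n_reads Reads per sample.
#' @param read_len Read length (bp); >= 70 recommended (shorter reads are
#'   rejected by QC by construction).
#' @param expression Named per-pathway RNA expression multipliers
#'   (default 1 for every pathway, including `HKG` and the hypothetical
#'   background genes, key `background`).
#' @param base_error_rate Per-base substitution error rate.
#' @param mean_q Mean Phred quality of simulated reads.
#' @param divergence_genus,divergence_genome Amino-acid divergence of a
#'   genus variant from the template, and of a genome's gene copy from
#'   its genus variant.
#' @param n_background Number of hypothetical (non-reference) genes per
#'   genome; these make most reads unassignable, as in real gut
#'   metagenomes where pathway signal is a small fraction of reads.
#' @param seed Integer seed.
#' @return List of class `community_spec`.
#' @export
community_spec <- function(n_genomes = 50L,
                           genus = NULL,
                           carrier_fraction = c(cutCD = 0.1),
                           abundance = NULL,
                           carriers = NULL,
                           n_reads = 2e4L,
                           read_len = 100L,
                           expression = NULL,
                           base_error_rate = 0.002,
                           mean_q = 30,
                           divergence_genus = 0.12,
                           divergence_genome = 0.03,
                           n_background = 40L,
                           seed = 1L) {
  genus <- genus %||% paste0("Genus", LETTERS[1:6])
  genus <- rep_len(genus, n_genomes)
  if (is.null(abundance)) abundance <- rep(1 / n_genomes, n_genomes)
  if (length(abundance) != n_genomes) stopf("abundance length != n_genomes")
  if (any(abundance < 0)) stopf("negative abundance")
  abundance <- abundance / sum(abundance)
  stopifnot(all(carrier_fraction >= 0), all(carrier_fraction <= 1))
  structure(list(
    n_genomes = as.integer(n_genomes), genus = genus,
    carrier_fraction = carrier_fraction, abundance = abundance,
    carriers = carriers, n_reads = as.integer(n_reads),
    read_len = as.integer(read_len), expression = expression,
    base_error_rate = base_error_rate, mean_q = mean_q,
    divergence_genus = divergence_genus,
    divergence_genome = divergence_genome,
    n_background = as.integer(n_background), seed = as.integer(seed)
  ), class = "community_spec")
}

#' Build the reference database matching a set of templates
#'
#' One reference sequence per (gene symbol, genus), each a seeded genus
#' variant of the template, plus decoy templates.  This mirrors a curated
#' multi-genus gene database against which simulated reads are searched.
#'
#' @param templates Output of [gene_templates()].
#' @param genus Genus labels to generate references for.
#' @param divergence_genus Amino-acid divergence of each genus variant
#'   from the template.
#' @param seed Seed for the genus-variant draws.
#' @return A `pathofun_refdb`.
#' @export
template_refdb <- function(templates = gene_templates(),
                           genus = paste0("Genus", LETTERS[1:6]),
                           divergence_genus = 0.12, seed = 20L) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  rows <- list()
  for (g in genus) {
    for (sym in names(templates)) {
      rows[[length(rows) + 1L]] <- data.frame(
        ref_id = sprintf("%s__%s", sym, g),
        genome_id = sprintf("tpl_%s", g), genus = g, gene_symbol = sym,
        sequence = mutate_protein(templates[[sym]], divergence_genus),
        decoy = FALSE, stringsAsFactors = FALSE)
    }
  }
  decoys <- attr(templates, "decoys")
  for (d in names(decoys)) {
    rows[[length(rows) + 1L]] <- data.frame(
      ref_id = sprintf("decoy__%s", d), genome_id = "decoy_tpl",
      genus = "unknown", gene_symbol = d, sequence = decoys[[d]],
      decoy = TRUE, stringsAsFactors = FALSE)
  }
  suppressWarnings(assemble_reference_db(do.call(rbind, rows)))
}

# Which genus variant does a genome's genes derive from.
genus_variant_seq <- function(refdb, sym, genus) {
  id <- sprintf("%s__%s", sym, genus)
  if (!id %in% names(refdb$seq)) stopf("no reference for %s in genus %s",
                                       sym, genus)
  as.character(refdb$seq[[id]])
}

#' Generate annotated genomes for a community
#'
#' Every genome carries exactly one copy of each housekeeping gene;
#' genomes designated carriers additionally carry one copy of each member
#' gene of their pathway, with bai genes placed contiguously so that the
#' operon passes the synteny rule.  Gene sequences are mutated copies of
#' the genome's genus reference variant at `divergence_genome`; the bulk
#' of each genome consists of hypothetical background genes absent from
#' the reference database.
#'
#' @param spec A [community_spec()].
#' @param refdb Reference database from [template_refdb()].
#' @param pathways Pathway definitions.
#' @return List of class `pathofun_genomes`; each element has
#'   `genome_id`, `genus`, `annotation` (locus_index, gene_symbol, start,
#'   end) and `seq` (nucleotide string).  Attribute `carriers` records
#'   the genome indices per pathway.
#' @export
make_genomes <- function(spec, refdb, pathways = pathway_defs()) {
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  on.exit(.Random.seed_restore(old), add = TRUE)

  n <- spec$n_genomes
  carriers <- list()
  for (pw in names(spec$carrier_fraction)) {
    k <- round(spec$carrier_fraction[[pw]] * n)
    carriers[[pw]] <- if (!is.null(spec$carriers[[pw]]))
      as.integer(spec$carriers[[pw]]) else sort(sample.int(n, k))
  }
  member_map <- setNames(pathways$members, pathways$pathway_id)

  genomes <- vector("list", n)
  for (i in seq_len(n)) {
    g <- spec$genus[i]
    syms <- hkg_symbols()
    bai_syms <- character()
    for (pw in names(carriers)) {
      if (!i %in% carriers[[pw]]) next
      mem <- member_map[[pw]]
      if (pw == "baiA-I") bai_syms <- mem else syms <- c(syms, mem)
    }
    n_bg <- spec$n_background
    bg_syms <- if (n_bg > 0) sprintf("hyp%03d", seq_len(n_bg)) else character()

    # protein for each locus
    make_prot <- function(sym) {
      if (grepl("^hyp", sym)) return(random_protein(300L))
      mutate_protein(genus_variant_seq(refdb, sym, g), spec$divergence_genome)
    }
    # order: shuffle singles and background, then splice the bai run in
    # (contiguous, synteny-valid) at a random position
    singles <- sample(c(syms, bg_syms))
    if (length(bai_syms)) {
      at <- sample.int(length(singles) + 1L, 1L)
      singles <- append(singles, bai_syms, after = at - 1L)
    }
    prots <- vapply(singles, make_prot, character(1))
    nts <- vapply(prots, back_translate, character(1))
    spacers <- vapply(seq_along(nts), function(j)
      paste(sample(c("A", "C", "G", "T"), 50L, replace = TRUE),
            collapse = ""), character(1))
    lens <- nchar(nts)
    # layout: spacer gene spacer gene ... (spacer before each gene)
    starts <- cumsum(c(1L, head(lens + 50L, -1L))) + 50L
    seqs <- paste0(spacers, nts, collapse = "")
    genomes[[i]] <- list(
      genome_id = sprintf("sim%03d", i), genus = g,
      annotation = data.frame(locus_index = seq_along(singles),
                              gene_symbol = unname(singles),
                              start = unname(starts),
                              end = unname(starts + lens - 1L),
                              stringsAsFactors = FALSE),
      seq = seqs)
    if (min(nchar(prots)) * 3L < 1L) stopf("zero-length gene in genome %d", i)
  }
  low_ident <- spec$divergence_genome + spec$divergence_genus > 0.30
  if (low_ident)
    warnf("combined divergence > 30%%: reads will be unassignable by design")
  structure(genomes, class = "pathofun_genomes", carriers = carriers,
            spec = spec)
}

#' Ground-truth table for a simulated community
#'
#' True pathway abundance is the abundance-weighted percentage of genomes
#' carrying the pathway; genus truth restricts the sum to carriers of a
#' genus.  The true RNA/DNA ratio of a pathway is its expression
#' multiplier divided by the housekeeping multiplier.
#'
#' @param genomes Output of [make_genomes()].
#' @return List with `pathway` (data.frame pathway, true_abundance_pct,
#'   true_rna_dna_ratio) and `genus` (data.frame pathway, genus,
#'   true_abundance_pct).
#' @export
truth_table <- function(genomes) {
  spec <- attr(genomes, "spec")
  carriers <- attr(genomes, "carriers")
  ab <- spec$abundance
  genus <- vapply(genomes, `[[`, character(1), "genus")
  expr <- function(pw) {
    e <- spec$expression[[pw]] %||% 1
    e_h <- spec$expression[["HKG"]] %||% 1
    e / e_h
  }
  pw_rows <- lapply(names(carriers), function(pw) {
    idx <- carriers[[pw]]
    data.frame(pathway = pw,
               true_abundance_pct = 100 * sum(ab[idx]),
               true_rna_dna_ratio = expr(pw), stringsAsFactors = FALSE)
  })
  gen_rows <- lapply(names(carriers), function(pw) {
    idx <- carriers[[pw]]
    if (!length(idx)) return(NULL)
    agg <- tapply(ab[idx], genus[idx], sum)
    data.frame(pathway = pw, genus = names(agg),
               true_abundance_pct = 100 * as.numeric(agg),
               stringsAsFactors = FALSE)
  })
  list(pathway = do.call(rbind, pw_rows),
       genus = do.call(rbind, gen_rows))
}

q_to_char <- function(q) {
  q <- pmin(pmax(as.integer(round(q)), 2L), 40L)
  strsplit(rawToChar(as.raw(q + 33L)), "", fixed = TRUE)[[1L]]
}

#' Sample sequencing reads from a simulated community
#'
#' DNA reads (`level = "MTG"`) are drawn uniformly along each genome
#' (genome chosen by relative abundance), so genes contribute reads in
#' proportion to abundance x gene length.  RNA reads (`level = "MTX"`)
#' are drawn from annotated genes only, weighted additionally by the
#' per-pathway expression multiplier.  Substitution errors occur at
#' `base_error_rate`; each read carries a homogeneous Phred+33 quality
#' drawn around `mean_q`.  Byte-deterministic under `seed`.
#'
#' @param genomes Output of [make_genomes()].
#' @param level `"MTG"` (DNA) or `"MTX"` (RNA/cDNA).
#' @param n_reads,seed Override the community spec's read count / seed.
#' @return A [Biostrings::QualityScaledDNAStringSet].
#' @export
sample_reads <- function(genomes, level = c("MTG", "MTX"),
                         n_reads = NULL, seed = NULL) {
  level <- match.arg(level)
  spec <- attr(genomes, "spec")
  n_reads <- as.integer(n_reads %||% spec$n_reads)
  stopifnot(n_reads > 0L)
  old <- .Random.seed_exists()
  set.seed(seed %||% (spec$seed + ifelse(level == "MTG", 1e4L, 2e4L)))
  on.exit(.Random.seed_restore(old), add = TRUE)

  L <- spec$read_len
  glens <- vapply(genomes, function(g) nchar(g$seq), integer(1))
  if (any(glens == 0L)) stopf("zero-length genome")

  starts <- integer(n_reads)
  lens <- integer(n_reads)
  if (level == "MTG") {
    gi <- sample.int(length(genomes), n_reads, replace = TRUE,
                     prob = spec$abundance)
    maxs <- pmax(glens[gi] - L + 1L, 1L)
    starts <- floor(runif(n_reads) * maxs) + 1L
    lens <- pmin(L, glens[gi] - starts + 1L)
  } else {
    # RNA reads come from the pooled transcript population: a genome's
    # share is abundance x its total expressed length, a gene's share
    # within the genome is length x expression multiplier
    map <- symbol_pathway_map()
    e_of <- function(sym) {
      pw <- map[sym]
      key <- ifelse(grepl("^hyp", sym), "background",
                    ifelse(is.na(pw), "background", pw))
      vapply(key, function(k) spec$expression[[k]] %||% 1, numeric(1))
    }
    wlist <- lapply(genomes, function(g)
      (g$annotation$end - g$annotation$start + 1L) *
        e_of(g$annotation$gene_symbol))
    wtot <- vapply(wlist, sum, numeric(1))
    if (any(wtot <= 0)) stopf("all expression weights zero in a genome")
    gi <- sample.int(length(genomes), n_reads, replace = TRUE,
                     prob = spec$abundance * wtot)
    for (u in unique(gi)) {
      sel <- which(gi == u)
      ann <- genomes[[u]]$annotation
      gidx <- sample.int(nrow(ann), length(sel), replace = TRUE,
                         prob = wlist[[u]])
      gl <- ann$end[gidx] - ann$start[gidx] + 1L
      rl <- pmin(L, gl)
      off <- floor(runif(length(sel)) * (gl - rl + 1L))
      starts[sel] <- ann$start[gidx] + off
      lens[sel] <- rl
    }
  }
  seqs <- substring(vapply(genomes, `[[`, character(1), "seq")[gi],
                    starts, starts + lens - 1L)

  # substitution errors
  n_err <- rbinom(n_reads, lens, spec$base_error_rate)
  for (r in which(n_err > 0L)) {
    ch <- strsplit(seqs[r], "", fixed = TRUE)[[1L]]
    pos <- sample.int(length(ch), min(n_err[r], length(ch)))
    for (p in pos) {
      alt <- setdiff(c("A", "C", "G", "T"), ch[p])
      ch[p] <- alt[sample.int(3L, 1L)]
    }
    seqs[r] <- paste(ch, collapse = "")
  }
  # random strand
  flip <- runif(n_reads) < 0.5
  if (any(flip)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs[flip])))
    seqs[flip] <- unname(rc)
  }
  q <- q_to_char(rnorm(n_reads, spec$mean_q, 3))
  quals <- strrep(q, lens)
  reads <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(seqs, sprintf("read%06d", seq_len(n_reads)))),
    Biostrings::PhredQuality(quals))
  reads
}

#' Simulate a multi-dataset case/control study
#'
#' Emulates a multi-cohort design: each dataset has a disease and a
#' control arm; patient arms receive multiplicatively shifted true
#' carrier abundances, and each dataset carries a lognormal random
#' intercept so that mixed-model recovery is testable.  Per-sample true
#' abundances (the TruthTable) are always produced; read sets are
#' optional because most statistical tests operate on abundance tables.
#'
#' @param n_datasets Number of datasets (cohorts).
#' @param n_per_arm Samples per arm per dataset.
#' @param diseases Disease label per dataset (recycled).
#' @param effects Named list: disease -> named vector of per-pathway
#'   multiplicative effects on true abundance (default 1 = null).
#' @param base_abundance Named vector of control-arm mean true abundance
#'   (%) per pathway.
#' @param sd_dataset SD of the dataset random intercept on log abundance.
#' @param sd_sample SD of per-sample lognormal noise on log abundance.
#' @param seed Integer seed.
#' @param emit_reads If TRUE, also simulate a read set per sample (slow;
#'   sized by `n_genomes`/`n_reads`).
#' @param n_genomes,n_reads Community size per sample when emitting reads.
#' @return List with `sample_sheet` (sample_id, dataset, disease, arm,
#'   level, subject, timepoint), `truth` (long data.frame sample_id x
#'   pathway -> true_abundance_pct) and, when `emit_reads`, `reads`
#'   (named list of read sets) plus `refdb`.
#' @export
make_study <- function(n_datasets = 12L, n_per_arm = 6L,
                       diseases = c("CVD", "T2D", "CRC", "IBD"),
                       effects = list(),
                       base_abundance = c(cutCD = 0.5, grdH = 0.3),
                       sd_dataset = 0.4, sd_sample = 0.5,
                       seed = 1L, emit_reads = FALSE,
                       n_genomes = 20L, n_reads = 5000L) {
  stopifnot(n_per_arm >= 1L, n_datasets >= 1L)
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  diseases <- rep_len(diseases, n_datasets)
  pw <- names(base_abundance)
  sheet <- list(); truth <- list()
  for (d in seq_len(n_datasets)) {
    u_d <- rnorm(1L, 0, sd_dataset)
    for (arm in c("control", "patient")) {
      eff <- rep(1, length(pw)); names(eff) <- pw
      if (arm == "patient" && !is.null(effects[[diseases[d]]])) {
        e <- effects[[diseases[d]]]
        eff[names(e)[names(e) %in% pw]] <- e[names(e) %in% pw]
      }
      for (s in seq_len(n_per_arm)) {
        sid <- sprintf("D%02d_%s_%02d", d, arm, s)
        sheet[[length(sheet) + 1L]] <- data.frame(
          sample_id = sid, dataset = sprintf("D%02d", d),
          disease = diseases[d], arm = arm, level = "MTG",
          subject = sid, timepoint = 1L, stringsAsFactors = FALSE)
        ab <- base_abundance * eff * exp(u_d) *
          exp(rnorm(length(pw), 0, sd_sample))
        truth[[length(truth) + 1L]] <- data.frame(
          sample_id = sid, pathway = pw,
          true_abundance_pct = unname(ab), stringsAsFactors = FALSE)
      }
    }
  }
  out <- list(sample_sheet = do.call(rbind, sheet),
              truth = do.call(rbind, truth))
  if (emit_reads) {
    templates <- gene_templates()
    refdb <- template_refdb(templates)
    reads <- list()
    for (i in seq_len(nrow(out$sample_sheet))) {
      sid <- out$sample_sheet$sample_id[i]
      tr <- out$truth[out$truth$sample_id == sid, ]
      frac <- setNames(pmin(tr$true_abundance_pct / 100, 0.9), tr$pathway)
      # one carrier genome per pathway at the target abundance share
      n_pw <- length(frac)
      abund <- c(unname(frac),
                 rep((1 - sum(frac)) / (n_genomes - n_pw), n_genomes - n_pw))
      spec <- community_spec(
        n_genomes = n_genomes,
        carrier_fraction = setNames(rep(1 / n_genomes, n_pw), names(frac)),
        carriers = setNames(as.list(seq_len(n_pw)), names(frac)),
        abundance = abund, n_reads = n_reads, seed = seed + 100L * i)
      genomes <- make_genomes(spec, refdb)
      reads[[sid]] <- sample_reads(genomes, "MTG")
    }
    out$reads <- reads
    out$refdb <- refdb
  }
  out
}

#' Simulate an association-level design for mixed-model recovery
#'
#' Draws per-sample abundances and Bernoulli disease labels directly from
#' the random-intercept logistic model
#' `logit P(disease) = intercept + u_dataset + beta * log(abundance + 1)`,
#' so that [glmm_disease()] recovery of `beta` can be checked exactly.
#'
#' @param n_datasets,n_per_dataset Design size.
#' @param beta True fixed effect on log(abundance + 1).
#' @param sd_dataset SD of the dataset random intercept.
#' @param intercept Fixed intercept.
#' @param seed Integer seed.
#' @return data.frame with `dataset`, `abundance`, `disease` (0/1).
#' @export
simulate_association <- function(n_datasets = 12L, n_per_dataset = 200L,
                                 beta = 1, sd_dataset = 0.5,
                                 intercept = -1, seed = 1L) {
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(.Random.seed_restore(old), add = TRUE)
  ds <- rep(sprintf("D%02d", seq_len(n_datasets)), each = n_per_dataset)
  u <- rnorm(n_datasets, 0, sd_dataset)[rep(seq_len(n_datasets),
                                            each = n_per_dataset)]
  ab <- rlnorm(length(ds), 0, 1)
  p <- plogis(intercept + u + beta * log1p(ab))
  data.frame(dataset = ds, abundance = ab,
             disease = rbinom(length(ds), 1L, p),
             stringsAsFactors = FALSE)
}
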