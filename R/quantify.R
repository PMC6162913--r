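# Quantification: gene-length-corrected counts, housekeeping-gene (HKG)
# normalized pathway abundance/expression with presence rules, genus
# rollups, RNA/DNA ratios and detection fractions.
#
# "Abundance" of a pathofunction is the percentage of community genomes
# carrying it: median corrected count over the pathway's member genes,
# divided by the mean corrected count of the three single-copy HKGs
# (rplB, recA, pyrG), times 100.

#' Count assigned reads per gene symbol, gene-length corrected
#'
#' Decoy hits are excluded (they only absorb reads).  Raw counts per
#' (sample, gene symbol, genus) are corrected by the median reference
#' length of the symbol (over non-decoy references).
#'
#' @param hits Hit table from [assign_top_hits()]; a `sample_id` column
#'   marks multi-sample tables, otherwise `sample_id` is used.
#' @param refdb A `pathofun_refdb` (provides median reference lengths).
#' @param sample_id Sample id for single-sample hit tables.
#' @return data.frame `sample_id`, `gene_symbol`, `genus`, `raw`,
#'   `corrected`.
#' @export
count_genes <- function(hits, refdb, sample_id = "sample") {
  stopifnot(inherits(refdb, "pathofun_refdb"))
  if (!"sample_id" %in% names(hits)) {
    hits$sample_id <- if (nrow(hits)) sample_id else character(0)
  }
  hits <- hits[!hits$decoy, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(data.frame(sample_id = character(), gene_symbol = character(),
                      genus = character(), raw = numeric(),
                      corrected = numeric(), stringsAsFactors = FALSE))
  missing_len <- setdiff(unique(hits$gene_symbol), names(refdb$median_len))
  if (length(missing_len))
    stopf("no reference length for symbol(s): %s",
          paste(missing_len, collapse = ", "))
  key <- paste(hits$sample_id, hits$gene_symbol, hits$genus, sep = "\r")
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), "\r", fixed = TRUE))
  out <- data.frame(sample_id = parts[, 1L], gene_symbol = parts[, 2L],
                    genus = parts[, 3L], raw = as.numeric(tab),
                    stringsAsFactors = FALSE)
  out$corrected <- out$raw / refdb$median_len[out$gene_symbol]
  out <- out[order(out$sample_id, out$gene_symbol, out$genus), ]
  rownames(out) <- NULL
  out
}

# per-sample corrected count per symbol (summed over genera); returns a
# samples x symbols matrix with zeros for unobserved symbols
symbol_matrix <- function(counts, samples = NULL, symbols = NULL) {
  samples <- samples %||% sort(unique(counts$sample_id))
  symbols <- symbols %||% sort(unique(counts$gene_symbol))
  m <- matrix(0, length(samples), length(symbols),
              dimnames = list(samples, symbols))
  if (nrow(counts)) {
    agg <- tapply(counts$corrected,
                  list(counts$sample_id, counts$gene_symbol), sum)
    common_s <- intersect(samples, rownames(agg))
    common_g <- intersect(symbols, colnames(agg))
    sub <- agg[common_s, common_g, drop = FALSE]
    sub[is.na(sub)] <- 0
    m[common_s, common_g] <- sub
  }
  m
}

hkg_mean_per_sample <- function(counts, samples) {
  m <- symbol_matrix(counts, samples, hkg_symbols())
  rowMeans(m)
}

#' Pathway abundance relative to housekeeping genes
#'
#' For each sample, pathway abundance (%) is
#' `100 * median(corrected member-gene counts) / mean(corrected HKG
#' counts)`, set to 0 when fewer than the pathway's required number of
#' member genes are detected (all members for two-gene pathways; four of
#' nine for the bai operon).  The three TMA-forming pathways (cutCD,
#' cntAB, grdH) are computed separately.  Samples with all three HKG
#' counts zero are flagged and reported as NA.
#'
#' @param counts Output of [count_genes()].
#' @param refdb A `pathofun_refdb`.
#' @param pathways Pathway definitions (default: the database's).
#' @param median_over For pathways passing the presence rule with some
#'   member genes undetected (bai): take the median over `"detected"`
#'   genes only (default -- a pathway passing the presence rule always
#'   has positive abundance) or over `"all"` member genes, zeros
#'   included (stricter; a 4-of-9 bai detection then stays at 0).
#' @param samples Optional sample universe (adds all-zero samples).
#' @return data.frame: `sample_id` plus one column per non-HKG pathway
#'   (abundance %); attributes `hkg_mean` (named numeric) and `excluded`
#'   (samples without HKG signal).
#' @export
pathway_abundance <- function(counts, refdb, pathways = NULL,
                              median_over = c("detected", "all"),
                              samples = NULL) {
  median_over <- match.arg(median_over)
  pathways <- pathways %||% refdb$pathways %||% pathway_defs()
  samples <- samples %||% sort(unique(counts$sample_id))
  if (!length(samples))
    return(structure(data.frame(sample_id = character(),
                                stringsAsFactors = FALSE),
                     hkg_mean = numeric(), excluded = character()))
  all_syms <- unique(c(unlist(pathways$members), unique(counts$gene_symbol)))
  m <- symbol_matrix(counts, samples, sort(all_syms))
  hkg <- rowMeans(m[, hkg_symbols(), drop = FALSE])
  excluded <- names(hkg)[hkg == 0]

  pws <- pathways[pathways$pathway_id != "HKG", , drop = FALSE]
  out <- data.frame(sample_id = samples, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(pws))) {
    mem <- pws$members[[k]]
    need <- pws$min_genes_present[k]
    sub <- m[, mem, drop = FALSE]
    n_det <- rowSums(sub > 0)
    med <- apply(sub, 1L, function(v) {
      if (median_over == "detected" && any(v > 0)) median(v[v > 0])
      else median(v)
    })
    val <- ifelse(n_det >= need, 100 * med / hkg, 0)
    val[hkg == 0] <- NA_real_
    out[[pws$pathway_id[k]]] <- unname(val)
  }
  attr(out, "hkg_mean") <- hkg
  attr(out, "excluded") <- excluded
  out
}

#' Genus-resolved pathway abundance
#'
#' Per (sample, pathway, genus): 100 x the cumulative corrected count of
#' the genus's member genes over the sample's HKG mean.  No presence
#' rule is applied at genus level; values are continuous.
#'
#' @inheritParams pathway_abundance
#' @return Long data.frame `sample_id`, `pathway`, `genus`, `abundance`.
#' @export
genus_abundance <- function(counts, refdb, pathways = NULL, samples = NULL) {
  pathways <- pathways %||% refdb$pathways %||% pathway_defs()
  samples <- samples %||% sort(unique(counts$sample_id))
  hkg <- hkg_mean_per_sample(counts, samples)
  map <- symbol_pathway_map(pathways)
  cc <- counts[!counts$gene_symbol %in% hkg_symbols(), , drop = FALSE]
  cc <- cc[cc$gene_symbol %in% names(map), , drop = FALSE]
  if (nrow(cc) == 0L)
    return(data.frame(sample_id = character(), pathway = character(),
                      genus = character(), abundance = numeric(),
                      stringsAsFactors = FALSE))
  cc$pathway <- unname(map[cc$gene_symbol])
  agg <- stats::aggregate(corrected ~ sample_id + pathway + genus, cc, sum)
  agg$abundance <- 100 * agg$corrected / hkg[agg$sample_id]
  agg$corrected <- NULL
  agg <- agg[order(agg$sample_id, agg$pathway, agg$genus), ]
  rownames(agg) <- NULL
  agg
}

#' Total genus abundance from housekeeping genes
#'
#' The share of a sample's community affiliated with a genus, measured
#' as the genus's mean corrected HKG count over the sample-wide mean
#' corrected HKG count, in percent.  Used for taxa-function correlation.
#'
#' @inheritParams pathway_abundance
#' @return Long data.frame `sample_id`, `genus`, `abundance_pct`.
#' @export
genus_total_abundance <- function(counts, refdb, samples = NULL) {
  samples <- samples %||% sort(unique(counts$sample_id))
  hkg <- hkg_mean_per_sample(counts, samples)
  cc <- counts[counts$gene_symbol %in% hkg_symbols(), , drop = FALSE]
  if (nrow(cc) == 0L)
    return(data.frame(sample_id = character(), genus = character(),
                      abundance_pct = numeric(), stringsAsFactors = FALSE))
  # mean over the three HKG symbols; unobserved symbols count as zero
  agg <- stats::aggregate(corrected ~ sample_id + genus, cc, sum)
  agg$abundance_pct <- 100 * (agg$corrected / 3) / hkg[agg$sample_id]
  agg$corrected <- NULL
  agg[order(agg$sample_id, agg$genus), , drop = FALSE]
}

#' RNA/DNA expression ratios over matched sample pairs
#'
#' Per pathway, the per-pair ratio expression/abundance is computed over
#' declared DNA/RNA sample pairs; pairs where either value is 0 (or NA)
#' are dropped, and the median over the remaining pairs is reported.  If
#' no valid pair remains the ratio is NA (undefined), never 0.
#'
#' @param abundance Wide abundance table (DNA level), see
#'   [pathway_abundance()].
#' @param expression Wide expression table (RNA level), same layout.
#' @param pairs data.frame with columns `mtg_sample`, `mtx_sample`
#'   declaring matched pairs.
#' @return List with `median` (named numeric per pathway) and `pairs`
#'   (long data.frame of per-pair ratios).
#' @export
rna_dna_ratio <- function(abundance, expression, pairs) {
  stopifnot(all(c("mtg_sample", "mtx_sample") %in% names(pairs)))
  pws <- intersect(setdiff(names(abundance), "sample_id"),
                   setdiff(names(expression), "sample_id"))
  ia <- match(pairs$mtg_sample, abundance$sample_id)
  ie <- match(pairs$mtx_sample, expression$sample_id)
  if (anyNA(ia) || anyNA(ie)) stopf("pair sample(s) missing from tables")
  rows <- list()
  med <- setNames(rep(NA_real_, length(pws)), pws)
  for (pw in pws) {
    a <- abundance[[pw]][ia]
    e <- expression[[pw]][ie]
    ok <- !is.na(a) & !is.na(e) & a > 0 & e > 0
    if (any(ok)) {
      r <- e[ok] / a[ok]
      med[pw] <- median(r)
      rows[[pw]] <- data.frame(pathway = pw,
                               mtg_sample = pairs$mtg_sample[ok],
                               mtx_sample = pairs$mtx_sample[ok],
                               ratio = r, stringsAsFactors = FALSE)
    }
  }
  list(median = med,
       pairs = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
               else data.frame(pathway = character(), mtg_sample = character(),
                               mtx_sample = character(), ratio = numeric(),
                               stringsAsFactors = FALSE))
}

#' Detection fraction: percentage of samples harboring a pathway
#'
#' @param abundance Wide abundance (or expression) table.
#' @return Named numeric, percent of samples with value > 0 per pathway
#'   (NA samples excluded; NA for an empty cohort).
#' @export
detection_fraction <- function(abundance) {
  pws <- setdiff(names(abundance), "sample_id")
  vapply(pws, function(pw) {
    v <- abundance[[pw]]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else 100 * mean(v > 0)
  }, numeric(1))
}
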