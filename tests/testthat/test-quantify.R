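# Quantification: gene-length correction, HKG normalization, presence
# rules, genus rollups, RNA/DNA ratios, detection fractions.

test_that("counts are corrected by the median reference length", {
  db <- toy_refdb()  # cutC refs of 400 and 600 aa -> median 500
  h <- toy_hits(c(cutC = 10))
  cnt <- count_genes(h, db, "s1")
  expect_equal(cnt$raw, 10)
  expect_equal(cnt$corrected, 10 / 500)
  expect_equal(nrow(count_genes(toy_hits(c(cutC = 0)), db, "s1")), 0L)
  bad <- toy_hits(c(cutC = 1)); bad$gene_symbol <- "nosuch"
  expect_error(count_genes(bad, db, "s1"), "nosuch")
})

test_that("pathway abundance is median over members per HKG mean", {
  db <- toy_refdb()
  # corrected: cutC = 10/500 = 0.02, cutD = 12/300 = 0.04 -> median 0.03
  # HKG: rplB 9/300, recA 12/400, pyrG 15/500 -> mean 0.03
  h <- toy_hits(c(cutC = 10, cutD = 12, rplB = 9, recA = 12, pyrG = 15))
  ab <- pathway_abundance(count_genes(h, db, "s1"), db)
  expect_equal(ab$cutCD, 100)
  # scale invariance: k-fold read counts leave the ratio unchanged
  h3 <- toy_hits(c(cutC = 30, cutD = 36, rplB = 27, recA = 36, pyrG = 45))
  ab3 <- pathway_abundance(count_genes(h3, db, "s1"), db)
  expect_equal(ab3$cutCD, ab$cutCD)
})

test_that("presence rules zero incomplete pathways exactly", {
  db <- toy_refdb()
  base <- c(rplB = 9, recA = 12, pyrG = 15)
  # cutCD requires both genes
  only_c <- pathway_abundance(
    count_genes(toy_hits(c(base, cutC = 10)), db, "s1"), db)
  expect_equal(only_c$cutCD, 0)
  both <- pathway_abundance(
    count_genes(toy_hits(c(base, cutC = 10, cutD = 2)), db, "s1"), db)
  expect_gt(both$cutCD, 0)
  # bai requires four of nine distinct genes
  bai3 <- c(base, baiA = 5, baiB = 5, baiC = 5)
  expect_equal(pathway_abundance(
    count_genes(toy_hits(bai3), db, "s1"), db)$`baiA-I`, 0)
  bai4 <- c(bai3, baiD = 5)
  expect_gt(pathway_abundance(
    count_genes(toy_hits(bai4), db, "s1"), db)$`baiA-I`, 0)
})

test_that("bai median spans detected genes by default, all nine on request", {
  db <- toy_refdb()
  cnt <- count_genes(
    toy_hits(c(rplB = 10, recA = 10, pyrG = 10,
               baiA = 5, baiB = 5, baiC = 5, baiD = 5)), db, "s1")
  det <- pathway_abundance(cnt, db)   # default: detected genes
  all9 <- pathway_abundance(cnt, db, median_over = "all")
  # 4 of 9 detected: the detected-gene median is positive (pathway is
  # present), while a median over all nine members is dragged to 0 by
  # the five undetected genes
  expect_gt(det$`baiA-I`, 0)
  expect_equal(all9$`baiA-I`, 0)
  # with >= 5 of 9 detected both conventions are positive
  cnt9 <- count_genes(
    toy_hits(c(rplB = 10, recA = 10, pyrG = 10, baiA = 5, baiB = 5,
               baiC = 5, baiD = 5, baiE = 5)), db, "s1")
  expect_gt(pathway_abundance(cnt9, db, median_over = "all")$`baiA-I`, 0)
})

test_that("samples without HKG signal are flagged and NA", {
  db <- toy_refdb()
  h <- toy_hits(c(cutC = 5, cutD = 5), sample_id = "bad")
  ab <- pathway_abundance(count_genes(h, db), db)
  expect_true(is.na(ab$cutCD[ab$sample_id == "bad"]))
  expect_equal(attr(ab, "excluded"), "bad")
})

test_that("genus abundances are cumulative and additive", {
  db <- local({
    aa <- function(n) strrep("A", n)
    assemble_reference_db(data.frame(
      ref_id = c("cutC_a", "cutC_b", "cutD_a", "cutD_b",
                 "rplB_1", "recA_1", "pyrG_1"),
      genome_id = "g", genus = c("GA", "GB", "GA", "GB", "GA", "GA", "GA"),
      gene_symbol = c("cutC", "cutC", "cutD", "cutD", hkg_symbols()),
      sequence = aa(300), decoy = FALSE, stringsAsFactors = FALSE))
  })
  h <- rbind(
    transform(toy_hits(c(cutC = 6, cutD = 2), genus = "GA"), sample_id = "s"),
    transform(toy_hits(c(cutC = 4, cutD = 8), genus = "GB"), sample_id = "s"),
    transform(toy_hits(c(rplB = 10, recA = 10, pyrG = 10), genus = "GA"),
              sample_id = "s"))
  cnt <- count_genes(h, db)
  ga <- genus_abundance(cnt, db)
  cut_rows <- ga[ga$pathway == "cutCD", ]
  # two genera splitting the reads: genus sums equal the cumulative signal
  hkg_mean <- mean(c(10, 10, 10) / 300)
  total_cut <- 100 * ((6 + 2) / 300 + (4 + 8) / 300) / hkg_mean
  expect_equal(sum(cut_rows$abundance), total_cut)
  # genus-level cumulative value exceeds the median-based pathway value
  # when counts are skewed
  ab <- pathway_abundance(cnt, db)
  expect_gt(sum(cut_rows$abundance), ab$cutCD)
  # absent genus contributes nothing
  expect_false("GC" %in% ga$genus)
})

test_that("genus totals derive from housekeeping shares", {
  db <- local({
    aa <- function(n) strrep("A", n)
    rows <- expand.grid(genus = c("GA", "GB"), sym = hkg_symbols(),
                        stringsAsFactors = FALSE)
    assemble_reference_db(data.frame(
      ref_id = paste0(rows$sym, "_", rows$genus), genome_id = "g",
      genus = rows$genus, gene_symbol = rows$sym, sequence = aa(300),
      decoy = FALSE, stringsAsFactors = FALSE))
  })
  h <- rbind(
    transform(toy_hits(c(rplB = 30, recA = 30, pyrG = 30), genus = "GA"),
              sample_id = "s"),
    transform(toy_hits(c(rplB = 10, recA = 10, pyrG = 10), genus = "GB"),
              sample_id = "s"))
  h$ref_id <- paste0(h$gene_symbol, "_", h$genus)
  tot <- genus_total_abundance(count_genes(h, db), db)
  expect_equal(tot$abundance_pct[tot$genus == "GA"], 75)
  expect_equal(tot$abundance_pct[tot$genus == "GB"], 25)
})

test_that("RNA/DNA ratios use only both-positive pairs", {
  ab <- data.frame(sample_id = c("d1", "d2", "d3"),
                   cutCD = c(1, 3, 2), grdH = c(1, 1, 1))
  ex <- data.frame(sample_id = c("r1", "r2", "r3"),
                   cutCD = c(2, 0, 4), grdH = c(0, 0, 0))
  pairs <- data.frame(mtg_sample = c("d1", "d2", "d3"),
                      mtx_sample = c("r1", "r2", "r3"))
  rr <- rna_dna_ratio(ab, ex, pairs)
  expect_equal(unname(rr$median["cutCD"]), 2)       # ratios {2, 2}
  expect_true(is.na(rr$median["grdH"]))             # all RNA zero -> NA
  expect_equal(nrow(rr$pairs[rr$pairs$pathway == "cutCD", ]), 2L)
  # identical values in matched pairs give median 1
  ex_same <- ab; ex_same$sample_id <- c("r1", "r2", "r3")
  same <- rna_dna_ratio(ab, ex_same, pairs)
  expect_equal(unname(same$median["cutCD"]), 1)
})

test_that("detection fractions count positive samples", {
  tab <- data.frame(sample_id = paste0("s", 1:4),
                    cutCD = c(1, 0.5, 0, 2), dsrAB = c(0, 0, 0, 0))
  d <- detection_fraction(tab)
  expect_equal(unname(d["cutCD"]), 75)
  expect_equal(unname(d["dsrAB"]), 0)
  empty <- detection_fraction(data.frame(sample_id = character(),
                                         cutCD = numeric()))
  expect_true(is.na(empty["cutCD"]))
})
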