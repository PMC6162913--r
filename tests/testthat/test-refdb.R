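# Reference-database construction: cutoff selection, cophenetic audit,
# synteny detection, database assembly and round trip.

test_that("automatic cutoff lands in the largest score gap", {
  cand <- data.frame(seq_id = paste0("s", 1:6),
                     hmm_score = c(900, 880, 860, 550, 120, 110),
                     coverage = 0.9)
  res <- select_true_positives(cand)
  # brute-force over all adjacent gaps in the descending score sequence
  s <- sort(cand$hmm_score, decreasing = TRUE)
  gaps <- s[-length(s)] - s[-1]
  k <- which.max(gaps)
  expect_gt(res$cutoff, s[k + 1]); expect_lt(res$cutoff, s[k])
  expect_setequal(res$accepted, paste0("s", 1:4))
  expect_setequal(res$rejected_decoys, paste0("s", 5:6))
})

test_that("manual cutoff accepts exactly the strictly-greater scores", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    cand <- data.frame(seq_id = sprintf("c%02d", seq_len(n)),
                       hmm_score = 101 + round(runif(n, 0, 900), 1),
                       coverage = runif(n, 0.8, 1))
    cut <- runif(1, 0, 1000)
    res <- select_true_positives(cand, manual_cutoff = cut)
    expect_setequal(res$accepted, cand$seq_id[cand$hmm_score > cut])
    expect_setequal(res$rejected_decoys, cand$seq_id[cand$hmm_score <= cut])
  }
  # grdH rule: drop around 550, manual cutoff 500
  res <- select_true_positives(
    data.frame(seq_id = c("a", "b", "c", "d"),
               hmm_score = c(700, 560, 501, 499), coverage = 1),
    manual_cutoff = 500)
  expect_setequal(res$accepted, c("a", "b", "c"))
})

test_that("degenerate candidate sets are handled", {
  eq <- data.frame(seq_id = c("a", "b", "c"), hmm_score = c(300, 300, 300),
                   coverage = 1)
  res <- select_true_positives(eq, manual_cutoff = 100)
  expect_setequal(res$accepted, c("a", "b", "c"))
  expect_length(res$rejected_decoys, 0)
  one <- data.frame(seq_id = "a", hmm_score = 900, coverage = 1)
  expect_error(select_true_positives(one), "manual_cutoff")
  expect_error(select_true_positives(
    data.frame(seq_id = "a", hmm_score = 90, coverage = 1)), "admission")
})

test_that("cophenetic audit reports distances to the top scorer", {
  tree <- "((s1:1,s2:2):3,(s3:1,s4:5):1);"
  cand <- data.frame(seq_id = paste0("s", 1:4),
                     hmm_score = c(900, 800, 300, 200), coverage = 1)
  res <- select_true_positives(cand, tree = tree, manual_cutoff = 500)
  aud <- res$audit
  expect_equal(aud$distance_to_top[aud$seq_id == "s1"], 0)
  expect_equal(aud$distance_to_top[aud$seq_id == "s2"], 3)
  expect_equal(aud$distance_to_top[aud$seq_id == "s3"], 6)
  expect_error(select_true_positives(
    cand, tree = "((s1:1,s2:2):3,s3:4);", manual_cutoff = 500), "s4")
})

test_that("cophenetic distance is a path-length metric", {
  expect_equal(cophenetic_distance("((A:1,B:2):3,C:4);", "A", "B"), 3)
  expect_equal(cophenetic_distance("((A:1,B:2):3,C:4);", "A", "C"), 8)
  expect_equal(cophenetic_distance("((A:1,B:2):3,C:4);", "A", "A"), 0)
  expect_error(cophenetic_distance("((A:1,B:2):3,C:4);", "A", "Z"), "Z")
  set.seed(7)
  for (i in 1:10) {
    tr <- ape::rtree(sample(4:10, 1))
    tr$edge.length <- abs(tr$edge.length)
    tips <- sample(tr$tip.label, 3)
    d12 <- cophenetic_distance(tr, tips[1], tips[2])
    d21 <- cophenetic_distance(tr, tips[2], tips[1])
    d13 <- cophenetic_distance(tr, tips[1], tips[3])
    d23 <- cophenetic_distance(tr, tips[2], tips[3])
    expect_equal(d12, d21)                       # symmetry
    expect_gte(d13 + d23 + 1e-12, d12)           # triangle inequality
    expect_equal(d12, coph_oracle(tr, tips[1], tips[2]), tolerance = 1e-10)
  }
})

bai_ann <- function(loci, syms) {
  all_loci <- sort(unique(c(loci, setdiff(1:200, loci))))
  data.frame(locus_index = all_loci,
             gene_symbol = ifelse(all_loci %in% loci,
                                  syms[match(all_loci, loci)], "hyp"),
             stringsAsFactors = FALSE)
}

test_that("bai synteny rule counts distinct symbols within bounded runs", {
  # 4 genes within separation <= 10: carrier
  a <- bai_ann(c(100, 105, 109, 111), c("baiA", "baiB", "baiC", "baiE"))
  expect_true(is_bai_carrier(a))
  # gaps of 20: no run
  b <- bai_ann(c(100, 120, 140, 160), c("baiA", "baiB", "baiC", "baiE"))
  expect_false(is_bai_carrier(b))
  r <- find_bai_operons(b)
  expect_true(all(!r$qualifies))
  # 4 records but only 3 distinct symbols: not a carrier
  c3 <- bai_ann(c(10, 12, 15, 18), c("baiA", "baiA", "baiB", "baiC"))
  expect_false(is_bai_carrier(c3))
  expect_equal(find_bai_operons(c3)$n_symbols, 3L)
})

test_that("synteny is invariant to interleaved non-bai genes", {
  loci <- c(50, 57, 63, 70)
  syms <- c("baiA", "baiB", "baiC", "baiD")
  sparse <- data.frame(locus_index = loci, gene_symbol = syms,
                       stringsAsFactors = FALSE)
  dense <- bai_ann(loci, syms)  # every intervening locus annotated
  expect_equal(is_bai_carrier(sparse), is_bai_carrier(dense))
  expect_equal(find_bai_operons(sparse)$n_symbols,
               find_bai_operons(dense)$n_symbols)
})

test_that("reference database assembly counts, medians and round trip", {
  aa <- function(n) strrep("M", n)
  genes <- rbind(
    do.call(rbind, lapply(1:3, function(g) data.frame(
      ref_id = paste0(hkg_symbols(), "_g", g), genome_id = paste0("g", g),
      genus = "GenusA", gene_symbol = hkg_symbols(),
      sequence = aa(300), decoy = FALSE, stringsAsFactors = FALSE))),
    data.frame(ref_id = c("cutC_a", "cutC_b", "dec_1"),
               genome_id = "g1", genus = "GenusA",
               gene_symbol = c("cutC", "cutC", "grdB_like"),
               sequence = c(aa(400), aa(600), aa(100)),
               decoy = c(FALSE, FALSE, TRUE), stringsAsFactors = FALSE))
  db <- assemble_reference_db(genes)
  expect_equal(nrow(db$meta), 12L)
  expect_length(db$seq, 12L)
  expect_equal(unname(db$median_len["cutC"]), 500)
  expect_equal(sum(db$meta$decoy), 1L)
  # symbol outside every pathway definition is warned about and decoyed
  genes2 <- genes; genes2$decoy <- FALSE
  expect_warning(db2 <- assemble_reference_db(genes2), "grdB_like")
  expect_true(db2$meta$decoy[db2$meta$gene_symbol == "grdB_like"])
  # no decoys is valid
  db3 <- assemble_reference_db(genes[!genes$decoy, ])
  expect_false(any(db3$meta$decoy))
  # duplicate ref_id rejected
  expect_error(assemble_reference_db(rbind(genes, genes[1, ])), "duplicate")
  # write -> read is bit-exact on metadata
  dir <- withr::local_tempdir()
  write_refdb(db, dir)
  db_rt <- read_refdb(dir)
  expect_identical(db_rt$meta, db$meta)
  expect_equal(as.character(db_rt$seq), as.character(db$seq))
  expect_identical(db_rt$median_len, db$median_len)
})

test_that("selenoprotein references keep U and score only against U", {
  m <- blosum62u()
  expect_equal(m["U", "U"], 4L)
  expect_true(all(m["U", setdiff(colnames(m), "U")] < 0))
  tpl <- get_templates()
  expect_equal(substr(tpl[["grdH"]], nchar(tpl[["grdH"]]),
                      nchar(tpl[["grdH"]])), "U")
})
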