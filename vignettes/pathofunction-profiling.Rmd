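---
title: "Quantifying microbiota pathofunctions from metagenomes and metatranscriptomes"
author: "pathofun"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying microbiota pathofunctions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathofun)
```

## The problem

Some functions of the commensal gut microbiota can damage their host when
expressed over long periods or at high levels: choline and carnitine
degradation to trimethylamine (TMA, the precursor of pro-atherogenic TMAO),
7&alpha;-dehydroxylation of primary bile acids to deoxycholic/lithocholic
acid (DCA/LCA), and sulfate/sulfite reduction to hydrogen sulfide.  These
"pathofunctions" are spread across taxonomically distant organisms, so a
gene-targeted, function-centric readout is more informative than taxonomic
profiling.  `pathofun` quantifies them from shotgun DNA (metagenome, MTG)
and cDNA (metatranscriptome, MTX) reads via curated marker-gene reference
databases:

* TMA formation: `cutC`/`cutD` (choline TMA-lyase + activator),
  `cntA`/`cntB` (carnitine oxygenase/reductase), `grdH` (betaine
  reductase &beta;-subunit, a selenoprotein), each quantified separately;
* DCA/LCA formation: the nine-gene bile-acid-inducible (bai) operon
  `baiA`&ndash;`baiI`;
* H<sub>2</sub>S formation: `dsrA`/`dsrB` (dissimilatory sulfite
  reductase).

## The estimator

Reads passing quality control (mean Phred &ge; 20, length &ge; 70) are
assigned to reference proteins by six-frame translated local alignment
(Smith&ndash;Waterman, BLOSUM62, gap open 11 / extend 1, the blastx
conventions).  A read's single top-scoring hit is recorded only if the
alignment covers at least 20 amino acids at 70% identity or better.
Per gene symbol, read counts are divided by the median reference length
of the symbol (gene-length correction).  The abundance of a pathofunction
in a sample is then

$$
A_P \;=\; 100 \times
\frac{\operatorname{median}_{g \in P} \; c_g}
     {\tfrac13 (c_{rplB} + c_{recA} + c_{pyrG})}
$$

where $c_g$ is the length-corrected count of gene $g$.  Because every
bacterial genome carries exactly one copy of each of the three
housekeeping genes (HKG) `rplB`, `recA`, `pyrG`, the denominator measures
"total genomes in the sample", and $A_P$ reads as *the percentage of
community genomes carrying pathofunction P*.  On RNA samples the same
formula yields relative *expression*.  A pathway counts as present only
when all of its member genes are detected; for the nine-gene bai operon
the cutoff is four genes.  Genus-resolved tables use the cumulative
(summed) counts of all of a genus's member genes over the same HKG
denominator, without a presence rule.

Two safeguards transfer directly from the screening design:

* **Decoys.** Sequences related to, but functionally distinct from, a
  target family (e.g. glycine/sarcosine reductase relatives of `grdH`,
  or below-cutoff screen candidates) stay in the search database.  They
  absorb reads that would otherwise land on the nearest true reference
  and are excluded from counting.
* **Score-drop cutoffs with a phylogenetic audit.** Candidate screens are
  admitted at profile score > 100 and &ge; 80% model coverage; the
  true-positive cutoff sits in the largest gap of the descending score
  curve (`select_true_positives()`), overridable manually -- for the grdH
  family the conventional manual cutoff is 500, just below the score
  drop near 550.
  The function reports each candidate's cophenetic distance to the
  top-scoring sequence so the expected score/distance monotonicity can be
  audited by eye; we deliberately expose this as a report, not a hard
  filter: the check is a curation aid, not an objective rule.
* **Synteny for the bai operon.** A genome counts as a bai carrier when
  at least four *distinct* bai gene symbols occur with consecutive locus
  separations of at most ten annotation positions.  We count distinct
  symbols (so paralogous repeats cannot qualify a genome) and measure
  separation between consecutive bai genes in locus order, the most
  conservative reading of the rule; locus position is the integer rank in
  the annotation table because locus-tag string formats vary.

## Statistics

The association battery mirrors standard microbiome practice: Welch's
t-test on $\log(x+1)$ abundances with `*` (p < 0.05) and `+` (p < 0.1)
tiers; Mann&ndash;Whitney U tests (exact by enumeration when both arms
have &le; 8 samples, normal approximation with tie correction otherwise)
with Benjamini&ndash;Hochberg control within a declared family;
Spearman correlations (t-approximation p-values); rank-based AUC;
random-intercept logistic models `disease ~ log(abundance+1) +
(1|dataset)` fitted by Laplace-approximated ML (lme4), falling back to
ordinary logistic regression for single-dataset diseases; and a binomial
GLM of presence/absence on omics level with log total reads as an offset,
to compare MTG and MTX detection at unequal sequencing depth (with a
Firth-style penalized fit under complete separation).  RNA/DNA
expression ratios use only sample pairs positive at both levels and
report the median; with no valid pair the ratio is undefined (NA), never
zero.  Temporal variability between two time points is
$100\,|v_1-v_2|/\max(v_1,v_2)$, from 0% (no change) to 100% (absent at
one time point); it is symmetric, scale-invariant, and undefined when
both values are zero.

The co-occurrence network connects two entities when their abundances
correlate within a dataset (Spearman rho strictly > 0.35, p < 0.05 and
BH q < 0.05 over all pairs of that dataset) in at least three datasets;
edge width is the number of supporting datasets and node size the median
abundance over all samples, zeros included (medians over detected-only
samples would inflate rare entities).  Negative correlations never form
edges -- the support rule is signed -- though the mean rho is kept as edge
metadata.  Cohorts with overlapping samples can be merged before
correlation via the config's merge map.

## What the simulator emulates

`community_spec()` / `make_genomes()` / `sample_reads()` generate
communities with known ground truth: every genome carries exactly one
copy of each HKG; a controllable fraction carry pathway genes (bai
carriers receive all nine genes in a synteny-valid run); gene sequences
are mutated copies of per-genus reference variants (defaults: 12%
amino-acid divergence between a genus variant and the family template,
3% between a genome and its genus variant -- within the span where the
70% identity threshold retains essentially all reads).  Back-translation
uses translation table 11 with uniform synonymous codons, since the
search operates on translated reads and codon bias is irrelevant.  The
bulk of each genome (40 hypothetical 300-aa genes plus short intergenic
spacers) is invisible to the reference database, so most reads are
unassignable -- qualitatively mimicking real gut metagenomes where
pathway signal is a small fraction of reads.  DNA reads fall uniformly
along genomes (gene share proportional to length); RNA reads are drawn
from the pooled transcript population, i.e. jointly proportional to
genome abundance x gene length x expression multiplier, which makes the
RNA/DNA ratio estimator consistent with the recorded truth
(expression multiplier of the pathway over that of the HKGs).  Reads get
substitution errors at 0.2% per base and a homogeneous within-read Phred
quality drawn around mean 30 (sd 3); only the mean enters QC, so
within-read quality structure is deliberately not modelled.  Everything
is byte-deterministic under the seed.

What the simulator does *not* emulate -- and hence what green tests do
not certify about real data: instrument-specific error and quality
profiles, paired-end structure, within-species copy-number and strain
variation of the housekeeping genes, chimeric reads, and realistic
phylogenetic correlation structure between genera.  Parameter-recovery
results should be read as "the estimator is consistent and approximately
unbiased under its own sampling model", not as field calibration.

`make_study()` generates multi-cohort case/control designs at the truth
level (lognormal per-sample abundance with dataset random intercepts and
multiplicative disease effects), optionally with reads;
`simulate_association()` draws labels directly from the random-intercept
logistic model so that the mixed model's fixed effect has a known true
value.

## Numerical and design choices

* **"Similarity" = percent identity** over alignment columns (gaps count
  as columns), the blastx `pident` semantics; a `positives` metric
  (fraction of positive-scoring columns) is available via
  `metric = "positives"`, since "70% similarity" thresholds in this
  field are sometimes computed over positives rather than identities.
* **Tie-breaking** in top-hit assignment: highest score, then highest
  identity, then longest alignment, then lexicographically smallest
  reference id -- output is fully deterministic.  One read contributes at
  most one count.
* **Seed prefilter.** Exact amino-acid 6-mer seeds restrict alignment to
  candidate references (the role a seeded aligner plays at scale);
  `prefilter = FALSE` aligns all pairs.  At the simulated divergence
  levels the two paths produce identical hit tables; the tests assert
  this equality.
* **bai median.** For a bai detection passing the four-gene presence rule
  the abundance median is taken over the *detected* member genes
  (default).  Taking it over all nine members (option
  `median_over = "all"`) zeroes any 4-of-9 detection -- which would
  contradict the presence rule -- so the detected-gene median is the
  default and the all-member median the stricter option.
* **Welch test degeneracies.** If both arms are constant the test is
  undefined; we report p = 1 when the constants agree and p = 0 under
  exact separation, flagged either way.
* **Selenocysteine.** grdH references retain the terminal U; the
  alignment matrix scores U/U as +4 and U against anything else as -4.
* **HKG denominator.** The per-sample mean of the three per-symbol
  corrected counts, each aggregated over all genomes (carrier and
  non-carrier alike).  Samples with no HKG signal are flagged and
  reported NA rather than 0.
* **GLM offset.** "Adjusting for depth" is implemented as log(total
  reads) added to the linear predictor of the binomial presence model;
  this is the standard way to put detection probabilities on a common
  depth scale in a binomial model, and it is exposed as a modeling
  choice.
* **FDR families.** BH within dataset (network and genus tests) --
  configurable; the family definition is a genuine analysis choice.
* **Problem sizes.** The test suite and the acceptance script simulate
  50-genome communities at 200,000 reads for parameter recovery (the
  point where Poisson noise at 1% true abundance is a few percent),
  40,000-read matched MTG/MTX pairs for expression ratios, and
  12 x 200 samples for mixed-model recovery; these sizes make the
  checks sharp while keeping a full run in minutes on one core.

## Worked example

```{r example, eval = FALSE}
library(pathofun)

db <- template_refdb()                       # synthetic multi-genus references
spec <- community_spec(n_genomes = 20, carrier_fraction = c(cutCD = 0.2),
                       n_reads = 2e4, seed = 7)
genomes <- make_genomes(spec, db)
truth_table(genomes)$pathway                 # ground truth, % of genomes

reads <- filter_reads(sample_reads(genomes, "MTG"))
hits  <- assign_top_hits(reads, db)
ab    <- pathway_abundance(count_genes(hits, db, "s1"), db)
ab                                           # estimated % of genomes

## or in one step, with provenance:
cfg <- pipeline_config(seed = 7, simulate = list(
  n_samples = 1, n_genomes = 20, n_reads = 2e4,
  carrier_fraction = c(cutCD = 0.2)))
res <- run_pipeline(cfg, "pathofun_out")
```

## Known limitations

The aligner is exact but desk-scale: hundreds of thousands of reads
against hundreds of references, not billions against millions
(`read_hits()` accepts precomputed outfmt-6 tables from an external
aligner for that regime).  HKG copy-number variation and genome-size
correction beyond gene length are out of scope.  E-values are not
computed; thresholds are alignment-length and identity based, as in the
screening design.  Local-FDR q-values are replaced by
Benjamini&ndash;Hochberg throughout: BH is deterministic, standard, and
free of density-estimation tuning; q-values from the two methods are not
numerically interchangeable, which matters only when comparing absolute
q-values across analyses that define FDR differently.
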