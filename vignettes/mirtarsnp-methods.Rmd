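---
title: "Methods: models, parameters and design choices in mirtarsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mirtarsnp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mirtarsnp` asks whether single-nucleotide differences between two genotype
groups of the same species create or destroy miRNA–mRNA interactions, and
whether degradome evidence supports the surviving calls. This vignette
documents the models behind each stage, the tunable parameters with their
defaults and rationale, the numerical conventions, what the synthetic-data
generator does and does not emulate, and the package's known limitations.

## Duplex scoring

Plant miRNA target recognition is close to sequence-complementary, which
the field has long summarized as a position-weighted penalty over the
duplex. `score_duplex()` pairs miRNA position $i$ (counted from the miRNA
5′ end) with the site base opposite it, the site being read 3′→5′ against
the miRNA. Penalties:

| event               | penalty | doubled in core? |
|---------------------|---------|------------------|
| Watson–Crick pair   | 0       | —                |
| G:U wobble          | 0.5     | yes              |
| mismatch            | 1.0     | yes              |
| bulged base (≤ 1)   | 1.0     | yes              |

The core is miRNA positions 2–13 (`core_start`, `core_end`), covering the
seed and the cleavage-critical center; a reported site needs total penalty
≤ `cutoff` (default 4.0). All parameters live in `score_params()` and every
downstream stage takes them explicitly. The published tools this scheme
descends from differ in detail and none fully specifies its constants;
these values were chosen because they are the classical plant-scoring
lineage and, critically, the whole scheme is small enough to verify by
exhaustive enumeration of all ≤1-bulge alignments, which the test suite
does on hundreds of random duplexes.

Two conventions needed fixing where the scheme is silent:

* **Site-bulge position.** The result stores one state per alignment
  column. A site base bulged between miRNA positions $k-1$ and $k$ takes
  effective miRNA position $\min(k, m)$ for core doubling; columns after
  the bulge sit opposite miRNA position (column − 1). The enumeration
  oracle in the tests implements the same convention independently.
* **Tie-breaking.** Among equal-score alignments the bulge-free one wins,
  then the smallest bulge index. Among overlapping reported windows,
  `find_sites()` keeps the lowest score, then the leftmost window.

The inferred cleavage position is the transcript base opposite miRNA
position 10 (`site_end − 9` when bulge-free). A bulge at miRNA positions
9–11 makes the coordinate ambiguous by one base; the call is then flagged
`approximate` rather than suppressed. All reported coordinates are
1-based; intervals handled internally are 0-based half-open.

## Hairpin discovery

The annotation chain mirrors standard small-RNA practice: reads of
16–30 nt that match no exclusion sequence exactly are assigned to
reference matures by Hamming distance ≤ 2 (no indels — the mismatch
allowance is stated without one); unassigned reads with ≤ 15 exact genome
matches (both strands, overlapping occurrences counted) are evaluated as
novel-miRNA candidates. All three thresholds are exposed as arguments and
enforced as hard rules in directed tests.

Folding uses Nussinov maximum base pairing over {A:U, G:C, G:U} with a
minimum loop of 3. A thermodynamic model would be the conventional choice;
maximum pairing was picked because it is deterministic, parameter-light,
and exactly checkable against brute-force enumeration of nested pairings —
and because `parse_dotbracket()` provides an import hook for structures
computed by any external folder, so the choice is not load-bearing.

For each genomic match both flanking windows (read ± `window`, default
200 nt) are folded and judged by community-style precursor criteria: the
mature must lie on one arm (no internal pairing, partners on one side),
have at most 4 unpaired bases, and the precursor must be ≥ 50% paired. Two
practical complications surfaced and shaped the implementation:

* Maximum pairing on a window with 200 nt of flanking context happily
  pairs the mature with that context, and the reverse complement of a
  hairpin is itself a hairpin, so the fold alone cannot orient a locus.
  Candidate windows are therefore ranked by miRNA\* support first, then by
  fewer unpaired mature bases, then by total pairing.
* The predicted miRNA\* is the segment pairing the mature with 2-nt 3′
  overhangs. Rather than extrapolating from a single anchor pair, every
  paired mature base proposes an interval; a proposal must contain the
  majority of the mature's pairing partners (guarding against isolated
  misassigned pairs nominating far-away intervals), and is accepted only
  if an observed read equals it exactly (`end_slop` relaxes the ends if
  asked). Loci whose mature read is itself the passenger strand of an
  already-annotated duplex are collapsed into that locus.

A locus with miRNA\* support and no reference assignment is
`specific_with_star`; without support it stays `specific_candidate`.
Reference-assigned loci are `conserved` or `known` according to a
user-supplied family table, since the boundary between the two is a
curation decision, not a computable one. Expression is reads per million:
`count * 1e6 / library_total`.

## Nucleotide diversity and its null

`pi_from_haplotypes()` is the definition: mean pairwise per-site
difference, excluding columns with non-ACGT characters from numerator and
denominator. `pi_from_variants()` is the estimator used at scale:

$$\pi = \frac{1}{L}\sum_{s} \frac{n_s}{n_s - 1}\Big(1 - \sum_a p_{a,s}^2\Big)$$

with $n_s$ the non-missing allele count at site $s$ and $L$ the **full**
interval length (monomorphic sites count — this keeps π on the per-site
scale diversity figures are reported on). The two estimators agree exactly
on complete haplotype matrices, which the suite property-tests to 1e-12;
with missing data they intentionally differ (the haplotype version drops
the column for everyone, the variant version adjusts $n_s$), so
missingness behavior is tested per function.

Locus classes are built by `classify_loci()`: mature, precursor and
±2000-nt flank intervals per provenance group (conserved/known vs
specific), binding sites lifted from transcript to genome coordinates
through gene models (unliftable sites are counted and skipped), and the
genome background. Overlaps within a class are merged.

Significance is a length-matched permutation test: `n_perm` random
interval sets matched in number and length to the class (uniform placement,
chromosomes weighted by valid start positions), one-sided
$p = (1 + \#\{\pi_{null} \le \pi_{obs}\})/(n_{perm}+1)$. The add-one form
keeps $p > 0$ and makes the test exact under exchangeability; the suite
verifies calibration by drawing the "class" from the same process as the
null over 400 simulated datasets and checking the α = 0.05 rejection rate
against its binomial confidence interval. Seeds are explicit and recorded
in the output table.

## SNP impact

Group-specific sequences are rebuilt from the group-major allele (within-
group frequency > 0.5). For mature miRNAs, genomic SNPs are lifted to
mature-local coordinates strand-aware (minus-strand alleles complemented)
and multi-SNP haplotypes are enumerated jointly up to a cap of 8; a 50/50
tie yields both haplotypes for miRNAs but leaves transcripts at the
reference allele, since an unresolved major allele is no basis for
rewriting an mRNA. Degenerate IUPAC alleles are expanded to their base
sets at parse time, each expanded base taking an equal share of the
allele count; how such calls arise (heterozygotes vs ambiguity codes) is a
property of the upstream caller, so the expansion is a documented
convention rather than an inference.

Target sets computed under both allele sets are diffed per (miRNA,
transcript): sites matched by any interval overlap are `conserved`
(overlap rather than exact coordinates, because a SNP can shift the
optimal window by a base), reference-only sites are `disrupted`, and
alternative-only sites are `created`. A created site is accepted as a
genuine group-B target only if the best orthologue among group-B
transcripts — shortlisted by shared 12-mers, then ranked by global
alignment identity — exceeds 0.90 identity *strictly* and carries a site
for the same miRNA overlapping the alignment-lifted region. Global
alignment replaces a BLAST search because in the > 90%-identity regime a
single global alignment is the right tool and removes an external
dependency. A-unique targets are the disrupted set, B-unique the created
set; swapping the group labels swaps the counts exactly.

## Degradome confirmation

Tags map by exact match (degradome tags are transcript-derived prefixes;
exact coordinates are the point). Categories follow the CleaveLand
convention relative to the profile maximum $M$ and the median over stored
(nonzero) positions — a config flag includes zeros, since the convention
is ambiguous on that point: 4 if $c = 1$; 0 if $c > 1$ and uniquely
maximal; 1 if maximal but shared; 2 if median $< c < M$; 3 if
$1 < c \le$ median. The significance model is a binomial tail against
uniform placement, $p = P(X \ge c)$ with $X \sim \mathrm{Bin}(N,
1/(\mathrm{len} - \mathrm{tag\_len} + 1))$; a seeded resampling variant is
provided and agrees with the closed form to Monte Carlo accuracy in the
tests. `confirm_interaction()` searches ± 1 nt around the predicted
cleavage position and returns the lowest-category, then highest-count
call.

## The synthetic scenario

`make_scenario()` emulates the study design the pipeline is built for:
two genotype groups sharing one genome; hairpin loci expressed as
collapsed reads (passenger reads for half the loci); transcripts carrying
planted binding sites; fixed group-differentiated SNPs inside a subset of
sites; shared low-frequency background polymorphism; and a degradome
library peaked at the predicted cleavage positions.

Defaults — 2 × 12-kb chromosomes, 6 hairpins (21-nt matures, 15-nt
loops), 12 × 500-nt transcripts, 6 baseline sites, 3 A-unique + 2
B-unique + 1 neutral events, 5 diploid samples per group, background SNP
rate 10⁻³/bp, degradome peak fraction 0.5 of 40 tags — are one fixed
choice of a small but complete instance of that design: large enough that
every stage has work to do (both strands, both provenance classes, all
delta types, noise reads for every filter), small enough that the whole
pipeline runs in seconds. The per-event score margin around the cutoff is
1.0 on both sides, which is also the feasibility limit: a single base edit
changes the penalty by at most 2 (a core match→mismatch), so the generator
rejects margins above 1.

Planting is constructive and self-verifying. Binding sites start as the
reverse complement of the miRNA and receive a deterministic composition of
mismatch and G:U edits; edits avoid the duplex ends (terminal edits invite
equal-scoring bulged alignments that shift the reported window) and a
fractional half-unit reserves a G/T position for its wobble before
mismatches are placed. After planting, the local window is re-scanned and
the placement is redrawn until the planted window is also the locally
optimal one, so truth tables and `find_sites()` output cannot drift apart.
Impact events likewise re-scan the broken allele and retry elsewhere if a
bulged alignment undercuts the margin. Hairpins are verified against
`evaluate_hairpin()` in both directions (pass within the unpaired
tolerance, fail beyond it). All randomness descends from one root seed
through labelled child streams, and identical config + seed reproduces the
bundle byte-for-byte.

What the generator does **not** emulate: sequencing error and adapter
artifacts, expression-level realism, indels, linkage between background
SNPs, transcript splicing (gene models are single-exon, plus-strand), and
genome-scale repeat structure. Passing the planted-recovery tests
therefore shows the inference chain is correct under its stated model, not
that it is robust to every artifact of real libraries.

## Problem sizes used by the checks

The test suite runs the scoring oracle on 200 random duplex pairs and 25
brute-forced transcripts, the folding oracle on 500 sequences up to 14 nt,
the π equivalence on 200 random haplotype matrices, permutation
calibration on 400 simulated datasets at `n_perm = 199`, planted-event
recovery on 20 scenario replicates, the degradome oracle on all 5-position
profiles with counts ≤ 4 plus 500 peak replicates, and two full pipeline
runs for byte-determinism. These sizes were chosen so each check has clear
statistical teeth while the whole suite stays comfortably interactive.

## Known limitations

* Maximum-pairing folds over-pair long windows; orientation therefore
  leans on miRNA\* evidence, and loci without passenger reads can be
  annotated on either strand of a two-armed match. Import curated
  structures via `parse_dotbracket()` where this matters.
* Conserved/known assignment is Hamming-only; a reference set with
  length-variant matures will under-assign.
* The binomial degradome null ignores positional biases of real PARE
  libraries; the resampling variant shares the uniformity assumption.
* Indels are logged and excluded throughout; the pipeline is
  SNP-focused by design.
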