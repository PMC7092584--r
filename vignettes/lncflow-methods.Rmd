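---
title: "lncflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

lncflow re-implements, as a reusable and testable pipeline, the
discovery-and-integration analysis used in ruminant mammary-gland lncRNA
studies: candidate filtering of assembled transcripts, positional
classification against the coding annotation, linking to adjacent
protein-coding genes (apcGenes) and antisense partners, miRNA precursor
detection, differential expression between unreplicated pooled stage
libraries (E = early, P = peak, L = late lactation), term enrichment, and
assembly of a competing-endogenous-RNA (ceRNA) network. Raw-read processing
(trimming, alignment, assembly), external coding-potential classifiers,
covariance-model family assignment, cross-species BLAST conservation and
miRNA target *prediction* are out of scope: targets arrive as an input
table, and protein evidence arrives as a pluggable exclusion list.

Everything downstream of assembled transcripts is testable without any
download because the package ships a synthetic-data generator that plants
machine-readable ground truth for every stage.

# Coordinate model

All internal coordinates are 0-based half-open `[start, end)` on a named
scaffold with a mandatory strand. GTF (1-based inclusive) and BED (0-based
half-open) conventions are converted only at I/O boundaries, so no module
ever reasons about conventions. Transcripts with strand `"."` are rejected
at parse time with a warning: every positional class is defined in terms of
strand, so an unstranded transcript has no well-defined classification.

# The filter cascade

Candidates pass seven screens in a fixed order; each removal is attributed
to the *first* failing rule, and every rule is a pure per-transcript
predicate, so the retained set is independent of rule order (only the
attribution changes).

| step | rule | boundary semantics |
|------|------|--------------------|
| 1 | exon overlap with a coding exon on the same strand | known lncRNAs bypass |
| 2a | spliced length | removed if `< 200` bp (200 kept) |
| 2b | exon count | removed if single-exon |
| 2c | read coverage, max over libraries | removed if `< 0.8` (0.8 kept) |
| 2d | FPKM, max over libraries | removed if `< 0.1` (0.1 kept) |
| 3 | longest ORF, six frames | removed if `> 100` aa (100 kept) |
| 4--5 | protein-evidence exclusion list | listed ids removed |
| 6 | scaffold-end margin | removed if `< 2000` bp from either end |
| 7 | optional poly(A) gate | **off by default** |

Notes on the deliberately interpretive points:

* *Read coverage* is taken as the fraction of the transcript covered by
  reads, supplied per transcript per library in the expression table; the
  aligner-derived quantity is out of scope and the screening literature does
  not define it further. The threshold applies to the per-library maximum:
  a transcript adequately expressed in *any* stage survives, matching the
  goal of cataloguing lncRNAs expressed in at least one lactation stage.
* Step 1 would contradict the existence of a reported sense-lncRNA class if
  it applied to everything; the package resolves this by letting transcripts
  annotated as known lncRNAs bypass the sense-overlap removal. This is a
  reading, and it is configurable (`drop_sense_exon_overlap`).
* The published step 7 is not interpretable as printed ("transcripts with
  aaaaa were retained"), so it is implemented as an optional boolean
  poly(A)-evidence gate that is inert unless explicitly enabled.
* Steps 4--5 (external coding-potential tools and protein-database hits)
  collapse into one exclusion list, preserving the contract — drop
  transcripts with protein evidence — without re-implementing CPC/CNCI.

The ORF scanner counts codons from `ATG` up to but excluding the stop, over
three forward frames and three reverse-complement frames; ORFs running off
the end are not counted, and a codon containing `N` is treated as neither a
start nor a stop (it extends an open frame). The test suite checks the
scanner against a naive per-position enumeration oracle.

# Positional classification

Classes are assigned by a fixed priority — sense > antisense > intronic >
bidirectional > intergenic — because the five literature categories are
"loose" and overlapping; exon-level evidence is the strongest signal and a
fixed order turns the catalogue into a testable partition. Specific
decisions:

* minimum overlap to count is 1 bp (no threshold is stated anywhere);
* *intronic* requires the full lncRNA span inside a single intron and
  accepts either strand (the intronic definition, unlike sense/antisense,
  does not mention strand);
* *bidirectional* requires no span overlap with any coding gene, opposite
  strands, divergent (head-to-head) orientation, and TSS distance strictly
  below a 1000-bp window. The published definition is expression-based and
  not operational; 1 kb is the conventional divergent-promoter distance and
  the window is a config knob (`bidirectional_window`);
* ties inside a rule break to the lexicographically smallest gene id.

apcGenes are the nearest non-overlapping coding gene on each side within
10 kb, *inclusive* at exactly 10,000 bp (10,001 yields no link), measured
span-end to span-start (gene-body gap, not TSS-to-TSS). Genes overlapping
or abutting the lncRNA are never apcGenes — overlap already produces
sense/antisense/intronic evidence. Sides are reported in the lncRNA's
reading orientation (the 5′ neighbor is upstream).

A note on the strand-antisymmetry property checked in the tests: flipping
the strand of the lncRNAs swaps sense and antisense and leaves intronic and
intergenic untouched. (Flipping *both* genes and lncRNAs would leave
relative orientation — and hence every label — unchanged, and bidirectional
lncRNAs become convergent under a flip, so neither is asserted.)

# Duplex scoring and precursor matching

The thermodynamic duplex predictor used in the original analysis is
replaced by an explicitly parameterized complementarity alignment so scores
are reproducible bit for bit: a local (Smith–Waterman, Gotoh affine-gap)
alignment of the lncRNA against the reverse complement of the mRNA with
pair scores G:C `+3`, A:T `+2`, G:U wobble `+1`, mismatch `-2`, gaps
`-3`/`-1`, reporting threshold 40. The pairing relation is symmetric, so
the score is invariant under swapping the two sequences. The engine is a
single small C++ routine with full traceback; an independent pure-R dynamic
program serves as the test oracle.

Precursor matching aligns each lncRNA against each hairpin (both
orientations, best kept) under match `+1`, mismatch `-1`, gap `-2`.
`identity` = matches / alignment columns (gaps included); `coverage` =
aligned hairpin positions / hairpin length. A hit requires identity
`>= 0.90` and coverage strictly `> 0.90`, reading the two published screens
("identity ≥ 90 %", "comparison coverage greater than 90 %") literally. At
these thresholds the empirical false-positive rate on random 1-kb vs 80-nt
sequences is zero in the test suite's null checks.

# Differential expression without replicates

The stage libraries are pooled singletons, so no replicate variance is
estimable and a dispersion-based package cannot be fit honestly. lncflow
instead defines its own exact conditional test (the Audic–Claverie
construction): conditional on `t = x + y`, `x ~ Binomial(t, Na/(Na+Nb))`
under the null; the two-sided p-value sums all outcomes with probability
mass no larger than the observed one, with `p(0,0) = 1`. This is a
documented divergence from the original analysis — no numerical agreement
with a dispersion-based tool is claimed. Benjamini–Hochberg adjustment is
applied within each contrast (per-contrast DE counts are the reported
quantity), and a transcript is called when `q <= 0.05` **and**
`|log2fc| >= 1`, both boundaries inclusive per the stated screening
conditions ("no more than", "no less than"). The fold change is FPKM-based
with pseudocount 0.01 (config knob) to handle zeros. Extremely significant
outcomes are floored at `p = 1e-300` to keep p-values in `(0, 1]` through
the BH step.

# Enrichment

One-sided upper-tail hypergeometric test per term, BH across terms. The
significance flag follows the published criterion (raw `p <= 0.05`), with
the q-value reported alongside — the source states both "Benjamini-
corrected" and "P-value ≤ 0.05", so both columns are emitted and the flag
follows the printed criterion. The background population defaults to all
genes in the annotation universe and is overridable; the original study's
background is unstated.

# ceRNA network

Admission rules, applied in a fixed, cycle-free order:

1. lncRNA nodes: per-library maximum read count strictly `> 10` and at
   least one apcGene or antisense link;
2. miRNA nodes: any miRNA (from the target table or a precursor hit) with a
   lncRNA-side connection to an admitted lncRNA;
3. mRNA nodes: differentially expressed in at least one contrast and linked
   (apc/antisense to an admitted lncRNA, or targeted by an admitted miRNA).

Edges are typed (`mirna_targets_mrna`, `mirna_targets_lncrna`,
`lncrna_precursor_of_mirna`, `apc`, `antisense`); sponge-target and
precursor links are distinct types so a sponge-only graph can be extracted.
"Core model scoring" is undefined in the source; because the stated role of
core miRNAs is *connecting lncRNAs and mRNAs*, the hub score is the number
of distinct (lncRNA, mRNA) pairs a miRNA bridges (lncRNA neighbors ×
mRNA neighbors), with plain degree centrality available behind a flag. The
published "1290 pairs" selection is not fully specified beyond these
screens; only the stated screens are implemented.

# The synthetic world

`simulate_dataset()` emits a complete dataset — GTF, transcript and hairpin
FASTA, expression TSV, evidence/target/term tables — plus a ground-truth
JSON, deterministically from one seed (one seed, one byte stream). What it
emulates, and the fixed choices behind it:

* **Geometry.** Coding genes (three exons over 8 kb) occupy fixed offsets
  inside 20-kb slots laid out across scaffolds; planted lncRNAs sit at
  offsets that respect the classifier's decision margins with room to
  spare — sense/antisense overlap the middle exon, intronic lncRNAs sit
  wholly inside the second intron, bidirectional lncRNAs start 401 bp from
  the gene TSS in divergent orientation, intergenic lncRNAs are > 10 kb
  from any gene — so the planted class is provably unambiguous and 100 %
  recovery is the correct expectation, not a lucky one.
* **Filter failures** are planted one rule each (a 150-bp transcript has
  good coverage, a low-coverage transcript has good length, and so on), so
  first-fail attribution must equal the planted rule exactly. For this
  reason only planted *coverage* failures draw coverage from
  Uniform(0, 0.8); other failures draw the retained range
  Uniform(0.85, 1).
* **Expression.** Counts are Poisson around depth-scaled expected
  abundances (log-normal weights, default depth 10^6 per library). No
  overdispersion: the emulated libraries are pooled singletons, for which a
  replicate-variance model is unidentifiable — and this matches the exact
  test's null, enabling a clean type-I-error check. Planted fold changes
  (default |log2fc| = 2, up/down alternating) multiply the *expected*
  count in library P without renormalizing, so the planted count ratio is
  exact in expectation; L mirrors E. FPKM is computed from realized counts
  and spliced lengths by the standard definition.
* **Sequences** are i.i.d. uniform ACGT — the null model for duplex and
  precursor false-positive checks — except planted features: hairpins
  embedded verbatim (or with evenly spaced substitutions at 15 % for
  planted rejections) at a recorded offset, a 149-aa ORF in planted ORF
  failures, and stop codons inserted to break any accidental ORF above
  100 aa in transcripts meant to survive the filter (the protected hairpin
  region is never touched).
* **Wiring.** Target rows connect planted triple miRNAs to one
  bidirectional lncRNA (guaranteed an apcGene link and high counts, hence
  admitted) and one planted-DE gene each, plus one hub miRNA wired to two
  lncRNAs and three genes so the planted hub outranks every triple miRNA.
  Enriched terms annotate exactly the planted-DE genes.

What the generator does **not** emulate — hence what a green test does not
establish: alignment and assembly artifacts, isoform ambiguity,
overdispersed biological replication, realistic sequence composition
(repeats, GC structure, real hairpin stems), and genome-scale gene density.
Green tests establish that the *rules* are implemented exactly as stated,
not that the original study's counts are reproduced; those counts depend on
deposited raw data and external tools, and several are internally
inconsistent in print, so they are not targets.

# Numerical and degenerate-input choices

* Exact-test ties are compared with a `1 + 1e-7` relative tolerance so
  floating-point noise cannot drop an outcome from the two-sided sum;
  p-values are floored at `1e-300` and capped at 1.
* BH is the literal step-up formula (`cummin` on the sorted tail),
  validating inputs to `(0, 1]`.
* Alignment tie-breaks are deterministic: best cell chosen
  leftmost-in-`a` then leftmost-in-`b`, and the traceback prefers diagonal
  over gap-in-`b` over gap-in-`a`.
* An empty candidate set flows through the whole pipeline and produces
  header-only tables and a zero-count manifest with exit status 0.
* Classifier ties (several genes satisfying the same rule) break to the
  smallest gene id; apcGene ties at equal gap break the same way.
* Gap-0 (abutting) genes are not apcGene links: the link invariant is
  `0 < gap <= 10000`.

# Reproducibility

`run_all()` writes every stage table plus a `manifest.json` with per-stage
record counts, an md5 per output file and a config hash; input paths are
echoed as basenames so a rerun into a fresh directory with identically
named inputs is byte-identical, which the acceptance suite asserts. The
analysis stages are deterministic; the only stochastic component is the
generator, which derives everything from its single seed.
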