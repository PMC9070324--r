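---
title: "Extracting fungal communities from plant transcriptome assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting fungal communities from plant transcriptome assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mycosieve)
library(dplyr)
```

## The problem

A de novo transcriptome assembled from field-grown plant tissue is a mixture:
alongside the host's transcripts it contains transcripts of epiphytic and
endophytic microorganisms, fungi above all. Because assembly and
quantification are reference-free, these microbial transcripts survive every
upstream step and show up in annotation as puzzling "contaminants". This
package treats the mixture as a two-community sample and provides the
downstream half of the analysis: separating the fungal compartment, placing
it taxonomically, and profiling where and what it expresses. Upstream tools —
assembler, ORF caller, quantifier, aligners, domain scanners — are
deliberately out of scope; the package consumes their standard tabular
outputs (FASTA, extended BLAST tabular hits with subject lineages, TPM
matrices, annotation tables).

## Transcript-set construction

Assemblies report multiple isoforms per locus. `select_representative_isoforms()`
keeps, per locus, the longest isoform among those passing two gates: mean TPM
across all samples strictly greater than 1, and an annotated ORF length
passing 255 nt. Two boundary choices deserve a note:

* **ORF gate inclusive by default** (`>= 255`). A strict reading of "greater
  than 255" conflicts with retained sets whose minimum CDS length equals 255;
  the inclusive boundary reconciles the two, and `orf_strict = TRUE` restores
  the strict gate.
* **TPM gate over the mean of all samples.** Which samples feed the gate is
  underdetermined in common practice; the mean over all samples is the
  least surprising choice and is what the generator's truth tables assume.

Missing expression is treated as a failed gate and reported, never imputed as
zero. `assembly_summary()` reports the count, mean length, N50 (largest
length L such that transcripts of length ≥ L hold at least half of all
bases), and CDS length extremes.

## The two classifiers

**Separation stage.** `vote_host_vs_fungus()` ranks a transcript's hits by a
deterministic key — ascending E-value, then descending bit score, then
ascending subject id — discards hits with E-value above `1e-10`, and lets the
top 10 surviving hits vote. The transcript is fungal when at least 70% of the
voting hits carry a lineage containing the taxon name `Fungi` (exact match).
When fewer than 10 hits qualify, the vote is taken over all available hits
(`min_hits` controls the floor, default 1): discarding short hit lists would
silently drop genuinely fungal transcripts with few database relatives. The
rank key makes every vote reproducible regardless of input row order; ties
beyond (E-value, bit score) cannot occur because subject ids break them
lexicographically.

**Phylum stage.** `classify_phylum()` categorizes each voting hit by its
subject's phylum (Ascomycota / Basidiomycota / other, with a missing phylum
rank counting as other) and applies a consensus rule:

* `"unanimity"` (default): all voting hits Ascomycota → `ASCOMYCOTA`; all
  Basidiomycota → `BASIDIOMYCOTA`; no hit to either main phylum →
  `OTHER_FUNGI`; anything else → the ambiguous class `ASCO_OR_BASIDIO`.
* `"majority"`: a phylum is called when its fraction of voting hits reaches
  `majority_fraction`.

The strict default means that *any* discordant hit — including one outside
the two main phyla — demotes a call to the ambiguous class. We chose this as
the default because it makes the classifier's error structure transparent and
analyzable: under independent per-hit label noise ε, a unanimity call over
*N* hits succeeds exactly when all *N* hits keep the true label, so the
true-positive rate is (1−ε)^N in closed form — a property the benchmark suite
verifies directly. The lenient variant (`other_hits = "ignore"`), in which
hits outside the two main phyla do not break unanimity, is one flag away for
users who prefer recall over caution.

`partition_transcriptome()` composes the two stages; every transcript gets
exactly one call, fungal transcripts without qualifying phylum-stage hits are
reported and carry `NOT_APPLICABLE`, and the per-group counts always sum to
the fungal total.

**Genus assignment.** `assign_to_reference_set()` is a threshold filter: at
least one hit with E-value strictly below `1e-10` and query coverage strictly
above 0.70. Coverage uses the *query* as denominator throughout the package —
the natural reading when the question is "how much of this transcript is
explained by the reference" — with amino-acid alignment lengths converted to
nucleotide units (×3) on request (`alignment_units = "amino_acid"`).

## Benchmarking the classifier

`build_benchmark_sets()` draws a labeled query set (defaults: 2,000
Ascomycota + 700 Basidiomycota) from a labeled pool without replacement and
returns the remainder as the reference — self-exclusion, so a query can never
match itself. For a rule-based classifier there is nothing to train, so the
full query set is used for evaluation only. `evaluate_classifier()` computes
one-vs-rest confusion matrices per class; queries called into the ambiguous
or not-applicable classes count as negatives for every real class, the
standard one-vs-rest convention. `sweep_parameters()` crosses E-value cutoffs
(default `1e-10`, `1e-20`) with top-N values and reports TPR/FPR per class,
sorted deterministically.

## Tissue specificity

SPM for tissue *t* is the cosine of the replicate-mean expression vector with
that tissue's unit vector, `x_t / sqrt(sum(x^2))`. It is scale-invariant and
its squares sum to one, so at most one tissue can exceed 1/√2 and a call at
the default threshold SPM > 0.95 (strict) is unique. All-zero transcripts
have no profile; they are dropped with a message rather than given an
arbitrary value, and downstream calls treat them as not specific.

## Enrichment

`hypergeometric_enrichment()` tests each term's over-representation in a
group against a custom background with the upper-tail hypergeometric
probability, computed by `stats::phyper`; the test suite checks it against
exhaustive enumeration of all draws for every background size up to 12. The
default is the raw-p convention (p < 0.05, no correction) for compatibility
with common practice in community profiling; because testing dozens of terms
uncorrected is anticonservative, `correction = "BH"` applies
Benjamini–Hochberg and flags significance on adjusted values instead. The
test is one-sided (enrichment only).

A calibration helper, `calibrate_enrichment_null()`, repeats a no-signal
enrichment analysis and reports the fraction of terms at raw p < α. Two
facts shape its defaults. First, the hypergeometric statistic is discrete:
for rare terms the attainable p-values are coarse and the test is
conservative, so the null fraction falls visibly below α (we measure ~0.041
at a 3–4,000-transcript background with 1–10% term frequencies). Second, the
discreteness vanishes as counts grow. The calibration defaults therefore use
a transcriptome-scale background (30,000 transcripts, group of 15,000, 30
terms at 30–60% frequency, 200 analyses), where the statistic is effectively
continuous and the null fraction sits within Monte-Carlo error of α. The
conservatism at small backgrounds is a property of the exact test, not a
defect of the implementation; users testing rare terms should expect fewer
than α·(number of terms) false positives.

## Threshold filters

`filter_transporter_hits()` retains a transcript when its *best-ranked* hit
passes E ≤ 1e−5 and coverage ≥ 0.70 (both inclusive, "at least"); the family
label comes from that hit, with ties resolved by the rank key.
`summarize_secreted_cazymes()` crosses CAZy class prefixes (GH, GT, PL, CE,
AA, CBM) with phylum groups for transcripts whose signal-peptide score is
strictly above 0.5; a transcript with several families of one class counts
once per class. `community_summary()` reports percentage shares (phylum
groups, genus assignment, HSP annotation) at full precision, leaving rounding
to presentation. The genus denominator is a parameter (`total_fungal` by
default, `ascomycota` as alternative) because either convention appears in
practice.

## The synthetic-data generators

Every input the pipeline consumes can be generated with known truth:

* `generate_transcripts()` — loci with representative isoforms passing both
  gates by construction, plus planted decoy isoforms (shorter but
  qualifying, TPM-failing, ORF-failing) that the filter must reject.
* `simulate_hit_table()` — per query, 1 + Poisson significant hits (capped)
  whose lineage matches the query's true category with probability 1−ε, plus
  binomial decoy hits with E-values above the significance range. E-values
  are log-uniform within stated ranges; bit scores decrease with E-value so
  the rank key is exercised.
* `generate_expression_matrix()` — tissue-specific transcripts concentrated
  in their tissue (mean 60 TPM vs 0.5 elsewhere; noise-free SPM ≈ 0.99996),
  balanced transcripts at 8 TPM, multiplicative mean-one log-normal
  replicate noise (sdlog 0.3).
* `generate_annotation_tables()` — per-term Bernoulli assignment with
  planted odds multipliers for enriched terms, Beta-distributed
  signal-peptide scores, HSP flags, CAZy families.
* `simulate_genus_hits()` — qualifying hits for true genus members,
  disqualifying or absent hits otherwise.

The default design emulates one study community at desk scale: 3,000 loci
with a 12% fungal compartment split 64/28/8 between Ascomycota,
Basidiomycota, and other fungi; three tissues × three replicates; 90% of
fungal loci root-specific and 27% of host loci tissue-specific, which puts
the fungal share of root-specific transcripts near 58%; a 12% genus rate
among Ascomycota and a 5.6% HSP rate. Benchmark-style designs raise
`hits_mean` above `hits_max` so every query votes with a full hit list, which
is what makes the (1−ε)^N closed form exact.

Determinism is strict: every generator is a pure function of (design, seed),
and `simulate_community()` splits one root seed into named per-generator
streams by a fixed affine scheme (`sub_seed()`), so components can be
regenerated independently. Two runs with the same seed produce byte-identical
files from `write_simulation()`.

**What the generators do not emulate.** Sequences are random nucleotides: no
codon structure, no homology between query and subject, no shared k-mers.
This is intentional — every downstream computation operates on hit tables and
annotations, not sequence content — but it means passing tests demonstrate
the correctness of the decision rules, not the behavior of upstream aligners
on real data. Hit-label noise is independent per hit, whereas real
misannotation is correlated within database clades; real TPM noise is
heavier-tailed than log-normal; and enrichment in real communities comes with
correlated term co-occurrence. Results on real data inherit the error
characteristics of the upstream tools.

## Problem sizes and numerical choices

The test suite validates each core against an independent oracle at sizes
chosen for exactness and speed: hypergeometric p-values against full
enumeration for all backgrounds up to 12; N50 against a brute-force oracle on
1,000 random multisets of up to 20 lengths; the voting rule against
enumeration of all vote tables up to 10 hits; SPM normalization on 10,000
random profiles to 1e−12; noisy-recovery TPR on 2,000 queries within three
standard errors of its closed form; null calibration over 200 analyses.
Degenerate inputs have defined behavior throughout: empty hit tables give
empty (not failing) results, zero-expression transcripts have no SPM profile,
empty transcript sets are an error for summaries that would divide by zero,
and every boundary (70% vote, SPM 0.95, coverage 0.70, score 0.5, ORF 255) is
pinned by a test on the exact threshold value.

## Limitations

* The package classifies from one hit table per stage; combining nucleotide-
  and protein-level evidence streams is left to the caller.
* Lineage matching is by exact taxon name (`Fungi`); synonyms or rank
  irregularities in user-supplied lineages must be normalized upstream.
* Terms are opaque strings: no ontology traversal, no term-term
  relationships.
* The bundled reference tables (`agave_community_tables()`) are printed
  summary statistics for consistency arithmetic; the package cannot (and
  does not try to) regenerate them from raw reads.
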