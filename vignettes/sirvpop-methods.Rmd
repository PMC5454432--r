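---
title: "Methods: comparative genomics and CRISPR biogeography of rudivirus populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative genomics and CRISPR biogeography of rudivirus populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`sirvpop` implements a population-genomic analysis of *Sulfolobus
islandicus* rod-shaped viruses (SIRVs, family *Rudiviridae*: lytic,
rod-shaped archaeal viruses with ~35 kb linear dsDNA genomes at ~26.5%
G+C) and the CRISPR immune records of their hosts. The pipeline has four
analytical layers:

1. **Pangenome** — homologous gene clusters from all-vs-all protein
   comparison, partitioned into a core genome (clusters present in every
   isolate) and a variable genome.
2. **Molecular evolution** — within-cluster codon alignments, Nei–Gojobori
   Pn/Ps, Jukes–Cantor distances under complete deletion, and a
   neighbor-joining tree on the concatenated core alignment.
3. **CRISPR interactions** — repeat-spacer array detection, spacer
   orientation, ungapped spacer-to-protospacer matching with whole-spacer,
   5′-half and seed identities plus PAM status, and immunity calls
   reconciled against observed plaque assays.
4. **Biogeography** — per-location match fractions, identity
   distributions, and the partition of matches over core / variable /
   non-coding genome regions.

A seeded synthetic-data generator produces virus populations and host
arrays with the statistical structure these analyses assume, together with
a ground-truth ledger, so the full pipeline is testable without any
downloads.

# Pangenome construction

ORFs are taken from the genome annotations (GFF CDS features); a naive
fallback caller (longest ORF of ≥ 60 codons per stop-to-stop segment,
ATG/GTG/TTG starts) exists for FASTA-only input, because reimplementing a
gene caller is out of scope and annotation-driven extraction makes cluster
counts well-defined.

Every protein pair is aligned with exact affine-gap Smith–Waterman
(BLOSUM62, gap open 11, extend 1; a gap of length $k$ costs
$11 + k$). Raw scores are converted to bits with the Karlin–Altschul form
$\mathrm{bits} = (\lambda S - \ln K)/\ln 2$ using the standard gapped
BLOSUM62/11-1 constants $\lambda = 0.267$, $K = 0.041$; these shift all
bit scores jointly and largely cancel in the ratio below. The ambiguous
residue X scores 0 against everything, so it neither attracts nor repels.

The similarity graph keeps an edge when the **bit-score ratio** — the
alignment bit score divided by the smaller of the two self-alignment bit
scores, a length-normalized similarity in $[0,1]$ — is at least 0.3. "Max
bit score" is read as the self-alignment bit score and the minimum of the
two is used so the ratio cannot exceed 1; this is the standard score-ratio
construction. Clusters are the attractors of **Markov clustering** on the
ratio-weighted graph: self-loops set to each node's maximum incident
weight, column-stochastic normalization, then repeated expansion (matrix
squaring) and inflation (elementwise power 2.0, renormalization), pruning
entries below $10^{-8}$, until the largest column change falls below
$10^{-6}$ or 100 iterations (a warning flags non-convergence and returns
the current state). Cluster ids c1…cN are assigned by decreasing size,
ties broken by the lexicographically smallest member, so output is stable
under input reordering. The e-value normalization and reciprocal-best-hit
preprocessing of full orthology pipelines are deliberately not replicated:
at a 0.3 ratio screen the edge set, not the weighting, dominates
membership.

**Six-frame rescue.** Annotation sets miss genes. For every cluster ×
genome cell that is absent, each member protein is Smith–Waterman-aligned
against all six translated frames of that genome (split at stops,
TBLASTN-style). A hit reaching 0.3 × the member's self-alignment bit score
upgrades the cell — to *present* when the member protein occurs verbatim
downstream of an in-frame start, otherwise to *present-no-start* (the
"sequence present, no start codon" category of presence/absence maps).
The rescue denominator is the member's self-bit rather than the pairwise
minimum because the genomic segment is not a gene. A cluster is **core**
when it is present (including rescued cells) in every genome.

# Molecular evolution

**Codon alignment.** Cluster CDS are translated and the proteins aligned
by progressive profile Needleman–Wunsch (guide order: decreasing length,
ties by name; profiles are residue-frequency columns, gaps carrying no
mass; same BLOSUM62/11-1 scoring). Each protein gap expands to one codon
gap, so every row ungaps exactly to its input CDS. This is a deliberate
lightweight substitute for a full multiple aligner: rudivirus gene
clusters are closely related and indel-sparse, and the two-sequence case
is exactly optimal pairwise NW (verified against a brute-force oracle).

**Pn/Ps (Nei–Gojobori).** Per codon, potential synonymous sites are the
fraction of the three possible changes at each position that are
synonymous; changes creating stops count as nonsynonymous sites, so
$S + N = 3 \times$ codons. Observed differences average all equally
weighted single-step pathways between the two codons, excluding pathways
through stop codons; codon pairs whose pathways are all excluded, or that
contain gaps or N, are skipped. Cluster-level Pn/Ps pools counts over all
unordered member pairs, $(\sum N_d / \sum N) / (\sum S_d / \sum S)$,
rather than averaging per-pair ratios — near-identical pairs make
per-pair ratios blow up on a zero denominator. When pooled $S_d = 0$ the
ratio is flagged undefined rather than infinite. Pn/Ps < 1 indicates
purifying selection. The published analysis aligned clusters with five or
more members; that threshold is the `min_pnps_members` default.

**Distances and tree.** Jukes–Cantor: with $p$ the mismatch fraction,
$d = -\tfrac{3}{4}\ln(1 - 4p/3)$, saturated ($p \ge 0.75$) distances
flagged infinite. Complete deletion is applied alignment-wide — any
column with a gap or N in *any* row is removed before any pair is
compared — matching the conventional "eliminate all positions containing
gaps and missing data" setting. The core-genome tree is neighbor joining
(via `ape::nj`) on the concatenated alignment of single-copy core
clusters, with taxa sorted for deterministic tie-breaks and negative
branch lengths clamped to zero. NJ is a deliberate substitute for
maximum-likelihood: the claims consumed downstream (geographic monophyly)
are topology-level, and no bootstrap is computed in this version.

# CRISPR layer

**Array detection** is CRT-style seed-and-extend: an exact 8-mer recurring
at a spacing compatible with one repeat (23–47 nt) plus one spacer
(17–50 nt) nucleates a candidate, further copies are chained at compatible
spacings, and repeat boundaries are extended column-wise while at most 20%
of copies disagree with the majority base. Arrays need ≥ 3 repeats; the
consensus is the column majority. **Orientation**: the consensus is
compared by Hamming distance to a reference repeat in both orientations;
a better reverse-complement match reverse-complements all spacers and
reverses their order; ties are flagged ambiguous and spacers are emitted
in both orientations.

**Matching** is ungapped: identity is computed for every window of spacer
length on both strands. A window is reported when (i) whole-spacer
identity is *strictly* greater than 50% and (ii) the window contains an
exact match run of ≥ 12 nt. The anchor deserves a note: at 26.5% G+C two
random bases agree with probability ~0.305, so a 39-nt spacer exceeds 50%
identity by composition alone in roughly 0.5% of windows — hundreds of
spurious sites per genome. Word-anchored matching is also what
BLASTN-based spacer pipelines actually do, and it is what makes
"decoys share no 12-mer with any virus" a guarantee of zero spurious
reports. Overlapping reported windows collapse to the local maximum
(leftmost on ties). The 5′-half identity covers the first
$\lceil L/2 \rceil$ spacer bases; the **seed** identity covers the first
8 (PAM-proximal) bases — 8 nt being the convention for type I systems,
configurable because the source literature does not fix it.

**PAM.** The motif (default CCN, the conventional *Sulfolobus* type I-A
PAM; the real motif is configurable because it is rarely printed) is read
from the bases immediately 5′ of the protospacer on the
protospacer-containing strand; side and motif are configurable and
recorded in the run manifest. Out-of-bounds positions yield
`pam_present = FALSE`.

**Immunity calls.** A host is predicted immune to a virus when at least
one match exceeds the identity threshold and (by default) carries a PAM;
match counts with and without PAM, per protospacer site and per distinct
spacer, are reported so stricter rules can be applied downstream.
Reconciliation against the spot-assay matrix (clearing counts 0–3 at
high/medium/low titer): predicted immune yet clearing at the *low* titer
is an **anti-CRISPR candidate**; predicted susceptible yet no clearing
even at the *high* titer is a **resistance candidate**.

# The synthetic generator

The generator emulates the structure the analyses assume: ~35 kb genomes
at 26.5% G+C; 30 core gene families in a syntenic central block; a pool of
64 variable families confined to the two terminal zones, sampled per
regional founder (24 per founder) with Poisson gain/loss on tip branches
(0.15 events/gene/branch); two geographic regions on a two-level tree
(region branch 60%, tip branch 40% of the root-to-tip substitution rate;
defaults 0.05 substitutions/site for core, 0.08 for variable genes).
Genes evolve by codon-level mutation: a binomial number of substitutions
per branch, proposals drawn from the background base frequencies (which
keeps G+C stationary), stop-creating changes rejected, and nonsynonymous
changes accepted with probability ω (0.2 core, 0.5 variable) — a simple
acceptance scheme, not a full codon model, sufficient for Pn/Ps < 1
recovery. Intergenic sequence is a regional property: each region draws
one intergenic reservoir and a gap-layout plan shared by its isolates, so
a zero-rate simulation yields identical same-region genomes and
same-region isolates share non-coding sequence.

Hosts (4 per region) carry one repeat-spacer array (24-nt fixed repeat,
25 spacers of 39 nt). Non-decoy spacers copy protospacers sampled at
sites whose adjacent bases already match the PAM — guaranteeing a planted
PAM without overwriting evolved sequence — from a same-region virus with
probability 0.8, mutated at 0.05/base (local) or 0.25/base (foreign);
15% of spacers are decoys rejection-sampled to share no 12-mer with any
virus. The divergence defaults are chosen for test power (clean
separation of the local/foreign identity distributions), as no
quantitative between-region divergence is available to calibrate them.

The observed infection matrix derives from a match-based protection
truth: a host is protected from a virus when any of its spacers has a
reportable (>50%, anchored) match with a PAM in that virus, computed by
the generator's own plain-R exhaustive matcher — a code path independent
of the compiled matcher used by the pipeline, and the same oracle the
test suite uses. Optionally, protected pairs can be flipped to clearing
to plant anti-CRISPR discordance.

One subtlety worth naming: "core" is a *presence* property, so with
gene gain and loss active, variable families that happen to be carried by
both regional founders end up present in every isolate and are correctly
called core by the pipeline even though the generator labelled the family
variable. Truth comparisons for the core count are therefore made against
the presence-based truth (families present in every simulated genome),
not against the family labels; the family-label comparison is what the
adjusted Rand index on cluster membership checks.

**What the generator does not emulate:** recombination between viruses
(present in real populations), indel evolution within genes, rearranged
gene order between regions, multi-copy genes, host genome structure
beyond a single array in random background, and spacer acquisition
history (spacers are independent draws, not an ordered record). Passing
the end-to-end tests therefore demonstrates correct recovery of the
planted signal under these idealized conditions, not performance on real
data — where annotation error, recombination and divergent array
architectures will dominate.

# Numerical and design choices

- Internal coordinates are 0-based half-open; every emitted table is
  1-based inclusive. One conversion point each way.
- N bases never count as matches in any identity computation.
- Reported percentages round half-up at one decimal (the convention of
  the field's reporting style); full-precision fractions are emitted
  alongside.
- "More than 50%" is strict: identity exactly 0.5 is not reported.
- Matching is per-spacer for match fractions but per-site for the region
  partition, mirroring the two denominators used in practice; duplicated
  match rows are deduplicated by spacer × site.
- Non-coding is every base not covered by an ORF; ties in the
  majority-rule assignment of a match break core > variable > non-coding.
- The ratio screen boundary keeps edges at exactly 0.3 ("0.3 or higher").
- MCL non-convergence returns the current clustering with a warning
  rather than failing the run.
- Geographic metadata travels in a sample sheet, not FASTA headers,
  because headers in the wild are unreliable.

# Problem sizes

The default simulation — 2 regions × 5 viruses of 35 kb, 8 hosts × 25
spacers — was chosen so a full pipeline run completes in a few minutes on
one core while keeping ≥ 500 ORFs in the all-vs-all step and ~200
spacers in the matching step; the unit-test fixtures use smaller genomes
(≈ 12 kb, 6 core families) where only correctness, not population
structure, is at stake. Oracle comparisons run at 200 random pairs
(Smith–Waterman), 500 codon pairs (Nei–Gojobori), 30 random graphs of
≤ 8 nodes (MCL), and 4–6-taxon additive matrices (NJ).

# Known limitations

- Cluster counts on real data are sensitive to the annotation set and to
  the rescue step; both pre- and post-rescue counts are reported.
- The pooled Pn/Ps aggregation is an implementation choice; per-pair
  aggregation rules differ between published tools.
- The progressive profile aligner has no iterative refinement; deeply
  diverged clusters may misalign relative to a full MSA tool.
- The array detector targets well-formed arrays with near-exact repeats;
  heavily degenerated boundary repeats are truncated rather than
  recovered.
- No bootstrap or likelihood model selection on trees.
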