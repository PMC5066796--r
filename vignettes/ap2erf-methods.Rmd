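---
title: "Methods: gene-family dissection of AP2/ERF and HSP90"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family dissection of AP2/ERF and HSP90}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what the synthetic benchmark does and does
not demonstrate about real data.

## Domain detection

Detection is a position-specific scoring matrix (PSSM) scan. A profile is
built from a seed alignment: per column and residue,

    score = log2( ((count + c * q_a) / (total + c)) / q_a )   [bits]

with pseudocount weight `c` (default 1) and background frequencies `q_a`
from a bundled 20-value table (Robinson & Robinson usage frequencies, kept
as data so results are bit-reproducible across platforms). Columns with
more than 50% gaps are dropped; the retained columns define the canonical
domain coordinate system, which is how "position 14" and "position 19" of
the AP2 domain stay addressable whatever the seed looks like. Scanning is
an ungapped sliding window; overlapping same-domain windows are resolved
best-score-first, ties to the left. We deliberately do not implement a full
profile HMM (insert/delete states): the pipeline only needs
presence/absence and coordinates, and a gapped, more sensitive search is
available by switching the backend to `hmmscan` (profiles built from the
same seeds with `hmmbuild`). A `blastp` backend covers the classical
mining step at e ≤ 1e-5; because it searches single consensus sequences it
is the least sensitive of the three for deeply diverged family members,
which is why the mining design treats the union of searches as the
candidate set.

No bit-score cutoffs are published for this kind of scan, so each profile's
reporting threshold is calibrated at build time: the score exceeded by
fewer than 0.1% of 1e5 random background windows (fixed internal stream),
floored at 10 bits. For the bundled profiles the calibrated quantile is far
below zero — a random window almost never resembles a domain — so the
10-bit floor is what is actually in force; planted domains score an order
of magnitude above it.

The bundled seed alignments and reference domains are **synthetic**
stand-ins (filenames say so) constructed to carry the field's landmarks:
YRG/RPWG at the AP2 N-terminus, WLG (YLG in the AP2-subfamily flavour),
RAYD (RAHD in the AINTEGUMENTA flavour), and the diagnostic positions 14
and 19. They are not curated Pfam seeds, and scores against them are not
comparable to HMMER scores against Pfam.

## The classification tree

Superfamily: ≥ 1 AP2 domain → AP2/ERF; HATPase_c and HSP90 domains jointly
→ HSP90; both patterns at once is pathological and resolves to AP2/ERF with
a warning. Within AP2/ERF: AP2 + B3 → RAV; two AP2 domains → AP2 lineage;
a single AP2 domain is checked against the ERF reference set and called
soloist below 30% identity ("low homology" is not quantified anywhere we
could adopt; 30% is this package's setting, exposed as
`soloist_identity_cutoff`). Everything else splits on the domain's
diagnostic residues: V at canonical position 14 → DREB regardless of
position 19; A14 → ERF, with a non-D residue at 19 flagged
(`flag_noncanonical19`) rather than left unresolved — position-14 primacy
keeps the tree total, and the flag preserves auditability. Any other
residue at 14 is `unresolved` and is handed to the phylogenetic step.

Identity for the soloist check is computed column-wise when the two domain
instances have equal length (profile windows always do). A gapped global
alignment that excludes gap columns from the denominator systematically
inflates borderline identities — the optimizer buys back mismatching
stretches with gaps — which is exactly the wrong behaviour next to a hard
cutoff.

Clade assignment (`assign_groups`) places query domains on a
neighbour-joining tree with labelled references (A1–A6, B1–B6, AP2 and ANT
repeat flavours). A query takes the label of the smallest clade, supported
at ≥ 50% bootstrap, containing it and only references of one label. The 50%
threshold mirrors the convention of reporting only majority-supported
nodes. Two re-labelling rules operate here: a single-AP2 gene landing in
the AP2 clade becomes AP2 (overriding the domain-count call), and an
`unresolved` gene landing in an A or B clade becomes DREB or ERF.

CRF calls: the core `ATDxSS` must lie N-terminal of the AP2 domain; the
`SP[T/V]SVL` phosphorylation-site motif is searched in the C-terminal third
of the protein. "C-terminal" is not defined more precisely anywhere; the
final-third rule is this package's choice. The EAR motif has two published
shapes; both `[LD]xLxL` and `DLNxxP` are scanned and the matching form
reported — this is a heuristic flag, not a classification input.

Physio-chemical properties use average residue masses plus one water, and a
pI solved by bisection on the Henderson–Hasselbalch net charge with an
EMBOSS-style pKa set (termini 8.6/3.6), to 0.01 pH. `X` residues carry no
mass and no charge.

## Gene structure

Intron counts and splice phases are computed from coding exons only
(UTR-bearing exons are not modelled): the phase of an intron is the number
of coding nucleotides 5' of the junction modulo 3, with exons traversed in
transcription order, so mirrored plus/minus-strand genes agree. When a gene
has several mRNAs, the longest-CDS isoform is used — isoform handling is
not specified in the protocols this mirrors, and longest-CDS is the common
default. Paralog pairs are `conserved` when intron counts match, otherwise
`gain_loss` with the absolute difference; phase strings are reported as
side evidence, not as part of the verdict.

## Duplication, orthology, alignment statistics

Pairwise alignment is Smith–Waterman (BLOSUM62, gap open 11 / extend 1, via
Biostrings) with Karlin–Altschul e-values `K m n exp(-λS)` using the
documented gapped-BLOSUM62 constants (λ = 0.267, K = 0.041) — bundled
constants rather than a database-dependent estimate, for reproducibility.
Duplication events are pairs at identity ≥ 80% (identical columns over
aligned non-gap columns; "similarity" in the underlying protocol is read as
identity) and e ≤ 1e-10; same chromosome within 5 Mb start-to-start →
tandem, otherwise segmental (cross-chromosome qualifying pairs are
segmental — the distance rule is silent about them, and published figures
link cross-chromosome paralogs). Orthology is best-bidirectional-hit at
e ≤ 1e-10 with deterministic tie-breaks (e-value, then subject id), which
makes the pair set symmetric in the argument order.

## Phylogeny

Distances are p-distances with pairwise deletion: per pair, columns where
either sequence is gapped are dropped; the distance is the mismatch
fraction over the rest. A pair with no comparable column is an error naming
the pair. The tree is Saitou–Nei neighbour joining with the textbook
Q-criterion and branch-length formulas; a negative branch at a join is
clamped to zero with the deficit moved to its sister (their sum — the
joined pair's distance — is preserved), and the final trifurcation clamps
at zero. Q-ties break by input-matrix order, so the result is
deterministic. Bootstrap resamples columns with replacement; support for an
internal edge is the percentage of replicate trees containing the same
bipartition. Tests run 100 replicates — replicate count is a scale choice
that changes the variance of the support estimate, not the algorithm — and
the replicate count is exposed (`bootstrap_replicates`) for users who want
the conventional thousands.

## The synthetic benchmark: what it emulates, and what it cannot show

`generate_genomes()` emulates annotated proteomes in which every signal the
pipeline looks for is planted and recorded: domain instances with known
coordinates, V14/E19 vs A14/D19 diagnostics (a configurable minority of
DREB genes carries a non-E position 19), CRF and element motifs, label-
dependent intron counts (ERF/DREB mostly intronless, AP2/ANT intron-rich,
HSP90 split into an intron-poor and an intron-rich group with recorded
splice phases), tandem pairs within 5 Mb and segmental pairs elsewhere,
cross-species 1:1 ortholog copies, and two-block expression structure. The
subfamily mix and the subgroup proportions default to chickpea-like ratios;
the chromosome scale (8 × 40 Mb) keeps placement realistic while leaving
room for the 5-Mb window to separate tandem from segmental cleanly.

Two generator decisions deserve their rationale spelled out, because they
are what makes exact truth recovery a *structural* property rather than a
per-seed accident:

* **Per-gene domain individuation.** Every planted domain instance carries
  a fixed number of idiosyncratic substitutions (14 of the 60 AP2 columns,
  away from anchors, diagnostics and subgroup signatures; similar counts
  for B3/HATPase_c/HSP90). If instances were identical, any two same-
  subfamily genes would share a perfect 60-residue local alignment —
  identity 100%, e-value far below 1e-10 — and the duplication rule would
  fire on every such pair, swamping the planted events. With individuation,
  unrelated same-flavour genes sit near 60–65% domain identity, while
  planted duplicate and ortholog copies, which inherit the instance, stay
  above the 80% gate. The same individuation keeps subgroup clades
  resolvable: signatures are seven fixed positions per subgroup, disjoint
  across subgroups, so the between-subgroup signal survives the
  within-subgroup noise.
* **Orthologs as 1:1 copies.** Species beyond the first consist of copies
  of species-1 genes (kept with probability `planted_ortholog_fraction`,
  default 1) plus private background fillers; later species carry no
  unpaired family genes. If unpaired same-subfamily genes existed on both
  sides, the best-bidirectional-hit criterion would necessarily emit at
  least one unplanted pair (the maximum of the residual similarity
  submatrix is always mutual-best), so "BBH = truth exactly" could not hold
  for any seed. Presence/absence variation is therefore expressed as
  species-private background genes, not as unpaired family members.

Paralog copies diverge only in inter-domain segments (target whole-protein
identity `paralog_identity`, default 0.92): biologically, purifying
selection on the DNA-binding domain; operationally, the copy keeps the
donor's classification signature, so noise-free recovery stays exact. The
global `noise_mutation_rate` is the dial that does hit domains — it is what
degrades classifier recovery, monotonically on average, mostly through
flips of residue 14 and, at higher rates, lost soloist detections.

What passing these tests does **not** show: the generator has no codon
usage, no indels (so the scanner's ungapped window assumption is never
stressed), no gene-family birth/death beyond the planted pairs, no UTRs or
alternative splicing, no read-level noise (expression starts from counts),
and its domains are short synthetic models rather than Pfam profiles.
Perfect recovery here is a correctness statement about the pipeline's
logic, not a sensitivity claim about diverged real proteomes — on real
data the hmmscan backend and curated seeds should be preferred.

`generate_expression()` draws negative-binomial counts with mean
`block_mean × transcript_kb × library_size / 1e6` (dispersion 0 gives the
mean exactly, so FPKM recovers the planted block means to machine
precision); the default two blocks are separated 8-fold and mirrored across
conditions. `generate_ct_table()` constructs Ct values whose 2^−ΔΔCt is the
planted fold change exactly at zero noise; replicates are averaged on the
Ct scale (the conventional order of operations — averaging linear folds
first is biased upward).

## Numerical and interface choices

* Log-expression offset: `log10(x + 1)`, so zero FPKM maps to zero; the
  offset is exposed.
* Clustering: average linkage, Euclidean metric by default; both exposed.
  Heat-map normalization beyond log10 is left to the caller (raw log10
  values are emitted).
* Coordinates are 1-based inclusive everywhere (protein positions and
  GFF3 alike); GFF3 is read and written through rtracklayer, with CDS
  phase columns computed from cumulative coding length.
* All randomness flows from a single integer seed per entry point; the
  generator is byte-reproducible (fixture files hash identically across
  runs), and pipeline runs with the same configuration and seed produce
  identical md5 manifests.
* Problem sizes in the tests — proteomes of 25–60 genes for property
  checks, one 500-gene proteome for the headline recovery check, 100
  bootstrap replicates, 10 seeds for noise sweeps — were chosen as the
  smallest sizes at which the checked properties are non-trivial.

## Known limitations

The scanner cannot detect domains split by long insertions (delegate to
`hmmscan` for that). The e-values use fixed Karlin–Altschul constants, so
they are comparable within this package but not to BLAST runs against
other databases. Subgroup assignment requires reference taxa on the tree
and inherits any bootstrap instability; queries in unsupported regions are
reported as `none` rather than guessed. The published-count table bundled
for the tally arithmetic reflects the five legume proteome versions of the
original surveys; re-annotation of those genomes would change the inputs,
not the arithmetic.
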