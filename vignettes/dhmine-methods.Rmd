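---
title: "Mining and processing DH-type neuropeptide precursor genes with dhmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and processing DH-type neuropeptide precursor genes with dhmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhmine)
```

## The biological problem

Insect diapause hormone (DH) belongs to the PRXamide superfamily of
neuropeptides. Its precursors — like those of the related CAPA and PBAN
peptides — are prepropeptides: a signal peptide followed by a series of
peptide cassettes separated by basic endoproteolytic sites. Convertases
excise the cassettes, a peptidylglycine α-amidating step converts a
C-terminal glycine into an amide, and an N-terminal glutamine may cyclise
into pyroglutamate. What distinguishes DH-type precursors, particularly in
orthopterans, is long tandem arrays of DH-like cassettes whose amidated
C-termini fall into a small set of consensus classes (WFGPRXa and
WFGARXa variants). `dhmine` implements the complete desk-side workflow by
which such genes are found and characterised: motif-guarded homology mining
of genome contigs, precursor processing, C-terminal classification, mass
confirmation against LC-MS/MS observations, codon-usage comparison,
distance phylogeny, and the statistics of diapause bioassays and RNAi
knockdowns.

## Genome mining

Queries (known precursor proteins) are aligned against all six reading
frames of each contig with an optimal local alignment under BLOSUM62 and
affine gap costs 11/1 (the familiar protein-BLAST defaults; a gap of length
L costs 11 + L). Two filters define the two reporting tiers:

* **candidate** — best alignment covers at least `min_aligned_nt`
  nucleotides (default 100, i.e. ⌈100/3⌉ = 34 aligned residues). The
  length filter is stated in nucleotides because homology searches of
  protein queries against genomes are conventionally reported that way,
  but it is computed on the protein alignment.
* **target** — additionally, the conserved CAPA/PBAN C-terminal core
  `FGPR[VIY]` occurs in some frame of the contig.

A raw-score floor (`min_score = 50`) accompanies the length filter. Length
alone does not separate homology from chance at desk scale: on random
contigs, spurious ≥ 34-column local alignments score at most the mid-30s
under BLOSUM62, while genuine precursor homology scores in the hundreds, so
the floor suppresses only chance hits (a local BLAST run applies an
analogous internal reporting cutoff). Alignment itself is delegated to
`Biostrings::pairwiseAlignment`; the test suite verifies its scores against
an independent brute-force Gotoh dynamic program on random sequence pairs.

No E-value statistics are computed: the mining funnel is a length + motif
filter, which is how this family is screened in practice, and candidate
counts at desk scale are small.

## Precursor processing

`trim_signal()` offers three modes. The default heuristic finds the
maximal-scoring Kyte–Doolittle window (width 9, mean hydropathy ≥ 1.6)
within the first 40 residues and cleaves after the first A/G/S/C at or
downstream of the window end — the small-residue context favoured by signal
peptidase. This is a transparent approximation, not a trained
signal-peptide model: pipelines with externally predicted signal spans
should pass them through `mode = "fixed"`. On generated precursors
(Met + hydrophobic core + Ala), recovery is essentially exact; on real
precursors an error of a few residues shifts the first peptide's N-terminus
only, which is why the round-trip acceptance threshold is 99% rather
than 100%.

`cleave()` scans N→C and matches cleavage motifs longest-first
(`GRR` before `GR` before `KR`), non-overlapping, left-to-right — a
deterministic rule that reproduces all three canonical sites. `AR` is never
cleaved: a G→A substitution at a GR site is the classic natural knockout
that silences a cassette, and the excluded-motif list makes that rule
explicit and configurable. A `KK` motif can be added by configuration but
is off by default. Amidation follows peptidylglycine biology: a peptide is
amidated when its final residue is the donor G (which is then removed from
the mature sequence) or when the following motif begins with G (GR/GRR
donate their own glycine; in the rare case where both hold, the motif's G
is taken as donor and the peptide keeps its trailing G). A processed
peptide starting with Q is flagged as a *potential* pyroglutamate; both
forms are retained downstream, because cyclisation is not certain from
sequence alone. Segments shorter than `min_peptide_len = 4` are discarded
as linker fragments (the shortest credible mature peptide in this family
has 7 residues before amidation, so 4 is conservative) but recorded, which
makes the residue-conservation invariant testable: signal + peptides +
removed donors + motifs + discarded segments reconstruct the precursor
exactly. A trailing G on the final segment (no following site) is still
treated as a donor; this is a deterministic convention, not a biological
claim, and does not arise in the generator's architectures.

## Classification, repeats and logos

Classification is by anchored C-terminal patterns on the amidated sequence
*without* any trailing "a" marker (the amidation flag carries that
information), most specific first: the five DH types, then generic PK
(`F.?PRL$`), PVK (`F.?PR[VI]$`) and a PRXamide-like fallback
(`[AP]R[LVI]$`). Precedence matters — every type-I DH peptide also matches
the generic PRVa context — and the first matching rule wins, so permuting
priorities is the only way results can change. Peptides whose C-terminus
has the PRXamide core but lacks the family phenylalanine (e.g. …SARVa) are
deliberately left at the fallback label: the literature names such peptides
PK by history, not by a stated rule, and the package does not invent one.

`find_tandem_repeats()` reports maximal *adjacent* repeats of primitive
blocks (copies ≥ 2, not extendable by a full copy on either side, block not
itself a repeat), by exhaustive scan over block lengths — an O(n³) scan
that is exact at cassette-array sizes. Note that two copies of a block
separated by another cassette are a recurrence, not a tandem repeat, and
are not called. The test suite checks the scan against a brute-force
all-substrings oracle exhaustively for every label sequence up to length 7
over three labels.

`cterm_logo()` computes per-column residue frequencies over the k = 13
C-terminal positions (the window conventionally used for this family's
logos), left-padding shorter peptides with gaps and excluding gaps from
frequencies — the sub-13-mer handling is a package choice since no
convention exists. Information content is log₂20 − H bits; rendering is
left to dedicated logo tools.

## Masses and matching

Theoretical masses are neutral monoisotopic peptide masses: residue
monoisotopic masses (IUPAC values at six decimals — four-decimal agreement
with published tables requires at least five) plus water (18.010565 Da),
with −0.984016 Da for C-terminal amidation and −17.026549 Da for
N-terminal pyroglutamate, the sign convention of proteomics search engines.
Charge states, fragment ions and spectral scoring are out of scope;
matching is at the precursor-ion level within a ppm tolerance (default
15 ppm, a typical Orbitrap parent-ion window). All matches within
tolerance are reported per observed mass, sorted by absolute error —
leucine/isoleucine isomers are genuinely indistinguishable by mass and both
are returned. The shipped published peptide table is reproduced to within
±0.001 Da; the residual last-digit differences are rounding in the printed
table.

## Codon-usage indices

The reference codon-usage set is user-supplied (typically highly expressed
housekeeping genes such as actin/gapdh/ef); no species table is built in,
because the discriminating comparison is always against the study's own
reference genes. Counts are pooled, unseen codons receive a 0.5
pseudo-count (the CodonW convention, which keeps ln w finite), and per
synonymous family w = f/f_max. CAI is the geometric mean of w over
synonymously informative codons (Met, Trp and stops excluded), FOP the
fraction of optimal codons, CBI = (N_opt − N_exp)/(N_syn − N_exp) with
N_exp the uniform-usage expectation, and GC3s the G+C fraction at third
positions of degenerate codons. All four are invariant under silent codon
reordering, and the generator dials are honest: a requested GC3 skew is
recovered within ±0.02 at 1000 codons, and uniform synonym usage drives
CBI to 0. ENC and RSCU ordination are intentionally absent — they play no
role in the family-discrimination argument this package supports.

## Phylogeny

Distances are Poisson-corrected protein distances d = −ln(1 − p) with
p-distances computed after *complete deletion* of columns containing gaps
or ambiguity characters (mirroring the "remove all ambiguous positions"
convention of standard phylogenetics GUIs); pairwise deletion is available
behind a flag. Neighbor-joining is implemented in the package (Saitou–Nei
Q-criterion, pendant lengths from the standard formulas) with two
deliberate determinism rules: ties in Q are broken by the lowest index pair
in the current matrix order, and negative branch lengths are clamped to
zero with a message. `ape::nj` is used in the tests as an independent
oracle for the topology, never as the implementation. Bootstrap resamples
alignment columns with replacement and reports, for each internal edge of
the full-data tree, the percentage of replicates containing the same
bipartition; with a fixed seed the whole procedure is reproducible.
Maximum-likelihood inference and substitution models beyond Poisson are out
of scope.

## Bioassay statistics

Diapause incidence is 100·H2/(H1+H2), where H2 are the individuals that
hatch only after a chilling rescue. Relative expression uses 2^−ΔΔCt
against a reference gene and calibrator group; the fold change is invariant
under any constant Ct offset applied to both channels. One-way ANOVA is
classical fixed-effects (computed via `aov`); when the response has zero
variance the F statistic is defined as 0 with p = 1, since `aov`'s sums of
squares are floating-point noise there. Both Tukey HSD and Duncan's
multiple range test are provided for letter groupings because the
literature this package serves reports both, sometimes inconsistently
within one study; Tukey is the default and Duncan — which uses the
protection level 1 − (1 − α)^(p−1) for means p ranks apart and is provably
never less liberal than Tukey under the shared harmonic-mean standard
error — is behind a flag. Studentized-range quantiles come from R's own
`qtukey`, which covers arbitrary (p, df). Letters are maximal homogeneous
intervals over the ordered means, which is exact for range tests whose
critical value grows with span. Unbalanced designs use the harmonic-mean
group size with a warning. The replicate unit in all simulations is the
egg-pod (clutch), not the egg.

## The synthetic generators

Every generator is a pure function of its arguments and seed and emits
machine-readable ground truth alongside the data, so tests never re-derive
truth from generator internals. `gen_precursors()` builds
signal + [cassette + site] × n architectures: signals are
Met + a hydrophobic LVIF core + Ala; cassette prefixes exclude arginine so
no spurious cleavage context can arise by chance; sites are drawn from
G+KR, GRR and GR, all of which amidate the upstream peptide (the study
peptides this emulates are all amidated). `gen_genome()` back-translates
precursors with uniform synonymous codons and embeds them on a random
strand inside random-nucleotide contigs; decoys have every `FGPR[VIY]`
core mutated to `FGPRQ`, so they stay alignable but fail the motif filter.
`gen_bioassay()` draws H2 ~ Binomial(n_eggs, p); the default contrast in
the acceptance script (p = 0.191 vs 0.681, three pods of 100 eggs) echoes
the size of a published control-versus-treatment diapause contrast.

What the generators do *not* emulate — and hence what green tests do not
demonstrate about real data: intron-containing genes, signal peptides with
non-canonical cleavage contexts, unamidated cassettes, peptides sharing
cleavage sites, LC-MS/MS spectra (only precursor masses with Gaussian ppm
jitter), RNAi off-target biology, and photoperiod physiology.

## Deterministic fixtures and problem sizes

The synthetic five-gene bundle (`synthetic_lomdh_bundle()`) is a clearly
labelled stand-in for a set of five deposited DH-precursor accessions that
the package does not download: it fixes the per-gene cassette counts
(5/8/11/6/14) and the type census over all 44 DH-like cassettes
(27/7/3/4/3, types I–V) while simulating all sequence content, so the
processing and classification stages must recover the published
architecture from sequence alone. Test and acceptance problem sizes —
500-precursor round trips, 500-peptide mass libraries, 100 random 5–10-leaf
trees, 2000-replicate type-I-error simulations, 20–200 bootstrap
replicates — were chosen as the smallest sizes at which the binomial noise
on each estimated rate is well inside its acceptance margin.

## Known limitations

* The signal-peptide heuristic is a hydrophobicity rule, not a trained
  model; ambiguous N-termini shift the first cassette boundary.
* Classification patterns encode the published consensus classes; novel
  C-termini fall to the PRXamide-like fallback or `unclassified`.
* Mass matching is precursor-level only; no FDR is estimated.
* Codon indices depend on the supplied reference set; absolute values are
  not comparable across references.
* NJ with complete deletion discards whole columns; for very gappy
  alignments pairwise deletion (provided) or likelihood methods (not
  provided) are preferable.
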