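---
title: "Methods: characterizing cysteine-rich carboxypeptidase inhibitor families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: characterizing cysteine-rich carboxypeptidase inhibitor families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpikit)
```

## The problem

Plant metallocarboxypeptidase inhibitors (CPIs) are small (~35–50 residue)
cysteine-rich peptides, best known from potato and tomato, that block A/B-family
metallocarboxypeptidases by inserting their hydrophobic C-terminal tail into the
enzyme's catalytic groove. Family members share a rigid disulfide scaffold:
five to six cysteines with nearly fixed spacing and a conserved aspartate just
before the third cysteine. `cpikit` implements the computational
characterization of such a family end to end: curation of candidate sequences,
per-column consensus of a multiple alignment at several identity thresholds,
derivation of the cysteine-spacing motif
`CXXXCXXXXDCXXXXXCXXC` (`C-x(3)-C-x(4)-D-C-x(5)-C-x(2)-C`) and scanning
against it, a physicochemical panel used to judge antimicrobial-peptide-like
character, a bootstrapped distance phylogeny, and geometric typing of the
inhibitor–enzyme interface in a PDB complex.

Every stage is testable offline because the package also ships a seeded
generator of synthetic CPI-like families (below).

## Curation and mature-region trimming

`curate()` applies three machine-checkable exclusion rules, in order:
exact-duplicate residue strings (**redundant**, first occurrence wins),
ambiguity/non-standard codes `X B Z J U O` or `*` (**incomplete**), and a
cysteine count below the scaffold's five anchors (**cysteine_pattern**).
"Incomplete" and "uncharacterized" have no further machine-checkable meaning
for bare sequences, so the ambiguity-code reading is the operative one; the
cysteine threshold (`min_cys`, default 5) is configurable.

`trim_to_mature()` cuts each precursor at the third residue before the first
cysteine of the best motif match — the convention used when comparing database
entries against the functional potato/tomato inhibitors. Two boundary choices
keep the rule total: without a motif match the first cysteine anchors the cut,
and the start is clamped to position 1 when fewer than three residues precede
the anchor. The operation is idempotent.

## Threshold consensus and motif derivation

`column_frequencies()` reports per-column relative frequencies with the **row
count as denominator**, so gaps carry weight: a heavily gapped column cannot
reach a consensus threshold. `consensus_at_threshold()` emits, per column, a
residue letter when a single residue reaches the threshold, else the symbol of
the first qualifying physicochemical class, else no call. The five class
symbols (h hydrophobic, o alcohol, p polar, s small, t turnlike) follow the
MView-style convention; exact memberships are a convention rather than a
measurement, so `residue_class_scheme()` makes them configurable. Identity
always beats a class call at the same threshold, qualification follows scheme
order, and exact frequency ties go to the smaller (more specific) set. Note a
consequence of the default sets: a column such as A/K/D/R is called `t` at
90%, because the broad turnlike class covers all four residues.

`derive_spacing_motif()` takes the first five alignment columns whose cysteine
frequency reaches the anchor threshold (default 90%), adds the aspartate
column immediately preceding the third cysteine when it also qualifies, and
sets each spacer to the modal count of residues strictly between consecutive
anchors in the degapped rows (ties toward the shorter spacer). The motif is
deliberately limited to this five-cysteine consensus region; the family's
remaining cysteine(s) vary in position and stay outside the motif. Matching
(`scan_motif()`) is anywhere-in-sequence with fixed spacers, overlapping
matches all reported; `motif_match_rate()` is the percentage of records with
at least one hit.

## Physicochemical panel

All panel quantities are computed from first principles and rounded to the
precision conventionally printed (MW and pI 2 decimals, ratio integer percent,
Boman 2 decimals):

* **Molecular weight**: sum of average residue masses plus one water
  (18.01524 Da).
* **pI**: bisection on [0, 14] of the Henderson–Hasselbalch net charge, with
  the Bjellqvist pKa set (C-term 3.55, generic N-term 7.5 with per-residue
  overrides, D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0). The
  charge is strictly decreasing in pH so the root is unique; the default
  tolerance is 0.001 pH units and tests hold the result to a 10⁻⁴-step grid
  oracle within 10⁻³.
* **Formal charge**: `(K+R) − (D+E)`, His and termini excluded. This is the
  convention that yields the small integers conventionally reported for these
  peptides at neutral pH; it is a documented assumption, configurable only by
  computing `net_charge_continuous()` at a pH of choice instead.
* **Hydrophobic ratio**: percentage of residues in {A,C,F,I,L,M,V,W}
  (APD-style convention, configurable).
* **Boman index**: mean per-residue protein-binding value (kcal/mol, sign
  such that higher = more protein-binding; Pro = 0). Linear in composition by
  construction.

## Phylogeny

The reference analysis for such families is a maximum-likelihood JTT tree;
`cpikit` deliberately substitutes **neighbor joining on corrected distances
with the same bootstrap protocol**, because the downstream claims
(genus-level clustering) are topology-level and recoverable by distance
methods at a fraction of the cost, and an ML search is out of scope here.
`pairwise_distances()` offers p, Poisson and Kimura protein corrections
(default Kimura, `d = −ln(1 − p − 0.2p²)`) under pairwise gap deletion, with
explicit domain errors naming the offending pair. `nj_tree()` is an
in-package Saitou–Nei implementation — deterministic tie-breaking by lowest
index pair, negative branch lengths clamped to zero — validated in the test
suite against both an exhaustive four-point-condition oracle on additive
matrices and the independent `ape::nj()`. `bootstrap_supports()` resamples
columns with replacement, rebuilds the tree per replicate, and scores each
internal bipartition of the full-data tree as a percentage; replicates whose
resampled matrix leaves a pair outside the correction's domain are skipped
and counted (`skipped_replicates`). The reference protocol uses 1,000
replicates; tests scale down to 10–100 to stay within time budgets, which
does not change the estimator, only its Monte-Carlo noise.

## Interface interaction typing

`parse_structure()` reads PDB-format text directly (first model of
multi-model files; alternate locations resolved by occupancy then altloc
`A`). No pre-installed R package parses PDB, so the fixed-column reader is
in-package. `detect_interactions()` types cross-chain contacts:

| type | geometry | default cutoff |
|---|---|---|
| hbond | donor heavy atom (N, hydroxyl O, thiol S) to acceptor (O, His ring N) | 3.5 Å |
| attractive_charge | Arg/Lys side-chain N to Asp/Glu/C-terminal carboxylate O | 5.6 Å |
| pi_pi_t_shaped | aromatic ring centroids, inter-plane angle 60–90° | 6.0 Å |
| pi_alkyl | ring centroid to aliphatic side-chain carbon | 5.5 Å |

Crystal structures of such complexes carry no hydrogens, so hydrogen bonds
are detected donor-heavy-atom to acceptor; the published interface distances
for the potato inhibitor–carboxypeptidase A complex (2.85–3.02 Å for
hydrogen bonds, up to 5.42 Å for charge pairs) sit comfortably inside these
cutoffs, which follow common interaction-profiler conventions and are all
configurable in `geometry_params()`. The OXT-bearing residue's `O`/`OXT`
pair counts as a carboxylate (the inhibitor's C-terminal valine is the
canonical example); His is treated as positive only when
`his_positive = TRUE`, since protonation is structure-dependent. Tryptophan
contributes both rings and the nearer one is reported. Detection is invariant
under rigid motion, verified by property tests.

## The synthetic family generator

`generate_family()` emulates the curated natural family the pipeline was
designed around: ~42 sequences built as
`[propeptide 0–25] + [3 lead residues] + [scaffold 20] + [hydrophobic tail]`,
with wildcard segments drawn from the class observed to dominate each
inter-cysteine interval in real alignments — turnlike between Cys I–II,
polar/small/turnlike before the aspartate, hydrophobic after Cys III, no
preference in the last spacer — at `1 − substitution_noise` (default 0.9)
probability, and a hydrophobic-biased C-terminal tail. Violating sequences
(count exactly `round(n × violation_rate)`) receive one anchor-destroying
substitution, re-drawn until the scanner genuinely finds no match, so truth
labels and scanner behavior agree by construction.

Two deliberate simplifications: the tail length (2–6) is drawn **once per
family** rather than per sequence, so the mature regions stack gaplessly into
an alignment without an aligner — per-sequence tails would contradict the
gapless-alignment contract; and lead residues exclude cysteine so the trim
anchor is unambiguous. The generator does not emulate real codon-level
residue usage, indels, or the positional variability of the fifth/sixth
cysteines; a green pipeline run on synthetic data therefore establishes the
machinery (scanner ≡ oracle, consensus calls, recovery of the configured
scaffold, exact violation counts), not any biological claim about natural
sequences.

## Numerical choices and degenerate inputs

* Thresholds compare with a 10⁻¹² slack so exact rational frequencies (e.g.
  0.7 at threshold 70) qualify despite floating point.
* Modal spacer ties break toward the smaller spacer; NJ ties toward the
  lowest index pair; duplicate curation keeps the first record.
* `pairwise_distances()` raises on a pair with no comparable columns or with
  p outside the correction's domain, naming the pair; bootstrap replicates
  with such degeneracies are skipped and counted rather than failing the run.
* Sequences with no cysteine are untrimmable and raise an error.
* The pipeline log records versions, seed and per-stage timings; all data
  outputs are byte-reproducible given the same config, inputs and seed (the
  log's timings are exempt).

## Known limitations

* Real headline numbers of the source analysis (per-accession MW/pI/charge,
  the 4CPA interface distances, the ≥90% family match rate) require the
  deposited sequences and structure; without network access the package
  validates formulas against oracles and synthetic data instead.
* No multiple-alignment computation: aligned FASTA is consumed as input.
* No ML tree search, no toxicity/antimicrobial ML predictors, no secondary
  structure prediction, no binding-energy estimation.
* The interaction detector considers geometry only — no protonation-state
  prediction, no water-mediated contacts, no solvent accessibility.
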