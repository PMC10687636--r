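# cpikit

Characterization toolkit for plant **carboxypeptidase inhibitor (CPI)**
peptide families — small (~35–50 aa) cysteine-rich inhibitors of A/B-family
metallocarboxypeptidases, best known from potato and tomato, whose hydrophobic
C-terminal tail docks into the enzyme's catalytic groove. The package is aimed
at peptide/AMP researchers who want to run the full in-silico
characterization of such a family from sequences and a complex structure,
reproducibly and offline.

It implements, as one tested pipeline:

* **Curation** — FASTA in, rejection of redundant / incomplete /
  cysteine-deficient entries, mature-region trimming (cut 3 residues before
  the first motif cysteine).
* **Consensus & motif** — per-column frequencies of an alignment, MView-style
  threshold consensus (identity or class symbol at 100/90/80/70%), derivation
  of the family's cysteine-spacing motif
  `CXXXCXXXXDCXXXXXCXXC` = `C-x(3)-C-x(4)-D-C-x(5)-C-x(2)-C`,
  and a fixed-spacer scanner with match-rate statistics.
* **Physicochemical panel** — average molecular weight, isoelectric point
  (Henderson–Hasselbalch bisection, Bjellqvist pKa set), formal charge
  `(K+R)−(D+E)`, hydrophobic ratio, and the Boman protein-binding index
  (kcal/mol).
* **Phylogeny** — p/Poisson/Kimura protein distances (pairwise gap deletion),
  in-package neighbor joining (deterministic ties, clamped branch lengths),
  seeded column bootstrap with bipartition supports, Newick output.
* **Interface typing** — PDB parsing and geometric detection of cross-chain
  hydrogen bonds, attractive-charge pairs, T-shaped π-π and π-alkyl contacts
  with per-type distance cutoffs.
* **Synthetic families** — a seeded generator of CPI-like peptides (class-
  biased inter-cysteine segments, hydrophobic tail, optional propeptide,
  exact counts of motif-violating decoys) so every stage is testable without
  database downloads.

See `vignettes/cpi-characterization-methods.Rmd` for the model, conventions
and limitations.

## Worked example

```r
library(cpikit)

# a 42-member synthetic family, 10% of members carrying a broken anchor
fam <- generate_family(synthetic_config(n_sequences = 42, seed = 7,
                                        violation_rate = 0.1))
rep <- curate(fam$records)            # kept: 42, rejected: 0
motif <- derive_spacing_motif(fam$aln)
motif
#> <spacing_motif> CXXXCXXXXDCXXXXXCXXC  [C-x(3)-C-x(4)-D-C-x(5)-C-x(2)-C]

trimmed <- trim_to_mature(rep$kept, motif)
motif_match_rate(trimmed, motif)      # 90.47619  (38 of 42 match; 4 decoys)

head(physchem_table(trimmed), 3)
#>       id   species   pI   MW_Da charge hydrophobic_pct boman_kcal_mol
#> 1 SYN001 synthetic 7.79 3323.93      1              58           2.74
#> 2 SYN002 synthetic 7.78 3053.61      1              50           1.16
#> 3 SYN003 synthetic 6.86 3127.63      0              50           0.57

tree <- bootstrap_supports(fam$aln, n_reps = 100, seed = 7, correction = "p")
write_newick(tree)
#> "((SYN021:0.3395432692,(SYN002:0.2992307692,SYN031:0.3161538462)22:0.02..."
```

The match rate is the percentage of records the motif scanner hits at least
once (the 10% planted violations are missed by construction); supports on
internal nodes are bootstrap percentages — low here because wildcard segments
of the generator are nearly i.i.d., so there is little tree signal, which is
itself the expected behavior.

Interface typing on a complex (enzyme chain `A`, inhibitor chain `I`):

```r
rec <- detect_interactions(parse_structure("complex.pdb"), "A", "I")
interaction_table(rec)
#>                  Interaction Distance_A              Type From_role  To_role
#> 1    I:VAL38:N - A:TYR248:OH        2.5             hbond     donor acceptor
#> 2 A:ARG127:NH1 - I:VAL38:OXT        4.2 attractive_charge  positive negative
```

## Pipeline and CLI

```r
run_pipeline(run_config(fasta = "family.fasta",
                        alignment = "family.aln.fasta",
                        pdb = NULL, out_dir = "out", n_reps = 1000,
                        seed = 17))
```

writes `kept.fasta`, `rejected.tsv` (id, reason), `consensus.tsv` (column,
call per threshold), `freqs.tsv` (21 × ncol frequency matrix), `motif.txt`
(both syntaxes), `match_rate.txt`, `panel.tsv` (id, species, pI, MW_Da,
charge, hydrophobic_pct, boman_kcal_mol), `tree.nwk`, `supports.tsv`
(bipartition, support), optionally `interactions.tsv`, and `run.log`.
A JSON config file (`read_run_config()`) can carry the same fields.

The same stages are exposed as subcommands of the installed script
`inst/cli/cpikit.R` (`curate`, `consensus`, `motif derive|scan`, `physchem`,
`phylo`, `interactions`, `simulate`, `run`).

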