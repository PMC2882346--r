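# paradiv

Detection of paralog-diagnostic divergent residues between duplicated
protein families, and tests of their spatial clustering on a reference
β-propeller structure.

## The problem

After a gene duplication, the two paralogous copies can divide or
specialize the ancestral function. In fission yeasts the Tup1-like
co-repressor genes duplicated into *tup11⁺* and *tup12⁺*, and the two
proteins play distinct roles under specific stress conditions even though
they co-occupy the same chromatin. The sequence signature of such
specialization is a set of **group-diagnostic divergent residues**:
alignment columns that are conserved *within* each paralog clade across
species, but *differ between* the clades with a substantial change in
physicochemical properties. If those residues additionally cluster on one
surface of the shared fold — for a WD40 domain, on particular blades of
the seven-bladed β-propeller — they point at an interaction surface that
diverged after duplication.

`paradiv` packages that whole analysis for any pair of paralog groups:

1. **Alignment & phylogeny** — global pairwise alignment under BLOSUM62
   with affine gap costs (gap of length *L* costs
   `gap_open + (L−1)·gap_extend`, defaults 10 and 0.5), a domain-wise
   percent-identity cross-comparison (N-terminal / middle / C-terminal
   domains), Saitou–Nei neighbor joining with deterministic tie-breaking,
   and a progressive profile–profile multiple alignment.
2. **Divergent-site detection** — a column is reported when each group's
   criterion-species rows carry one identical non-gap residue, the two
   group residues differ, and the pair is *significant*:
   `BLOSUM62(r_a, r_b) < 0` **or** `charge(r_a)·charge(r_b) = −1`
   (charges: D,E = −1; K,R = +1; others, including H, 0). Sites are then
   polarized against an outgroup row: does group A, group B, or neither
   retain the outgroup residue?
3. **Structure mapping & clustering** — alignment columns are mapped onto
   the author numbering of a reference crystal structure (CA-only;
   residues missing from the coordinates are carried as *disordered*),
   counted per propeller blade, and tested against a permutation null
   (sites placed uniformly among eligible residues) with either a
   max-blade-count or a mean pairwise CA-distance statistic. Small nulls
   are enumerated exhaustively; Monte-Carlo p-values use the add-one
   correction `p = (1 + #extreme) / (1 + B)`.
4. **Simulation** — `simulate_paralog_families()` plants diagnostic sites
   with known residue pairs into two clades over a star species tree, plus
   neutral per-lineage noise and optional within-group corruption, giving
   ground truth for every stage; `make_toy_structure()` builds a
   deterministic CA-only β-propeller with geometrically separated blades.

## Worked example

The packaged example configuration runs the full pipeline on a synthetic
family of 2 clades × 3 species plus an outgroup (70 residues, 10 planted
sites) against the toy seven-blade structure:

```r
library(paradiv)
cfg <- system.file("extdata", "example_config.yaml", package = "paradiv")
files <- run_pipeline(cfg, output_dir = "paradiv_output")
read.table(files["sites"], sep = "\t", header = TRUE, comment.char = "#")
```

```
   column residue_a residue_b blosum_score charge_a charge_b blosum_negative opposite_charge           category residue_outgroup resno disordered blade
1       4         K         D           -1        1       -1            TRUE            TRUE A_matches_outgroup                K   304      FALSE     1
2       8         D         R           -2       -1        1            TRUE            TRUE A_matches_outgroup                D   308      FALSE     1
3      21         D         R           -2       -1        1            TRUE            TRUE A_matches_outgroup                D   321      FALSE     3
...
10     66         R         D           -2        1       -1            TRUE            TRUE A_matches_outgroup                R   366      FALSE     7
```

All ten planted sites are recovered (columns match the packaged
`synthetic_family_truth.tsv`), each with a negative BLOSUM62 score *and*
opposite charge, and each classified `A_matches_outgroup` because clade A
retains the ancestral residue. The blade summary counts the sites per
blade, and `clustering.json` holds the permutation test — for this evenly
spread family the maximum blade count is 2 and `p = 1`, i.e. no spatial
clustering, as it should be for sites planted uniformly.

Sites concentrated on one blade are detected sharply:

```r
toy <- make_toy_structure()                      # 7 blades x 10 residues
writeLines(toy$pdb, "toy.pdb")
model <- read_structure("toy.pdb", "A", toy$span)
blade3 <- seq(toy$annotation$start[3], toy$annotation$end[3])
clustering_test(blade3, model, toy$annotation, "max_blade_count",
                n_permutations = 1000, seed = 1)
#> Permutation clustering test (max_blade_count, upper tail)
#>   observed = 10, p = 0.000999 (montecarlo, 1000 permutations; 10 sites among 70 eligible residues)
```

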