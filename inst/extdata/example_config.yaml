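# Example pipeline configuration: end-to-end analysis of the packaged
# synthetic paralog family against the toy beta-propeller structure.
# Paths are resolved relative to this file.
fasta: synthetic_family.fasta
# matrix: defaults to the packaged BLOSUM62
structure:
  path: toy_structure.pdb
  chain: A
  seq_span: [301, 370]
  ref_id: outgroup
  ref_start: 301
blades: toy_blades.tsv
groups:
  group_a:
    label: A
    members:
      sp1: A_sp1
      sp2: A_sp2
      sp3: A_sp3
  group_b:
    label: B
    members:
      sp1: B_sp1
      sp2: B_sp2
      sp3: B_sp3
  outgroup_id: outgroup
  criterion_species: [sp1, sp2]
alignment:
  gap_open: 10
  gap_extend: 0.5
clustering:
  statistic: max_blade_count
  n_permutations: 1000
seed: 1
output_dir: paradiv_output
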