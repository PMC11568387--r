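seed: 20
sim:
  n_chromosomes: 2
  chrom_length: 150000.0
  n_genes: 20
  n_enhancers: 20
  depth: 150000.0
  n_convergent_genes: 2
peak_q: 0.05
peak_min_fold: 2.0
peak_window: 500
min_support: 2
max_length: 10000
presence_min_replicates: 1
diff_q: 0.05
overlap_n_perm: 50
assoc_q: 0.05
maf_min: 0.05
max_missing: 0.25
qual_min: 30.0
motif_sig: 0.0001
motif_ratio: 1.5
pbs_quantile: 0.95
stages:
  differential: yes
  overlap: yes
  association: yes
  pbs: yes
  motifs: yes
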