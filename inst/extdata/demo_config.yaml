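# Demo pipeline configuration: a reduced-scale two-group synthetic dataset.
# QC lower bounds are matched to the simulated library scale (a 0.8 Mb
# genome with 40 genes yields ~1e3 molecules per cell); the scale-free gates
# (mitochondrial percentage, global-methylation window) are at their
# full-scale defaults.
seed: 42
sim:
  n_chrom: 2
  chrom_length: 400000
  n_genes: 40
  n_cgis: 24
  n_imprinted: 4
  n_dmrs_planted: 6
  dmr_delta: 0.4
  n_degs_planted: 10
  deg_log2fc: 2.5
  coverage_mean: 10
  n_outlier_mito: 1
  n_outlier_small: 1
  n_outlier_hypo: 1
  n_outlier_lowcov: 1
qc:
  rna:
    min_reads: 100
    min_genes: 15
    max_genes: 1000000
    max_counts: 10000000
    max_pct_mito: 5
  bs:
    min_cpgs: 500
regions:
  min_cov_per_cpg: 5
  window_width: 1000
  vmr_top_fraction: 0.02
deg:
  alpha: 0.05
  lfc_min: 2
integration:
  K: 2
  lambda: 1
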