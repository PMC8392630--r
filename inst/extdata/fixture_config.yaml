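# Bundled demonstration run: a 0.5 Mb toy genome, 19 MZ + 19 DZ twin pairs,
# eight spiked differential regions. Used by the end-to-end examples and
# the determinism checks.
seed: 19
simulate:
  seed: 19
  chrom_lengths:
    chrA: 300000
    chrB: 200000
  n_pairs_mz: 19
  n_pairs_dz: 19
  window_size: 50
  fragment_size: 200
  baseline_mean: 50
  dispersion: 0.2
  pair_effect_sd: 0.3
  libsize_cv: 0.2
  spikes:
    - {chrom: chrA, start: 30000, end: 30300, log2fc: 2.0}
    - {chrom: chrA, start: 80000, end: 80400, log2fc: 1.5}
    - {chrom: chrA, start: 150000, end: 150300, log2fc: -1.5}
    - {chrom: chrA, start: 220000, end: 220350, log2fc: 1.8}
    - {chrom: chrB, start: 40000, end: 40300, log2fc: -2.0}
    - {chrom: chrB, start: 90000, end: 90400, log2fc: 1.5}
    - {chrom: chrB, start: 140000, end: 140300, log2fc: 2.2}
    - {chrom: chrB, start: 180000, end: 180250, log2fc: -1.8}
window_size: 50
fragment_size: 200
cutoff_fdr: 0.05
signal_fdr: 0.10
join_gap: 200
min_region_size: 150
alpha_q: 0.01
p_max: 0.01
n_train: 12
n_restarts: 1000
learning_rate: 0.05
max_epochs: 5000
max_rank: 10
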