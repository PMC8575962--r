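{
  "seed": 1,
  "n_chromosomes": 4,
  "chrom_length_cM": 150,
  "markers_per_chrom": 3000,
  "n_generations": 8,
  "mean_offspring": 2.5,
  "p_reproduce": 0.85,
  "background_n": 2000,
  "focal_chrom": "chr1",
  "focal_cM": 72,
  "focal_window_cM": [70, 74],
  "n_known_carriers": 5,
  "known_min_generation": 3,
  "genotyping_error": 0.001,
  "word_size": 32,
  "detect_min_cM": 0.5,
  "genome_threshold_cM": 6,
  "locus_threshold_cM": 1,
  "small_locus_threshold_cM": 0.5,
  "ethnicity_alpha": 0.05,
  "community_alpha": 0.001,
  "community_min_fold": 1.5,
  "geo_min_trees": 10,
  "geo_min_or": 4,
  "geo_rounding": 2,
  "geo_small_min_trees": 2,
  "geo_small_rounding": 0
}
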