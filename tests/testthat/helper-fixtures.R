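library(data.table)

# small coordinate backbone: one 100 cM chromosome unless asked otherwise
tiny_map <- function(n_chrom = 1, len = 100, n_markers = 500, seed = 1,
                     freq_range = c(0.3, 0.7)) {
  make_genetic_map(n_chrom, len, n_markers, seed, freq_range = freq_range)
}

# hapset with fully controlled alleles: haps is a list of 2-row 0/1
# matrices, one per sample id (names)
manual_hapset <- function(haps, gm) {
  ids <- names(haps)
  alleles <- do.call(rbind, haps)
  storage.mode(alleles) <- "integer"
  lens <- map_lengths(gm$map)
  segs <- CJ(sample = ids, hap = 1:2, chrom = lens$chrom)
  segs <- merge(segs, lens[, .(chrom, end_cM = length_cM)], by = "chrom")
  segs <- segs[, .(sample, hap, chrom, start_cM = 0, end_cM,
                   founder = paste(sample, hap, sep = "."))]
  hapset(ids, alleles, segs, gm$panel, gm$map)
}

# random unrelated cohort with planted true shared segments (haplotype
# copies), the regime of the detector-vs-oracle comparison
oracle_instance <- function(seed, n_samples = 20, n_markers = 2000,
                            n_planted = 15, len_range = c(200, 900)) {
  gm <- make_genetic_map(1, 100, n_markers, seed, freq_range = c(0.4, 0.6))
  hs <- simulate_background(n_samples, gm$panel, gm$map, seed = seed + 5000)
  set.seed(seed + 9000)
  len_range[2] <- min(len_range[2], n_markers %/% 2)
  for (i in seq_len(n_planted)) {
    ab <- sample(n_samples, 2)
    len <- sample(len_range[1]:len_range[2], 1)
    st <- sample(n_markers - len, 1)
    hr <- function(s, h) 2L * (s - 1L) + h
    hs$alleles[hr(ab[2], sample(2, 1)), st:(st + len)] <-
      hs$alleles[hr(ab[1], sample(2, 1)), st:(st + len)]
  }
  hs
}

# segment-table row builder for match-set unit tests
seg_row <- function(a, b, chrom = "chr1", s_cM, e_cM, n_mark = 1000L) {
  data.table(id_a = a, id_b = b, chrom = chrom,
             start_bp = s_cM * 1e6, end_bp = e_cM * 1e6,
             start_cM = s_cM, end_cM = e_cM, length_cM = e_cM - s_cM,
             n_markers = n_mark)
}

# desk-scale study configuration for structural tests
tiny_study_config <- function(seed) {
  study_config(seed,
               n_chromosomes = 2L, chrom_length_cM = 50,
               markers_per_chrom = 1000L, n_generations = 5L,
               mean_offspring = 2.5, background_n = 100L,
               n_known_carriers = 3L, known_min_generation = 2L,
               min_total_carriers = 4L, word_size = 16L,
               focal_cM = 25, focal_window_cM = c(23, 27),
               age_n_sim_controls = 10L, age_n_controls_cohort = 30L)
}
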