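test_that("detector basics: full sharing, opposite homozygotes, het runs", {
  gm <- tiny_map(n_markers = 600, seed = 2)
  m <- 600
  hsA <- manual_hapset(list(
    S1 = rbind(rep(0L, m), rep(1L, m)),        # all het
    S2 = rbind(rep(0L, m), rep(1L, m)),        # identical genotypes
    S3 = rbind(rep(0L, m), rep(0L, m)),        # hom ref
    S4 = rbind(rep(1L, m), rep(1L, m))), gm)   # hom alt
  pairs <- data.table(id_a = c("S1", "S3"), id_b = c("S2", "S4"))
  seg <- detect_ibd(hsA, word_size = 16, min_cM = 6, pairs = pairs)
  # identical samples: one segment spanning the whole chromosome
  expect_equal(nrow(seg[id_a == "S1"]), 1L)
  expect_equal(seg[id_a == "S1"]$length_cM, 100)
  # opposite homozygotes at every marker: nothing
  expect_equal(nrow(seg[id_a == "S3"]), 0L)
  # a single heterozygous site inside a run does not split it
  h <- rbind(rep(0L, m), rep(0L, m))
  h2 <- h; h2[1, 300] <- 1L                    # het at one marker in S6
  hsB <- manual_hapset(list(S5 = h, S6 = h2), gm)
  bf <- brute_force_ibd(hsB, min_cM = 6)
  expect_equal(nrow(bf), 1L)
  expect_equal(bf$length_cM, 100)
})

test_that("brute-force runs end at opposite homozygotes or chromosome ends", {
  hs <- oracle_instance(seed = 3, n_samples = 6, n_markers = 800)
  g <- as_genotypes(hs)
  bf <- brute_force_ibd(hs, min_cM = 2)
  panel <- hs$panel
  for (i in seq_len(min(nrow(bf), 50))) {
    r <- bf[i]
    i1 <- match(r$start_bp, panel$bp); i2 <- match(r$end_bp, panel$bp)
    ga <- g[r$id_a, ]; gb <- g[r$id_b, ]
    if (i1 > 1) expect_equal(abs(ga[i1 - 1] - gb[i1 - 1]), 2)
    if (i2 < nrow(panel)) expect_equal(abs(ga[i2 + 1] - gb[i2 + 1]), 2)
    expect_true(all(abs(ga[i1:i2] - gb[i1:i2]) < 2))
  }
  # guard: too-large instances refused
  big <- oracle_instance(1, n_samples = 20, n_markers = 2000)
  fake_pairs <- data.table(id_a = rep(big$samples, 300),
                           id_b = big$samples[1])
  expect_error(brute_force_ibd(big, pairs = fake_pairs), "too large")
})

test_that("seeded detector equals brute-force oracle on random instances", {
  for (seed in 1:10) {
    hs <- oracle_instance(seed)
    d <- detect_ibd(hs, word_size = 64, min_cM = 7)
    b <- brute_force_ibd(hs, min_cM = 7)
    expect_equal(nrow(d), nrow(b))
    if (nrow(d)) {
      expect_identical(d$id_a, b$id_a)
      expect_identical(d$id_b, b$id_b)
      expect_equal(d$start_bp, b$start_bp)
      expect_equal(d$end_bp, b$end_bp)
    }
  }
})

test_that("detection is symmetric and monotone in the length threshold", {
  hs <- oracle_instance(seed = 21, n_samples = 8, n_markers = 1000)
  p1 <- data.table(id_a = hs$samples[1:7], id_b = hs$samples[2:8])
  p2 <- data.table(id_a = hs$samples[2:8], id_b = hs$samples[1:7])
  expect_equal(detect_ibd(hs, 16, 2, pairs = p1),
               detect_ibd(hs, 16, 2, pairs = p2))
  d05 <- detect_ibd(hs, 16, 0.5, pairs = p1)
  d1 <- detect_ibd(hs, 16, 1, pairs = p1)
  d6 <- detect_ibd(hs, 16, 6, pairs = p1)
  key <- function(x) paste(x$id_a, x$id_b, x$chrom, x$start_bp, x$end_bp)
  expect_true(all(key(d6) %in% key(d1)))
  expect_true(all(key(d1) %in% key(d05)))
  expect_error(detect_ibd(hs, word_size = 4), "word_size")
})

test_that("truth recall: founder-shared segments are covered, FP rate low", {
  gm <- tiny_map(n_markers = 2000, seed = 31)
  ped <- simulate_pedigree_surviving(4, 2.5, seed = 7)
  hs <- drop_haplotypes(ped, gm$map, gm$panel, seed = 8)  # zero error
  ids <- ped$id
  cb <- utils::combn(ids[1:10], 2)
  pairs <- data.table(id_a = cb[1, ], id_b = cb[2, ])
  seg <- detect_ibd(hs, word_size = 16, min_cM = 1, pairs = pairs)
  word_cM <- 16 * 100 / 2000
  for (i in seq_len(nrow(pairs))) {
    truth <- true_ibd_segments(hs, pairs$id_a[i], pairs$id_b[i],
                               min_cM = 1 + 2 * word_cM)
    if (nrow(truth) == 0) next
    cp <- ibdtrace:::.canonical_pair(pairs$id_a[i], pairs$id_b[i])
    got <- seg[id_a == cp$a & id_b == cp$b]
    for (j in seq_len(nrow(truth))) {
      covered <- got[chrom == truth$chrom[j] &
                       start_cM <= truth$start_cM[j] + word_cM &
                       end_cM >= truth$end_cM[j] - word_cM]
      expect_gte(nrow(covered), 1L)
    }
  }
  # false positives between unrelated background pairs: logged, not zero
  bg <- simulate_background(40, gm$panel, gm$map, seed = 9)
  fp <- detect_ibd(bg, word_size = 16, min_cM = 6)
  rate <- nrow(fp) / choose(40, 2)
  message(sprintf("background FP rate at >6 cM: %.4f segments/pair", rate))
  expect_lt(rate, 0.05)
})

test_that("locus overlap: disjoint, nested, partial vs marker counting", {
  gm <- tiny_map(n_markers = 1000, seed = 12)
  win <- list(chrom = "chr1", start_cM = 40, end_cM = 44)
  segs <- rbind(seg_row("A", "B", s_cM = 10, e_cM = 20),
                seg_row("A", "B", s_cM = 41, e_cM = 43),
                seg_row("A", "B", s_cM = 38, e_cM = 42),
                seg_row("A", "B", chrom = "chr2", s_cM = 40, e_cM = 44))
  ov <- locus_overlap(segs, win)
  expect_equal(ov, c(0, 2, 2, 0))
  # marker-resolution oracle: count panel markers inside the intersection
  spacing <- 100 / 999
  m_in <- sum(gm$panel$cM >= 40 & gm$panel$cM <= 42)
  expect_equal(ov[3], m_in * spacing, tolerance = spacing * 2)
})

test_that("match sets apply strict thresholds and nest at-locus in genetic", {
  win <- list(chrom = "chr1", start_cM = 40, end_cM = 44)
  segs <- rbind(
    seg_row("A", "S1", s_cM = 10, e_cM = 16.5),   # 6.5 cM off-locus
    seg_row("A", "S2", s_cM = 10, e_cM = 16.0),   # exactly 6 -> excluded
    seg_row("A", "S3", s_cM = 30, e_cM = 50))     # covers locus, 20 cM
  ms <- build_match_sets(segs, "A", win)
  expect_setequal(ms$genetic_matches, c("S1", "S3"))
  expect_setequal(ms$at_locus_matches, "S3")      # window overlap 4 > 1
  expect_equal(ms$carrier_overlap[sample == "S3"]$at_locus_cM, 4)
  # exactly at the locus threshold is excluded too
  segs2 <- rbind(seg_row("A", "S4", s_cM = 0, e_cM = 10),
                 seg_row("A", "S4", s_cM = 40, e_cM = 41))
  ms2 <- build_match_sets(segs2, "A", win)
  expect_equal(ms2$at_locus_matches, character(0))
  expect_error(build_match_sets(segs, "A", win, genome_threshold = 0),
               "positive")
})

test_that("density filter and match file round trip", {
  segs <- rbind(seg_row("A", "B", s_cM = 0, e_cM = 10, n_mark = 200L),
                seg_row("A", "C", s_cM = 0, e_cM = 10, n_mark = 20L))
  kept <- ibs_density_filter(segs, min_per_cM = 5)
  expect_identical(kept$id_b, "B")
  path <- withr::local_tempfile(fileext = ".match")
  write_match_file(segs, path)
  expect_equal(read_match_file(path), segs, ignore_attr = TRUE)
})
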