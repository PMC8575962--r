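test_that("genetic map construction: spans, counts, determinism, errors", {
  gm <- make_genetic_map(1, 100, 1000, seed = 1)
  expect_equal(nrow(gm$panel), 1000L)
  expect_equal(max(gm$panel$cM) - min(gm$panel$cM), 100)
  gm2 <- make_genetic_map(2, 50, 10, seed = 7)
  expect_equal(nrow(gm2$panel), 20L)
  expect_equal(unname(table(gm2$panel$chrom)), array(c(10L, 10L)))
  expect_identical(make_genetic_map(2, 50, 10, seed = 7), gm2)
  expect_error(make_genetic_map(0, 100, 10, 1))
  expect_error(make_genetic_map(1, -5, 10, 1))
  expect_error(make_genetic_map(1, 100, 1, 1))
  # map invariants: strictly increasing, interpolation inverts
  expect_true(all(diff(gm$panel$bp) > 0))
  cm <- bp_to_cM(gm$map, "chr1", gm$panel$bp[123])
  expect_equal(cm, gm$panel$cM[123])
  expect_equal(cM_to_bp(gm$map, "chr1", cm), gm$panel$bp[123])
})

test_that("pedigree simulation: structure, extinction, branching size", {
  ped <- simulate_pedigree(2, 2, seed = 3)
  expect_true(validate_pedigree(ped))
  expect_setequal(unique(ped$generation), c(0L, 1L))
  expect_true(all(ped[founder == FALSE]$father %in% ped$id))
  # extinction error names the generation reached
  seeds <- 1:300
  died <- NULL
  for (s in seeds) {
    e <- tryCatch({simulate_pedigree(6, 0.7, seed = s); NULL},
                  error = function(e) conditionMessage(e))
    if (!is.null(e)) { died <- e; break }
  }
  expect_match(died, "extinct at generation [0-9]+")
  # founder-couple offspring conditioned on survival: mean
  # lambda / (1 - exp(-lambda)) for lambda = 2.5 => 2.723
  g1 <- vapply(1:100, function(s) {
    p <- simulate_pedigree_surviving(3, 2.5, seed = s)
    nrow(p[generation == 1L & founder == FALSE])
  }, 0)
  expect_equal(mean(g1), 2.5 / (1 - exp(-2.5)), tolerance = 0.12)
  # deep pedigree reaches requested depth
  p8 <- simulate_pedigree_surviving(8, 3, seed = 11)
  expect_equal(max(p8$generation), 7L)
})

test_that("gene dropping: mosaic tiling, Mendelian consistency, symmetry", {
  gm <- tiny_map(n_chrom = 2, len = 80, n_markers = 300, seed = 5)
  ped <- simulate_pedigree_surviving(4, 2.5, seed = 2)
  hs <- drop_haplotypes(ped, gm$map, gm$panel, seed = 9)
  # labels tile [0, len] without gap or overlap for every haplotype
  tl <- hs$segs[order(sample, hap, chrom, start_cM)]
  tl[, gap := start_cM - shift(end_cM, fill = 0), by = .(sample, hap, chrom)]
  expect_true(all(abs(tl$gap) < 1e-9))
  tot <- tl[, .(tot = sum(end_cM - start_cM)), by = .(sample, hap, chrom)]
  expect_true(all(abs(tot$tot - 80) < 1e-9))
  # every child allele at every marker is carried by the declared parent
  idx <- function(id, h) 2L * match(id, hs$samples) - 2L + h
  for (i in which(!ped$founder)) {
    kid <- ped$id[i]
    for (h in 1:2) {
      par <- if (h == 1) ped$father[i] else ped$mother[i]
      ok <- hs$alleles[idx(kid, h), ] == hs$alleles[idx(par, 1), ] |
        hs$alleles[idx(kid, h), ] == hs$alleles[idx(par, 2), ]
      expect_true(all(ok))
    }
  }
  # duplicated parent haplotypes transmit unchanged through any crossover
  par_al <- rbind(rep(c(0L, 1L), 150), rep(c(0L, 1L), 150))
  sg <- list(start = 0, end = 80, founder = "F.1")
  tr <- ibdtrace:::.transmit_chrom(par_al, list(sg, sg),
                                   gm$panel[chrom == "chr1"]$cM, 80)
  expect_identical(tr$alleles, par_al[1, ])
})

test_that("crossover counts are Poisson(map Morgans): mean and GOF", {
  set.seed(42)
  k <- replicate(10000, length(ibdtrace:::.sample_crossovers(100)))
  expect_equal(mean(k), 1.0, tolerance = 0.05)
  obs <- table(factor(pmin(k, 4), levels = 0:4))
  p <- c(dpois(0:3, 1), ppois(3, 1, lower.tail = FALSE))
  gof <- chisq.test(obs, p = p)
  expect_gt(gof$p.value, 1e-3)
  # breakpoints uniform in cM
  set.seed(43)
  br <- unlist(replicate(4000, ibdtrace:::.sample_crossovers(100)))
  expect_gt(ks.test(br, "punif", 0, 100)$p.value, 1e-3)
})

test_that("true IBD sharing matches kinship expectations", {
  gm <- make_genetic_map(20, 150, 10, seed = 77)
  sib <- vapply(1:200, function(s)
    simulate_meioses_pair(2, gm$map, gm$panel, seed = s)$fraction, 0)
  expect_equal(mean(sib), 0.5, tolerance = 0.02)
  # first cousins (M4): expected 2 * 2^-4 = 0.125
  c1 <- vapply(1:150, function(s)
    simulate_meioses_pair(4, gm$map, gm$panel, seed = 5000 + s)$fraction, 0)
  expect_equal(mean(c1), 0.125, tolerance = 0.02)
})

test_that("focal allele planting follows founder-segment truth", {
  gm <- tiny_map(n_markers = 400, seed = 8)
  ped <- simulate_pedigree_surviving(4, 2.5, seed = 21)
  hs <- drop_haplotypes(ped, gm$map, gm$panel, seed = 3)
  allele <- focal_allele("chr1", cM_to_bp(gm$map, "chr1", 50),
                         cM_to_bp(gm$map, "chr1", 48),
                         cM_to_bp(gm$map, "chr1", 52),
                         origin_hap = paste0(ped$id[1], ".1"))
  pf <- plant_focal_allele(ped, hs, allele)
  expect_true(ped$id[1] %in% pf$carriers)    # originating founder
  spouses <- ped[founder == TRUE & generation > 0L]$id
  expect_false(any(spouses %in% pf$carriers))  # unrelated founders
  # carrier flag equals label truth at the focal marker
  fm <- pf$focal_marker
  g <- as_genotypes(pf$hapset)
  expect_identical(unname(g[, fm] > 0), unname(pf$pedigree$carrier))
  expect_error(plant_focal_allele(ped, hs,
                                  focal_allele("chr9", 1, 0, 2, "x")),
               "outside map")
  # transmission is Mendelian: carrier children of carrier x non-carrier
  # couples occur at ~1/2 across seeds
  rate <- unlist(lapply(1:40, function(s) {
    p <- simulate_pedigree_surviving(3, 3, seed = 100 + s)
    h <- drop_haplotypes(p, gm$map, gm$panel, seed = 200 + s)
    al <- focal_allele("chr1", cM_to_bp(gm$map, "chr1", 50),
                       cM_to_bp(gm$map, "chr1", 48),
                       cM_to_bp(gm$map, "chr1", 52), paste0(p$id[1], ".1"))
    pl <- plant_focal_allele(p, h, al)
    kids <- p[father == p$id[1]]
    as.integer(kids$id %in% pl$carriers)
  }))
  expect_equal(mean(rate), 0.5, tolerance = 0.08)
})

test_that("background cohort: frequencies, disjoint ids, no true IBD", {
  gm <- tiny_map(n_markers = 50, seed = 4, freq_range = c(0.05, 0.95))
  bg <- simulate_background(10000, gm$panel, gm$map, seed = 6)
  emp <- colMeans(bg$alleles)
  se <- sqrt(gm$panel$freq * (1 - gm$panel$freq) / 20000)
  expect_true(all(abs(emp - gm$panel$freq) < 5 * se + 1e-12))
  expect_false(any(grepl("^I", bg$samples)))
  expect_equal(nrow(true_ibd_segments(bg, bg$samples[1], bg$samples[2])), 0L)
  expect_equal(true_ibd_fraction(bg, bg$samples[3], bg$samples[4]), 0)
})

test_that("annotations: Dirichlet plant, limit case, null case, migration", {
  cfg <- annotate_config()
  ann <- annotate_samples(sprintf("P%02d", 1:50), sprintf("B%03d", 1:200),
                          cfg, seed = 12)
  sums <- ann$ethnicity[, .(s = sum(value)), by = sample]
  expect_true(all(abs(sums$s - 1) < 1e-9))
  # concentration -> infinity with all mass on one region: proportions (1,0,..)
  lim <- annotate_config(ingroup_alpha = c(1e8, rep(1e-9, 4)))
  al <- annotate_samples("P1", "B1", lim, seed = 1)
  p1 <- al$ethnicity[sample == "P1"][order(region)]
  expect_equal(p1[region == "scandinavia"]$value, 1, tolerance = 1e-6)
  # in-group records cluster at the bin waypoint
  rec <- suppressMessages(bin_records(ann$records, cfg$bins))
  tin <- ann$trees[sample %in% sprintf("P%02d", 1:50)]$tree_id
  for (b in cfg$bins$bin) {
    rin <- rec[tree_id %in% tin & bin == b]
    wp <- cfg$waypoints[bin == b]
    expect_lt(abs(mean(rin$lat) - wp$lat), cfg$scatter_sd)
    expect_lt(abs(mean(rin$lon) - wp$lon), cfg$scatter_sd)
  }
  # null config: in-group indistinguishable from background
  nl <- null_annotate_config(cfg)
  annN <- annotate_samples(sprintf("P%02d", 1:50), sprintf("B%03d", 1:500),
                           nl, seed = 30)
  res <- test_ethnicities(annN$ethnicity[sample %in% sprintf("P%02d", 1:50)],
                          annN$ethnicity[!sample %in% sprintf("P%02d", 1:50)])
  expect_lte(sum(res$pass), 1L)  # at most a 5%-level false positive
  expect_error(annotate_config(waypoints = data.frame(
    bin = "1700-1800", lat = 1, lon = 1)), "fewer waypoints")
})

test_that("study files round-trip losslessly and the VCF is valid", {
  gm <- tiny_map(n_chrom = 2, len = 60, n_markers = 120, seed = 14)
  ped <- simulate_pedigree_surviving(3, 2.5, seed = 5)
  hs <- drop_haplotypes(ped, gm$map, gm$panel, seed = 6)
  ann <- annotate_samples(ped$id[1:4], ped$id[-(1:4)], annotate_config(),
                          seed = 2)
  dir <- withr::local_tempdir()
  write_study(dir, hs, ped, ann, carriers = ped$id[1])
  back <- read_study(dir)
  expect_identical(unname(back$hapset$alleles), unname(hs$alleles))
  expect_equal(back$hapset$panel$bp, hs$panel$bp)
  expect_equal(back$hapset$panel$freq, hs$panel$freq)
  expect_equal(back$hapset$map$anchors, hs$map$anchors)
  expect_identical(back$hapset$samples, hs$samples)
  expect_equal(back$hapset$segs[order(sample, hap, chrom, start_cM)],
               hs$segs[order(sample, hap, chrom, start_cM)],
               ignore_attr = TRUE)
  expect_equal(back$pedigree$id, ped$id)
  expect_identical(back$carriers, ped$id[1])
  expect_equal(back$annotations$records$lat, ann$records$lat)
  # independent format check with VariantAnnotation
  vcf <- VariantAnnotation::readVcf(file.path(dir, "genotypes.vcf"))
  expect_equal(dim(vcf)[1], nrow(gm$panel))
  gt <- VariantAnnotation::geno(vcf)$GT
  expect_true(all(grepl("^[01]\\|[01]$", gt)))
  expect_identical(gt[5, 3],
                   paste0(hs$alleles[5, 5], "|", hs$alleles[6, 5]))
})

test_that("same seed gives byte-identical synthetic outputs", {
  gm <- tiny_map(n_markers = 100, seed = 31)
  a <- drop_haplotypes(simulate_pedigree_surviving(3, 2, seed = 1),
                       gm$map, gm$panel, seed = 2)
  b <- drop_haplotypes(simulate_pedigree_surviving(3, 2, seed = 1),
                       gm$map, gm$panel, seed = 2)
  expect_identical(a$alleles, b$alleles)
  expect_identical(a$segs, b$segs)
  a1 <- annotate_samples("P1", c("B1", "B2"), annotate_config(), seed = 4)
  a2 <- annotate_samples("P1", c("B1", "B2"), annotate_config(), seed = 4)
  expect_identical(a1$records, a2$records)
})
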