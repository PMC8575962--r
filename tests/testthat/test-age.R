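test_that("clock likelihood maximizers match the closed forms", {
  grid <- age_grid(0, 5, 4000)
  step <- 10^(5 / 3999)                       # multiplicative grid step
  # recombination only, two 0.01 M uncensored flanks: t* = 1/L_tot = 50
  o <- clock_observation(0.01, 0.01)
  pm <- posterior_mode(o, clock = "recombination", prior = "flat",
                       grid = grid)
  expect_lt(abs(log(pm$mode / 50)), log(step) * 1.5)
  # mutation only, m = 10 over 1e6 bp at mu = 1.25e-8: t* = m/(2 mu s) = 400
  o2 <- clock_observation(0, 0, TRUE, TRUE, mutations = 10L, span_bp = 1e6)
  pm2 <- posterior_mode(o2, clock = "mutation", prior = "flat", grid = grid)
  expect_lt(abs(log(pm2$mode / 400)), log(step) * 1.5)
  # joint log-likelihood is the sum of the clock terms
  t <- c(10, 100, 1000)
  o3 <- clock_observation(0.02, 0.005, mutations = 3L, span_bp = 2.5e6)
  expect_equal(log_likelihood(t, o3, clock = "joint"),
               log_likelihood(t, o3, clock = "recombination") +
                 log_likelihood(t, o3, clock = "mutation"))
  # censored flank contributes only the survival term
  oc <- clock_observation(0.3, 0.01, left_censored = TRUE)
  expect_equal(log_likelihood(t, oc, clock = "recombination"),
               -2 * t * 0.3 + log(2 * t) - 2 * t * 0.01)
})

test_that("posterior is normalized, scale-consistent and shrinks properly", {
  o <- clock_observation(0.004, 0.006)
  pm <- posterior_mode(o, prior = "flat", clock = "recombination")
  dx <- diff(pm$grid)
  mass <- sum((pm$posterior[-1] + pm$posterior[-length(pm$posterior)]) / 2 *
                dx)
  expect_equal(mass, 1, tolerance = 1e-6)
  expect_true(pm$lower <= pm$mode && pm$mode <= pm$upper)
  # doubling all flank lengths halves the recombination-only mode
  o2 <- clock_observation(0.008, 0.012)
  pm2 <- posterior_mode(o2, prior = "flat", clock = "recombination")
  step <- pm$grid[2] / pm$grid[1]
  expect_lt(abs(log(pm2$mode / (pm$mode / 2))), 2 * log(step) + 1e-9)
  # tighter prior (smaller Ne) pulls the mode down monotonically
  modes <- vapply(c(1e6, 1e4, 1e3, 1e2), function(ne)
    posterior_mode(o, clock_params(Ne = ne), clock = "recombination")$mode,
    0)
  expect_true(all(diff(modes) <= 1e-9))
  # no clock information at all: flagged non-identifiable under a flat prior
  onull <- clock_observation(0.5, 0.5, TRUE, TRUE, mutations = 0L,
                             span_bp = 1e6)
  pmn <- posterior_mode(onull, prior = "flat")
  expect_false(pmn$identifiable)
  expect_error(posterior_mode(list()), "at least one")
})

test_that("flank extraction follows haplotype discordance and truth labels", {
  gm <- tiny_map(n_markers = 500, seed = 9)
  m <- 500
  # identical carrier haplotypes across the chromosome: censored both sides
  h <- rbind(c(rep(0L, 249), 1L, rep(0L, 250)), rep(0L, m))
  hs <- manual_hapset(list(C1 = h, C2 = h), gm)
  al <- focal_allele("chr1", gm$panel$bp[250], gm$panel$bp[240],
                     gm$panel$bp[260], "none")
  ob <- extract_observation(hs, c("C1", "C2"), al)
  expect_true(ob$left_censored && ob$right_censored)
  expect_equal(ob$left + ob$right, 1, tolerance = 0.01)   # 100 cM = 1 M
  # discordance immediately flanking the focal site: both flanks ~ 0
  h2 <- h; h2[1, c(249, 251)] <- 1L
  hs2 <- manual_hapset(list(C1 = h, C2 = h2), gm)
  ob2 <- extract_observation(hs2, c("C1", "C2"), al)
  expect_false(ob2$left_censored || ob2$right_censored)
  expect_equal(ob2$left + ob2$right, 0, tolerance = 1e-9)
  # non-carrier input refused
  hs3 <- manual_hapset(list(C1 = h, C2 = rbind(rep(0L, m), rep(0L, m))), gm)
  expect_error(extract_observation(hs3, c("C1", "C2"), al), "not a carrier")
  # gene-dropped parent-child pair: flank end matches the truth label
  # boundary (first recombination) within a short IBS overshoot
  ped <- simulate_pedigree_surviving(3, 2.5, seed = 41)
  gm2 <- tiny_map(n_markers = 2000, seed = 10)
  hsf <- drop_haplotypes(ped, gm2$map, gm2$panel, seed = 12)
  alf <- focal_allele("chr1", cM_to_bp(gm2$map, "chr1", 50),
                      cM_to_bp(gm2$map, "chr1", 48),
                      cM_to_bp(gm2$map, "chr1", 52),
                      paste0(ped$id[1], ".1"))
  pf <- plant_focal_allele(ped, hsf, alf)
  carr <- setdiff(pf$carriers, ped$id[1])
  if (length(carr) >= 1) {
    pair <- c(ped$id[1], carr[1])
    obf <- extract_observation(pf$hapset, pair, alf)
    truth <- true_ibd_segments(pf$hapset, pair[1], pair[2])
    cover <- truth[chrom == "chr1" & start_cM <= 50 & end_cM >= 50]
    flank_l <- (50 - cover$start_cM) / 100
    flank_r <- (cover$end_cM - 50) / 100
    spacing <- 100 / 1999 / 100
    # extraction can only stop at or beyond the true boundary, and IBS
    # overshoot beyond it dies within ~2 cM with overwhelming probability
    expect_gte(obf$left, flank_l - spacing - 1e-9)
    expect_gte(obf$right, flank_r - spacing - 1e-9)
    if (!obf$left_censored) expect_lt(obf$left, flank_l + 0.02)
    if (!obf$right_censored) expect_lt(obf$right, flank_r + 0.02)
  }
})

test_that("pair-private derived alleles are counted as mutations", {
  gm <- tiny_map(n_markers = 200, seed = 22)
  m <- 200
  base <- rbind(rep(0L, m), rep(0L, m))
  hap_c <- base; hap_c[1, 100] <- 1L           # focal allele
  hap_c[1, c(80, 120, 140)] <- 1L              # shared derived sites
  other <- base
  hs <- manual_hapset(list(C1 = hap_c, C2 = hap_c, X1 = other, X2 = other),
                      gm)
  al <- focal_allele("chr1", gm$panel$bp[100], gm$panel$bp[90],
                     gm$panel$bp[110], "none")
  ob <- extract_observation(hs, c("C1", "C2"), al)
  expect_equal(ob$mutations, 3L)               # focal site itself excluded
  # a site carried by any other haplotype is not private
  hs$alleles[5, 120] <- 1L                     # X1 hap 1 carries site 120
  ob2 <- extract_observation(hs, c("C1", "C2"), al)
  expect_equal(ob2$mutations, 2L)
})

test_that("control doubletons: planted set recovered exactly", {
  set.seed(7)
  n_sites <- 60
  ids <- sprintf("v%02d", 1:n_sites)
  carriers <- matrix(rbinom(2 * n_sites, 2, 0.2), nrow = 2,
                     dimnames = list(NULL, ids))
  controls <- matrix(rbinom(30 * n_sites, 2, 0.2), nrow = 30)
  planted <- c("v05", "v17", "v44")
  carriers[, planted] <- 1L
  controls[, match(planted, ids)] <- 0L
  # remove accidental doubletons so the planted set is the unique answer
  acc <- which(carriers[1, ] >= 1 & carriers[2, ] >= 1 &
                 colSums(controls >= 1) == 0)
  acc <- setdiff(ids[acc], planted)
  controls[1, match(acc, ids)] <- 1L
  expect_setequal(find_control_doubletons(carriers, controls), planted)
  # sites failing ancestral polarization are dropped
  ok <- rep(TRUE, n_sites); ok[match("v17", ids)] <- FALSE
  expect_setequal(find_control_doubletons(carriers, controls, ok),
                  c("v05", "v44"))
  # derived allele in one carrier only is excluded
  carriers[2, "v05"] <- 0L
  expect_setequal(find_control_doubletons(carriers, controls, ok), "v44")
})

test_that("age ranking and unit conversions", {
  f <- posterior_mode(clock_observation(0.05, 0.05), prior = "flat",
                      clock = "recombination")
  expect_equal(age_rank_report(f, as.list(c(100, 200, 300)))$percentile, 0)
  same <- age_rank_report(f, as.list(rep(f$mode, 5)))
  expect_equal(same$percentile, 50)            # mean-rank tie convention
  mixed <- age_rank_report(f, as.list(c(f$mode / 2, f$mode, f$mode * 2)))
  expect_equal(mixed$percentile, 100 * (1 + 0.5) / 3)
  expect_equal(generations_to_years(200), 5000)
  expect_equal(generations_to_years(0), 0)
  expect_equal(generations_to_years(182), 4550)
  expect_equal(generations_to_years(10, 30), 300)
})

test_that("clock simulators are deterministic and carry truth", {
  ctl <- simulate_control_ages(5, seed = 3)
  ctl2 <- simulate_control_ages(5, seed = 3)
  expect_equal(vapply(ctl, `[[`, 0, "mode"),
               vapply(ctl2, `[[`, 0, "mode"))
  expect_true(all(vapply(ctl, `[[`, 0, "t_true") > 0))
  set.seed(1)
  o <- simulate_clock_observation(100, flank_censor_morgans = 0.001)
  expect_lte(o$left, 0.001)
  expect_lte(o$right, 0.001)
})
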