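# Configuration-driven end-to-end study: simulate -> detect -> network ->
# classify -> enrich -> map -> date, with a single global seed fanned out
# to per-stage child seeds and a machine-readable report.

#' Default study configuration
#'
#' Defaults mirror the analysis constants of the original pipeline where they
#' are stated (6 / 1 / 0.5 cM thresholds, enrichment alphas 0.05 / 0.001,
#' fold > 1.5, OR >= 4 with 10 or 2 unique trees, clock rates r = 1e-8,
#' mu = 1.25e-8, Ne = 10,000); simulation sizes are desk-scale choices
#' documented in the methods vignette.
#'
#' @param seed global integer seed; all stage seeds derive from it.
#' @param ... overrides for any default field.
#' @export
study_config <- function(seed, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_chromosomes = 4L, chrom_length_cM = 150, markers_per_chrom = 3000L,
    panel_freq_range = c(0.25, 0.75),
    n_generations = 8L, mean_offspring = 2.5, p_reproduce = 0.85,
    background_n = 2000L,
    focal_chrom = "chr1", focal_cM = 72, focal_window_cM = c(70, 74),
    n_known_carriers = 5L, known_min_generation = 3L,
    min_total_carriers = 8L, max_ascertain_tries = 40L,
    genotyping_error = 0.001,
    word_size = 32L, detect_min_cM = 0.5,
    genome_threshold_cM = 6, locus_threshold_cM = 1,
    small_locus_threshold_cM = 0.5,
    ibs_min_density = 5,
    ethnicity_alpha = 0.05, community_alpha = 0.001,
    community_min_fold = 1.5,
    geo_min_trees = 10L, geo_min_or = 4, geo_rounding = 2L,
    geo_small_min_trees = 2L, geo_small_rounding = 0L,
    clock = clock_params(),
    annotate = annotate_config(),
    age_n_sim_controls = 76L, age_n_controls_cohort = 99L)
  ov <- list(...)
  for (nm in names(ov)) cfg[[nm]] <- ov[[nm]]
  cfg$thresholds <- c(cfg$genome_threshold_cM, cfg$locus_threshold_cM,
                      cfg$small_locus_threshold_cM)
  structure(cfg, class = "study_config")
}

#' Validate a raw study configuration
#'
#' Accepts a `study_config`, a plain list, or a path to a JSON file.
#' @param raw configuration input.
#' @return list(config, errors): `config` is NULL when errors are present.
#' @export
validate_config <- function(raw) {
  errors <- character()
  if (is.character(raw) && length(raw) == 1L && file.exists(raw))
    raw <- jsonlite::read_json(raw, simplifyVector = TRUE)
  if (!is.list(raw)) return(list(config = NULL, errors = "not a list"))
  if (is.null(raw$seed)) errors <- c(errors, "missing field: seed")
  num_pos <- c("genome_threshold_cM", "locus_threshold_cM",
               "small_locus_threshold_cM", "chrom_length_cM",
               "mean_offspring")
  for (f in num_pos)
    if (!is.null(raw[[f]]) && (!is.numeric(raw[[f]]) || raw[[f]] <= 0))
      errors <- c(errors, paste0("field must be positive: ", f))
  if (!is.null(raw$n_known_carriers) && raw$n_known_carriers < 1)
    errors <- c(errors, "n_known_carriers must be >= 1")
  if (!is.null(raw$genotyping_error) &&
      (raw$genotyping_error < 0 || raw$genotyping_error >= 0.5))
    errors <- c(errors, "genotyping_error must be in [0, 0.5)")
  if (length(errors)) return(list(config = NULL, errors = errors))
  if (inherits(raw, "study_config"))
    return(list(config = raw, errors = character()))
  keep <- intersect(names(raw), names(study_config(1)))
  keep <- setdiff(keep, c("seed", "clock", "annotate", "thresholds"))
  cfg <- do.call(study_config, c(list(seed = raw$seed), raw[keep]))
  list(config = cfg, errors = character())
}

# child seeds: stage-level reproducibility under one global seed
.stage_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% 2147483629)
}

#' Run the full synthetic study
#'
#' Stages: genetic map & panel; pedigree ascertainment (retried until the
#' requested depth holds at least `n_known_carriers` carriers at or beyond
#' `known_min_generation` and `min_total_carriers` overall, emulating the
#' ascertainment of a large carrier-rich pedigree); gene dropping; allele
#' planting; background cohort; genotyping error; IBD detection of every
#' sample against the known carriers; match sets, sharing network, carrier
#' classification and evaluation against truth; ancestry and community
#' enrichment of the genetic-match set; time-binned birth-location
#' enrichment; allele dating from two known carriers with control
#' doubletons. Every threshold application is logged in `report$funnel`.
#'
#' @param config a `study_config` (or anything [validate_config()] takes).
#' @param out_dir optional directory for stage files and `report.json`.
#' @param write_genotypes write the (large) VCF when `out_dir` is given.
#' @return a study report list; stage objects under `report$objects`.
#' @export
run_study <- function(config, out_dir = NULL, write_genotypes = TRUE) {
  v <- validate_config(config)
  if (length(v$errors))
    stop("invalid config: ", paste(v$errors, collapse = "; "))
  cfg <- v$config
  ss <- function(k) .stage_seed(cfg$seed, k)
  funnel <- list()
  note <- function(stage, what, n_in, n_out) {
    funnel[[length(funnel) + 1L]] <<- list(stage = stage, filter = what,
                                           n_in = n_in, n_out = n_out)
  }

  gm <- make_genetic_map(cfg$n_chromosomes, cfg$chrom_length_cM,
                         cfg$markers_per_chrom, seed = ss(1),
                         freq_range = cfg$panel_freq_range)
  total_cM <- sum(map_lengths(gm$map)$length_cM)

  # -- ascertainment: pedigree + drop + plant until carrier-rich ----------
  planted <- NULL
  for (try in seq_len(cfg$max_ascertain_tries)) {
    ped <- simulate_pedigree_surviving(cfg$n_generations,
                                       cfg$mean_offspring,
                                       ss(2) + 131L * (try - 1L),
                                       cfg$p_reproduce)
    hs <- drop_haplotypes(ped, gm$map, gm$panel,
                          seed = ss(3) + 131L * (try - 1L))
    allele <- focal_allele(
      cfg$focal_chrom,
      cM_to_bp(gm$map, cfg$focal_chrom, cfg$focal_cM),
      cM_to_bp(gm$map, cfg$focal_chrom, cfg$focal_window_cM[1]),
      cM_to_bp(gm$map, cfg$focal_chrom, cfg$focal_window_cM[2]),
      origin_hap = paste0(ped$id[1], ".1"))
    pf <- plant_focal_allele(ped, hs, allele)
    eligible <- pf$pedigree[carrier == TRUE &
                              generation >= cfg$known_min_generation]$id
    if (length(eligible) >= cfg$n_known_carriers &&
        length(pf$carriers) >= cfg$min_total_carriers) {
      planted <- pf; break
    }
  }
  if (is.null(planted))
    stop("stage pedigree: no carrier-rich pedigree found in ",
         cfg$max_ascertain_tries, " attempts")
  ped <- planted$pedigree
  set.seed(ss(4))
  knowns <- sort(sample(eligible, cfg$n_known_carriers))

  bg <- simulate_background(cfg$background_n, gm$panel, gm$map, seed = ss(5))
  all_hs <- bind_hapsets(planted$hapset, bg)
  truth <- stats::setNames(all_hs$samples %in% planted$carriers,
                           all_hs$samples)
  obs_hs <- add_genotyping_error(all_hs, cfg$genotyping_error, seed = ss(6))

  # -- IBD detection against the known carriers ---------------------------
  others <- setdiff(all_hs$samples, knowns)
  pairs <- rbind(CJ(id_a = knowns, id_b = others),
                 if (length(knowns) > 1L) .all_pairs(knowns) else NULL)
  segments <- detect_ibd(obs_hs, word_size = cfg$word_size,
                         min_cM = min(cfg$detect_min_cM,
                                      cfg$small_locus_threshold_cM),
                         pairs = pairs)
  seg_genome <- ibs_density_filter(segments, cfg$ibs_min_density)
  note("ibd", "ibs_density_filter", nrow(segments), nrow(seg_genome))

  allele <- focal_allele(
    cfg$focal_chrom,
    cM_to_bp(gm$map, cfg$focal_chrom, cfg$focal_cM),
    cM_to_bp(gm$map, cfg$focal_chrom, cfg$focal_window_cM[1]),
    cM_to_bp(gm$map, cfg$focal_chrom, cfg$focal_window_cM[2]),
    origin_hap = paste0(ped$id[1], ".1"))
  window <- locus_window_cM(gm$map, allele)
  ms <- build_match_sets(segments, knowns, window,
                         genome_threshold = cfg$genome_threshold_cM,
                         locus_threshold = cfg$locus_threshold_cM,
                         genome_segments = seg_genome)
  note("match", "genome > 6 cM", length(others),
       length(ms$genetic_matches))
  note("match", "locus > 1 cM", length(ms$genetic_matches),
       length(ms$at_locus_matches))

  net <- build_network(segments, window, total_map_cM = total_cM)
  calls <- classify_carriers(ms, samples = others)
  hist <- degree_histogram(calls)
  ev <- evaluate_calls(calls, truth)
  note("classify", "all-carriers rule", length(ms$at_locus_matches),
       sum(calls$class == "putative_carrier"))

  # -- enrichment ---------------------------------------------------------
  in_ids <- ms$genetic_matches
  # annotation in-group: the pedigree's blood members (founder couple and
  # descendants); married-in spouses carry background ancestry and trees
  blood <- ped[founder == FALSE | generation == 0L]$id
  ann <- annotate_samples(
    ingroup_ids = blood,
    background_ids = setdiff(all_hs$samples, blood),
    config = cfg$annotate, seed = ss(7))
  eth_in <- ann$ethnicity[sample %in% in_ids]
  eth_bg <- ann$ethnicity[!sample %in% c(in_ids, knowns)]
  eth_res <- test_ethnicities(eth_in, eth_bg, alpha = cfg$ethnicity_alpha)
  com_res <- test_communities(ann$communities[sample %in% in_ids],
                              ann$communities[!sample %in% c(in_ids, knowns)],
                              alpha = cfg$community_alpha,
                              min_fold = cfg$community_min_fold)

  trees_in <- ann$trees[sample %in% in_ids]$tree_id
  rec <- bin_records(ann$records, cfg$annotate$bins)
  geo <- location_enrichment(rec[tree_id %in% trees_in],
                             rec[!tree_id %in% trees_in],
                             rounding = cfg$geo_rounding,
                             min_trees = cfg$geo_min_trees,
                             min_or = cfg$geo_min_or)
  put <- calls[class == "putative_carrier"]$sample
  trees_put <- ann$trees[sample %in% put]$tree_id
  geo_small <- small_set_mode(rec[tree_id %in% trees_put],
                              rec[!tree_id %in% trees_put],
                              min_trees = cfg$geo_small_min_trees,
                              rounding = cfg$geo_small_rounding,
                              min_or = cfg$geo_min_or)

  # -- allele dating ------------------------------------------------------
  # the most distantly related known-carrier pair (least true sharing),
  # mirroring the choice of distant carriers for sequencing
  kp <- utils::combn(knowns, 2L)
  kfrac <- vapply(seq_len(ncol(kp)), function(i)
    true_ibd_fraction(all_hs, kp[1, i], kp[2, i]), 0)
  date_pair <- kp[, which.min(kfrac)]
  hap_of <- vapply(date_pair, function(id) {
    fcM <- cfg$focal_cM
    sg <- all_hs$segs[sample == id & chrom == cfg$focal_chrom &
                        start_cM <= fcM & end_cM > fcM &
                        founder == allele$origin_hap]
    sg$hap[1]
  }, integer(1))
  focal_obs <- extract_observation(obs_hs, date_pair, allele,
                                   carrier_haps = hap_of,
                                   consecutive_discordance = 2L)
  focal_age <- posterior_mode(focal_obs, cfg$clock, variant_id = "focal")
  # doubleton scan on the array panel (reported for completeness: a
  # common-variant panel essentially never yields control doubletons; the
  # control distribution is simulated from the pairwise coalescent instead)
  ctrl_ids <- utils::tail(bg$samples, cfg$age_n_controls_cohort)
  g <- as_genotypes(obs_hs)
  cg <- g[date_pair, , drop = FALSE]
  colnames(cg) <- obs_hs$panel$marker
  dblt <- find_control_doubletons(cg, g[ctrl_ids, , drop = FALSE])
  dblt <- setdiff(dblt, obs_hs$panel$marker[planted$focal_marker])
  note("age", "array control doubletons", ncol(g), length(dblt))
  ctrl_ages <- simulate_control_ages(cfg$age_n_sim_controls, cfg$clock,
                                     seed = ss(8))
  rank_rep <- age_rank_report(focal_age, ctrl_ages)

  report <- list(
    package_version = as.character(utils::packageVersion("ibdtrace")),
    config = cfg[setdiff(names(cfg), c("clock", "annotate"))],
    counts = list(
      pedigree_size = nrow(ped),
      true_carriers = length(planted$carriers),
      known_carriers = knowns,
      database_size = length(others),
      genetic_matches = length(ms$genetic_matches),
      at_locus_matches = length(ms$at_locus_matches),
      degree_histogram = if (nrow(hist)) as.list(
        stats::setNames(hist$count, hist$degree)) else list(),
      putative_carriers = sum(calls$class == "putative_carrier")),
    evaluation = ev[c("ppv", "sensitivity", "specificity")],
    enrichment = list(
      ethnicity_pass = eth_res[pass == TRUE]$region,
      community_pass = com_res[pass == TRUE]$community),
    geo = list(
      n_pass_cells = nrow(geo[pass == TRUE]),
      top_cells = geo[pass == TRUE][order(bin, -odds_ratio),
                                    utils::head(.SD, 1), by = bin],
      n_pass_cells_small = nrow(geo_small[pass == TRUE])),
    age = list(mode = focal_age$mode, lower = focal_age$lower,
               upper = focal_age$upper,
               years = generations_to_years(focal_age$mode,
                                            cfg$clock$generation_years),
               n_controls = length(ctrl_ages),
               n_array_doubletons = length(dblt),
               percentile = rank_rep$percentile,
               note = paste("controls simulated from the pairwise",
                            "coalescent; pairs combined by summed",
                            "log-likelihood ignoring genealogical",
                            "correlation")),
    funnel = funnel)

  objects <- list(map = gm$map, panel = gm$panel, pedigree = ped,
                  hapset = all_hs, observed = obs_hs, knowns = knowns,
                  carriers = planted$carriers, segments = segments,
                  seg_genome = seg_genome, match_sets = ms, network = net,
                  calls = calls, histogram = hist, evaluation = ev,
                  ethnicity = eth_res, communities = com_res, geo = geo,
                  geo_small = geo_small, annotations = ann,
                  focal_age = focal_age, control_ages = ctrl_ages,
                  window = window, allele = allele, truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (write_genotypes)
      write_study(out_dir, obs_hs, ped, ann, planted$carriers)
    write_match_file(segments, file.path(out_dir, "segments.match"))
    fwrite(calls, file.path(out_dir, "carrier_calls.csv"))
    fwrite(eth_res, file.path(out_dir, "ethnicity_enrichment.csv"))
    fwrite(com_res, file.path(out_dir, "community_enrichment.csv"))
    export_map(geo, file.path(out_dir, "geo_cells.geojson"),
               file.path(out_dir, "geo_cells.csv"))
    export_network(net, file.path(out_dir, "network_edges.csv"),
                   file.path(out_dir, "network.graphml"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report$objects <- objects
  report
}
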