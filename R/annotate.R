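# Synthetic ancestry annotations and genealogical birth records. The
# generator states a world: an in-group (pedigree-descended samples) with
# elevated Dirichlet means for planted regions, one enriched fine-scale
# community label, and family trees whose birth records cluster around a
# bin-specific migration waypoint; the background draws from a diffuse
# baseline. Enrichment tests downstream must recover exactly this plant.

#' Configuration for the annotation generator
#'
#' @param regions broad-scale region labels.
#' @param baseline_alpha Dirichlet parameters of background proportions.
#' @param ingroup_alpha Dirichlet parameters of in-group proportions
#'   (elevated mass on planted regions).
#' @param planted_regions labels whose enrichment is planted.
#' @param communities community label universe.
#' @param enriched_community the planted community label.
#' @param p_enriched_in,p_enriched_bg probability of the enriched label in
#'   the two groups.
#' @param p_other_community per-label probability of every other community
#'   (identical in both groups).
#' @param waypoints data.frame(bin, lat, lon), one row per time bin: the
#'   planted migration path.
#' @param scatter_sd Gaussian scatter (degrees) of in-group records around
#'   the waypoint.
#' @param settlement_spacing records snap to a settlement grid of this many
#'   degrees (real records concentrate at named places; without snapping,
#'   2-decimal cells would almost never aggregate).
#' @param records_per_bin_mean Poisson mean ancestor records per tree & bin.
#' @param background_lat,background_lon ranges of the diffuse background.
#' @param bins time-bin table, see [default_time_bins()].
#' @export
annotate_config <- function(
    regions = c("scandinavia", "england_nw_europe", "eastern_europe",
                "iberia", "other"),
    baseline_alpha = 10 * c(0.10, 0.25, 0.25, 0.15, 0.25),
    ingroup_alpha = 20 * c(0.45, 0.35, 0.10, 0.04, 0.06),
    planted_regions = c("scandinavia", "england_nw_europe"),
    communities = c("mountain_west_pioneers", sprintf("GC%02d", 1:29)),
    enriched_community = "mountain_west_pioneers",
    p_enriched_in = 0.75, p_enriched_bg = 0.03,
    p_other_community = 0.04,
    waypoints = data.frame(bin = c("1700-1800", "1800-1850", "1850-1910"),
                           lat = c(56.0, 41.0, 40.5),
                           lon = c(10.0, -74.0, -111.5)),
    scatter_sd = 0.5, settlement_spacing = 0.5,
    records_per_bin_mean = 3,
    background_lat = c(35, 60), background_lon = c(-115, 15),
    bins = default_time_bins()) {
  if (nrow(waypoints) < nrow(bins))
    stop("fewer waypoints than time bins")
  stopifnot(length(baseline_alpha) == length(regions),
            length(ingroup_alpha) == length(regions),
            all(planted_regions %in% regions),
            enriched_community %in% communities)
  structure(list(regions = regions, baseline_alpha = baseline_alpha,
                 ingroup_alpha = ingroup_alpha,
                 planted_regions = planted_regions,
                 communities = communities,
                 enriched_community = enriched_community,
                 p_enriched_in = p_enriched_in,
                 p_enriched_bg = p_enriched_bg,
                 p_other_community = p_other_community,
                 waypoints = as.data.table(waypoints),
                 scatter_sd = scatter_sd,
                 settlement_spacing = settlement_spacing,
                 records_per_bin_mean = records_per_bin_mean,
                 background_lat = background_lat,
                 background_lon = background_lon,
                 bins = as.data.table(bins)),
            class = "annotate_config")
}

#' Null annotation configuration (in-group drawn from the background world)
#'
#' In-group ancestry, community and spatial distributions all equal the
#' background's: downstream enrichment should find nothing beyond its
#' false-positive rate.
#' @param config a base [annotate_config()].
#' @export
null_annotate_config <- function(config = annotate_config()) {
  config$ingroup_alpha <- config$baseline_alpha
  config$p_enriched_in <- config$p_enriched_bg
  config$scatter_sd <- NA_real_  # sentinel: draw in-group records diffusely
  config
}

.rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Generate ancestry annotations and tree birth records
#'
#' @param ingroup_ids,background_ids sample id vectors (disjoint).
#' @param config an [annotate_config()].
#' @param seed integer seed.
#' @return list with `ethnicity` (sample, region, value; proportions sum to
#'   1 per sample), `communities` (sample, community), `records` (tree_id,
#'   ancestor_id, year, lat, lon), `trees` (sample, tree_id) linking each
#'   sample to its family tree, and the echoed `config`.
#' @export
annotate_samples <- function(ingroup_ids, background_ids, config, seed) {
  set.seed(as.integer(seed))
  ids <- c(ingroup_ids, background_ids)
  grp <- rep(c("in", "bg"), c(length(ingroup_ids), length(background_ids)))

  props <- rbind(.rdirichlet(length(ingroup_ids), config$ingroup_alpha),
                 .rdirichlet(length(background_ids), config$baseline_alpha))
  eth <- data.table(sample = rep(ids, each = length(config$regions)),
                    region = rep(config$regions, length(ids)),
                    value = as.vector(t(props)))

  p_enr <- ifelse(grp == "in", config$p_enriched_in, config$p_enriched_bg)
  comm <- list(data.table(
    sample = ids[stats::runif(length(ids)) < p_enr],
    community = config$enriched_community))
  for (cm in setdiff(config$communities, config$enriched_community)) {
    hit <- ids[stats::runif(length(ids)) < config$p_other_community]
    if (length(hit))
      comm[[length(comm) + 1L]] <- data.table(sample = hit, community = cm)
  }
  comm <- rbindlist(comm)[order(sample, community)]

  trees <- data.table(sample = ids,
                      tree_id = sprintf("T%05d", seq_along(ids)))
  snap <- function(x) round(x / config$settlement_spacing) *
    config$settlement_spacing
  diffuse_ingroup <- is.na(config$scatter_sd)
  nbin <- nrow(config$bins)
  # one Poisson record count per (sample, bin), then bulk coordinate draws
  counts <- data.table(
    tree_id = rep(trees$tree_id, each = nbin),
    clustered = rep(grp == "in" & !diffuse_ingroup, each = nbin),
    bin_i = rep(seq_len(nbin), length(ids)),
    nrec = stats::rpois(length(ids) * nbin, config$records_per_bin_mean))
  counts <- counts[nrec > 0L]
  records <- counts[, .(tree_id = rep(tree_id, nrec),
                        clustered = rep(clustered, nrec),
                        bin_i = rep(bin_i, nrec))]
  records[, ancestor_id := sprintf("%s.A%d.%d", tree_id, bin_i,
                                   seq_len(.N)), by = .(tree_id, bin_i)]
  yr_hi <- config$bins$to - c(rep(1L, nbin - 1L), 0L)
  records[, year := config$bins$from[bin_i] +
            floor(stats::runif(.N) * (yr_hi[bin_i] -
                                        config$bins$from[bin_i] + 1L))]
  wlat <- config$waypoints$lat; wlon <- config$waypoints$lon
  sd_use <- if (diffuse_ingroup) 1 else config$scatter_sd
  records[, `:=`(
    lat = fifelse(clustered,
                  stats::rnorm(.N, wlat[bin_i], sd_use),
                  stats::runif(.N, config$background_lat[1],
                               config$background_lat[2])),
    lon = fifelse(clustered,
                  stats::rnorm(.N, wlon[bin_i], sd_use),
                  stats::runif(.N, config$background_lon[1],
                               config$background_lon[2])))]
  records[, `:=`(lat = round(pmin(90, pmax(-90, snap(lat))), 2),
                 lon = round(pmin(180, pmax(-180, snap(lon))), 2),
                 clustered = NULL, bin_i = NULL)]
  list(ethnicity = eth, communities = comm, records = records,
       trees = trees, config = config)
}
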