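#' @useDynLib ibdtrace, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

# Quiet R CMD check notes for data.table NSE column names.
utils::globalVariables(c(
  "chrom", "bp", "cM", "freq", "marker", "founder", "hap", "start_cM",
  "end_cM", "sample_id", "id_a", "id_b", "length_cM", "start_bp", "end_bp",
  "n_markers", "carrier", "generation", "region", "value", "community",
  "tree_id", "year", "lat", "lon", "bin", "cell_lat", "cell_lon", "n_in",
  "n_bg", "odds_ratio", "pass", "degree", "class", "i.cM", "overlap_cM",
  "shared_cM", "at_locus_cM", "father", "mother", ".", "..keep",
  "ov", "s", "e", "start_cM.a", "start_cM.b", "end_cM.a", "end_cM.b",
  "V1", "founder_bool", "meioses", "k_hits", "adj_p", "fold", "p_value",
  "median_in", "n_markers_seg", "density", "known", "origin", "L", "E",
  "other", "max_seg_cM", "from", "to", "tot_in", "tot_bg", "log2_or",
  "n_in_records", "n_bg_records", "count", "clustered", "bin_i",
  "ancestor_id", "nrec", "panel_freq_range"
))

#' Construct a genetic map from anchor coordinates
#'
#' A genetic map gives, per chromosome, a strictly increasing table of
#' physical positions (bp) and genetic positions (cM). Genetic position
#' between anchors is linearly interpolated; everything downstream (segment
#' lengths, thresholds, crossover placement) is measured on this map.
#'
#' @param anchors data.frame with columns `chrom`, `bp`, `cM`.
#' @return An object of class `genetic_map`.
#' @export
genetic_map <- function(anchors) {
  dt <- as.data.table(anchors)[, .(chrom = as.character(chrom),
                                   bp = as.numeric(bp), cM = as.numeric(cM))]
  setkey(dt, chrom, bp)
  for (ch in unique(dt$chrom)) {
    sub <- dt[chrom == ch]
    if (nrow(sub) < 2L)
      stop("genetic map needs >= 2 anchors per chromosome (", ch, ")")
    if (any(diff(sub$bp) <= 0) || any(diff(sub$cM) <= 0))
      stop("map positions must be strictly increasing on chromosome ", ch)
  }
  if (sum(dt[, max(cM) - min(cM), by = chrom]$V1) <= 0)
    stop("total map length must be positive")
  structure(list(anchors = dt), class = "genetic_map")
}

#' @export
print.genetic_map <- function(x, ...) {
  len <- map_lengths(x)
  cat("<genetic_map> ", nrow(len), " chromosome(s), total ",
      round(sum(len$length_cM), 2), " cM\n", sep = "")
  invisible(x)
}

#' Chromosome spans of a genetic map
#'
#' @param map a `genetic_map`.
#' @return data.table with `chrom`, `start_cM`, `end_cM`, `length_cM`,
#'   `start_bp`, `end_bp`.
#' @export
map_lengths <- function(map) {
  map$anchors[, .(start_cM = min(cM), end_cM = max(cM),
                  length_cM = max(cM) - min(cM),
                  start_bp = min(bp), end_bp = max(bp)), by = chrom]
}

#' Interpolate genetic position (cM) at physical positions
#'
#' Linear interpolation between map anchors; positions outside the anchored
#' span are clamped to the ends (rule = 2).
#'
#' @param map a `genetic_map`.
#' @param chrom_id chromosome id (scalar).
#' @param bp numeric vector of physical positions.
#' @export
bp_to_cM <- function(map, chrom_id, bp) {
  a <- map$anchors[chrom == as.character(chrom_id)]
  if (nrow(a) == 0L) stop("chromosome not on map: ", chrom_id)
  stats::approx(a$bp, a$cM, xout = bp, rule = 2)$y
}

#' Interpolate physical position (bp) at genetic positions
#' @inheritParams bp_to_cM
#' @param cM numeric vector of genetic positions.
#' @export
cM_to_bp <- function(map, chrom_id, cM) {
  a <- map$anchors[chrom == as.character(chrom_id)]
  if (nrow(a) == 0L) stop("chromosome not on map: ", chrom_id)
  stats::approx(a$cM, a$bp, xout = cM, rule = 2)$y
}

#' Generate a synthetic genetic map and marker panel
#'
#' Markers are evenly spaced in genetic distance so that the cM span of each
#' chromosome is exactly `chrom_length_cM` (first marker at 0, last at the
#' span). Physical positions accumulate jittered gaps at roughly 1 Mb per cM,
#' emulating local variation in recombination rate. Founder alt-allele
#' frequencies are drawn from `freq_range` (uniform), the regime of a
#' genotyping array's common variants.
#'
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_cM genetic length per chromosome, cM.
#' @param n_markers markers per chromosome (>= 2).
#' @param seed integer seed; same seed gives byte-identical output.
#' @param freq_range length-2 numeric, uniform range for founder frequencies.
#' @return list with elements `map` (a `genetic_map` whose anchors are the
#'   markers) and `panel` (data.table: marker, chrom, bp, cM, ref, alt, freq).
#' @export
make_genetic_map <- function(n_chromosomes, chrom_length_cM, n_markers, seed,
                             freq_range = c(0.05, 0.95)) {
  if (n_chromosomes < 1L || n_markers < 2L || chrom_length_cM <= 0)
    stop("need n_chromosomes >= 1, n_markers >= 2, chrom_length_cM > 0")
  set.seed(as.integer(seed))
  bases <- c("A", "C", "G", "T")
  panel <- rbindlist(lapply(seq_len(n_chromosomes), function(ci) {
    cm <- seq(0, chrom_length_cM, length.out = n_markers)
    gaps_cm <- diff(cm)
    gaps_bp <- pmax(1, round(gaps_cm * 1e6 * stats::runif(n_markers - 1L, 0.5, 1.5)))
    bp <- cumsum(c(1, gaps_bp))
    ref <- sample(bases, n_markers, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    data.table(marker = sprintf("chr%d:%d", ci, bp),
               chrom = sprintf("chr%d", ci), bp = bp, cM = cm,
               ref = ref, alt = unname(alt),
               freq = stats::runif(n_markers, freq_range[1], freq_range[2]))
  }))
  setkey(panel, chrom, bp)
  list(map = genetic_map(panel[, .(chrom, bp, cM)]), panel = panel)
}
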