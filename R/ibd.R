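# Unphased IBD detection in the GERMLINE regime: exact haplotype seed
# matches are extended at genotype level until an opposite-homozygote
# marker, so reported segments are unphased even though seeding is phased.

.canonical_pair <- function(a, b) {
  sw <- a > b
  list(a = ifelse(sw, b, a), b = ifelse(sw, a, b))
}

.all_pairs <- function(ids) {
  cb <- utils::combn(ids, 2L)
  data.table(id_a = cb[1, ], id_b = cb[2, ])
}

.segments_dt <- function() {
  data.table(id_a = character(), id_b = character(), chrom = character(),
             start_bp = numeric(), end_bp = numeric(),
             start_cM = numeric(), end_cM = numeric(),
             length_cM = numeric(), n_markers = integer())
}

.runs_to_segments <- function(runs, a, b, ch, panel_ch) {
  if (nrow(runs) == 0L) return(NULL)
  data.table(id_a = a, id_b = b, chrom = ch,
             start_bp = panel_ch$bp[runs[, 1]],
             end_bp = panel_ch$bp[runs[, 2]],
             start_cM = panel_ch$cM[runs[, 1]],
             end_cM = panel_ch$cM[runs[, 2]],
             length_cM = panel_ch$cM[runs[, 2]] - panel_ch$cM[runs[, 1]],
             n_markers = runs[, 2] - runs[, 1] + 1L)
}

#' Detect unphased IBD segments by seeded haplotype matching
#'
#' For every requested pair, haplotype seed matches (`word_size` consecutive
#' exactly-agreeing markers on any of the four haplotype pairings) are
#' extended in both directions at genotype level until an opposite-homozygote
#' marker (heterozygous mismatches never stop extension; up to
#' `max_hom_mismatch` opposite homozygotes may be absorbed). Runs shorter
#' than `min_cM` are dropped. Pairs are reported in canonical (sorted) order.
#'
#' @param hs a `hapset` (all samples share its marker panel).
#' @param word_size seed length in markers, >= 8.
#' @param min_cM minimum reported segment length, cM.
#' @param max_hom_mismatch opposite-homozygote markers tolerated inside a
#'   run (genotyping-error absorption); default 0, the plain extension rule.
#' @param pairs optional data.frame/data.table with columns `id_a`, `id_b`
#'   restricting which pairs are scanned (default: all pairs).
#' @return data.table(id_a, id_b, chrom, start_bp, end_bp, start_cM,
#'   end_cM, length_cM, n_markers).
#' @export
detect_ibd <- function(hs, word_size = 64L, min_cM = 6, max_hom_mismatch = 0L,
                       pairs = NULL) {
  if (length(hs$samples) < 2L) stop("need at least two samples")
  if (word_size < 8L) stop("word_size must be >= 8")
  if (is.null(pairs)) pairs <- .all_pairs(hs$samples)
  pairs <- as.data.table(pairs)
  cp <- .canonical_pair(pairs$id_a, pairs$id_b)
  ci <- .chrom_index(hs$panel)
  chroms <- names(ci)
  cs <- vapply(ci, function(x) x$idx[1], 0L)
  ce <- vapply(ci, function(x) x$idx[length(x$idx)], 0L)
  hits <- detect_pairs_batch(t(hs$alleles),
                             match(cp$a, hs$samples),
                             match(cp$b, hs$samples),
                             cs, ce, as.integer(word_size),
                             as.integer(max_hom_mismatch))
  if (length(hits$pair) == 0L) return(.segments_dt())
  res <- data.table(id_a = cp$a[hits$pair], id_b = cp$b[hits$pair],
                    chrom = chroms[hits$chrom],
                    start_bp = hs$panel$bp[hits$start],
                    end_bp = hs$panel$bp[hits$end],
                    start_cM = hs$panel$cM[hits$start],
                    end_cM = hs$panel$cM[hits$end],
                    length_cM = hs$panel$cM[hits$end] -
                      hs$panel$cM[hits$start],
                    n_markers = hits$end - hits$start + 1L)
  res <- res[length_cM >= min_cM]
  setkey(res, id_a, id_b, chrom, start_cM)
  res[]
}

#' Brute-force IBD oracle: maximal opposite-homozygote-free runs
#'
#' Scans every marker of every pair for opposite homozygosity and emits the
#' maximal clean runs of length >= `min_cM`, with no seeding requirement.
#' Independent of the seeded detector; used as its testing oracle on small
#' instances (guarded at 1e7 pair-marker comparisons).
#'
#' @inheritParams detect_ibd
#' @export
brute_force_ibd <- function(hs, min_cM = 6, pairs = NULL) {
  if (is.null(pairs)) pairs <- .all_pairs(hs$samples)
  pairs <- as.data.table(pairs)
  m <- ncol(hs$alleles)
  if (nrow(pairs) * m > 1e7)
    stop("instance too large for brute force (", nrow(pairs) * m,
         " pair-marker comparisons)")
  g <- as_genotypes(hs)
  ci <- .chrom_index(hs$panel)
  out <- list()
  for (p in seq_len(nrow(pairs))) {
    cp <- .canonical_pair(pairs$id_a[p], pairs$id_b[p])
    a <- cp$a; b <- cp$b
    ga <- g[a, ]; gb <- g[b, ]
    for (ch in names(ci)) {
      cols <- ci[[ch]]$idx
      opp <- which(abs(ga[cols] - gb[cols]) == 2L)
      bounds <- c(0L, opp, length(cols) + 1L)
      starts <- utils::head(bounds, -1L) + 1L
      ends <- utils::tail(bounds, -1L) - 1L
      keep <- ends >= starts
      if (!any(keep)) next
      runs <- cbind(starts[keep], ends[keep])
      seg <- .runs_to_segments(runs, a, b, ch,
                               list(bp = hs$panel$bp[cols],
                                    cM = hs$panel$cM[cols]))
      out[[length(out) + 1L]] <- seg
    }
  }
  res <- rbindlist(out)
  if (length(out) == 0L || nrow(res) == 0L) return(.segments_dt())
  res <- res[length_cM >= min_cM]
  setkey(res, id_a, id_b, chrom, start_cM)
  res[]
}

#' Marker-density (IBS proxy) filter for reported segments
#'
#' Genome-wide matching pipelines filter out shared DNA that is likely
#' identical-by-state rather than by descent. The proprietary filter of the
#' original pipeline is unrecoverable; as a stand-in, segments must carry at
#' least `min_per_cM` genotyped markers per cM (sparse support is the IBS
#' signature on arrays). Disabled for at-locus scans, as in the original
#' pipeline.
#'
#' @param segments segment table from [detect_ibd()].
#' @param min_per_cM minimum marker density inside a segment (default 5,
#'   i.e. one marker per 0.2 cM).
#' @export
ibs_density_filter <- function(segments, min_per_cM = 5) {
  segments[n_markers / pmax(length_cM, 1e-9) >= min_per_cM]
}

#' Locus window in genetic coordinates
#' @param map a `genetic_map`.
#' @param allele a [focal_allele()].
#' @return list(chrom, start_cM, end_cM).
#' @export
locus_window_cM <- function(map, allele) {
  list(chrom = allele$chrom,
       start_cM = bp_to_cM(map, allele$chrom, allele$window_start),
       end_cM = bp_to_cM(map, allele$chrom, allele$window_end))
}

#' cM overlap of segments with a locus window
#'
#' Length of the interval intersection in cM; 0 when disjoint or on another
#' chromosome. Vectorized over segment rows.
#'
#' @param segments segment table.
#' @param window list(chrom, start_cM, end_cM), see [locus_window_cM()].
#' @export
locus_overlap <- function(segments, window) {
  ifelse(segments$chrom == window$chrom,
         pmax(0, pmin(segments$end_cM, window$end_cM) -
                pmax(segments$start_cM, window$start_cM)),
         0)
}

#' Build genetic-match and at-locus match sets against known carriers
#'
#' `genetic_matches`: samples sharing at least one segment strictly longer
#' than `genome_threshold` cM with at least one known carrier (on the
#' `genome_segments` table, typically IBS-filtered). `at_locus_matches`: the
#' genetic matches whose summed segment overlap with the locus window
#' exceeds `locus_threshold` cM for at least one known carrier, measured on
#' `segments` (typically unfiltered, detected at a lower length threshold).
#' Known carriers are the anchors of the scan and are excluded from both
#' sets. Both thresholds are strict (>), following the published wording.
#'
#' @param segments segment table used for at-locus overlap.
#' @param known_carriers character vector of known carrier sample ids.
#' @param window locus window from [locus_window_cM()].
#' @param genome_threshold genome-wide single-segment threshold, cM.
#' @param locus_threshold summed at-locus overlap threshold, cM.
#' @param genome_segments segment table for the genome-wide rule
#'   (default: `segments`).
#' @return object of class `match_sets`: list(genetic_matches,
#'   at_locus_matches, carrier_overlap, known_carriers, thresholds).
#' @export
build_match_sets <- function(segments, known_carriers, window,
                             genome_threshold = 6, locus_threshold = 1,
                             genome_segments = segments) {
  if (genome_threshold <= 0 || locus_threshold <= 0)
    stop("thresholds must be positive")
  seg_k <- .pair_vs_carriers(segments, known_carriers)
  gen_k <- .pair_vs_carriers(genome_segments, known_carriers)
  genome_tot <- gen_k[, .(genome_cM = sum(length_cM),
                          max_seg_cM = max(length_cM)),
                      by = .(sample = other, known)]
  genetic <- sort(unique(genome_tot[max_seg_cM > genome_threshold]$sample))
  seg_k[, overlap_cM := locus_overlap(seg_k, window)]
  loc_tot <- seg_k[, .(at_locus_cM = sum(overlap_cM)),
                   by = .(sample = other, known)]
  at_locus_all <- loc_tot[at_locus_cM > locus_threshold,
                          .(sample, known, at_locus_cM)]
  at_locus <- sort(intersect(unique(at_locus_all$sample), genetic))
  ov <- merge(loc_tot,
              genome_tot[, .(sample, known, genome_cM)],
              by = c("sample", "known"), all = TRUE)
  for (cc in c("at_locus_cM", "genome_cM"))
    ov[is.na(get(cc)), (cc) := 0]
  structure(list(genetic_matches = genetic, at_locus_matches = at_locus,
                 carrier_overlap = ov[order(sample, known)],
                 known_carriers = known_carriers,
                 thresholds = c(genome = genome_threshold,
                                locus = locus_threshold)),
            class = "match_sets")
}

# segments where exactly one side is a known carrier, reshaped to
# (other sample, known carrier) orientation
.pair_vs_carriers <- function(segments, known_carriers) {
  s1 <- segments[id_a %in% known_carriers & !id_b %in% known_carriers]
  s1 <- s1[, c(list(known = id_a, other = id_b), .SD),
           .SDcols = setdiff(names(segments), c("id_a", "id_b"))]
  s2 <- segments[id_b %in% known_carriers & !id_a %in% known_carriers]
  s2 <- s2[, c(list(known = id_b, other = id_a), .SD),
           .SDcols = setdiff(names(segments), c("id_a", "id_b"))]
  rbind(s1, s2)
}

#' @export
print.match_sets <- function(x, ...) {
  cat("<match_sets> ", length(x$genetic_matches), " genetic matches (> ",
      x$thresholds["genome"], " cM), ", length(x$at_locus_matches),
      " at-locus (> ", x$thresholds["locus"], " cM)\n", sep = "")
  invisible(x)
}

#' Write segments in a GERMLINE-.match-like tab-separated format
#' @param segments segment table.
#' @param path output file.
#' @export
write_match_file <- function(segments, path) {
  fwrite(segments, path, sep = "\t")
  invisible(path)
}

#' Read a match file written by [write_match_file()]
#' @param path file path.
#' @export
read_match_file <- function(path) {
  res <- fread(path, sep = "\t",
               colClasses = list(character = c("id_a", "id_b", "chrom")))
  setkey(res, id_a, id_b, chrom, start_cM)
  res[]
}
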