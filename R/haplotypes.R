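# Haplotype sets: phased 0/1 alleles over a marker panel plus, per
# haplotype, a tiling of each chromosome by founder-segment labels. The
# labels are the gene-dropping truth: two samples are truly IBD wherever
# their label intervals name the same founder haplotype, which gives an
# exact oracle for the IBD detector.

#' Construct a haplotype set
#'
#' @param samples character vector of sample ids.
#' @param alleles integer matrix (2 * n_samples) x n_markers of 0/1 alleles;
#'   rows ordered (sample1.hap1, sample1.hap2, sample2.hap1, ...).
#' @param segs data.table(sample, hap, chrom, start_cM, end_cM, founder):
#'   founder-origin label intervals tiling each chromosome per haplotype.
#' @param panel marker panel (see [make_genetic_map()]).
#' @param map a `genetic_map`.
#' @return object of class `hapset`.
#' @export
hapset <- function(samples, alleles, segs, panel, map) {
  stopifnot(nrow(alleles) == 2L * length(samples),
            ncol(alleles) == nrow(panel))
  rownames(alleles) <- paste(rep(samples, each = 2L), 1:2, sep = ".")
  structure(list(samples = samples, alleles = alleles,
                 segs = as.data.table(segs), panel = panel, map = map),
            class = "hapset")
}

#' @export
print.hapset <- function(x, ...) {
  cat("<hapset> ", length(x$samples), " samples x ", ncol(x$alleles),
      " markers\n", sep = "")
  invisible(x)
}

# per-chromosome marker column indices and cM positions
.chrom_index <- function(panel) {
  sp <- split(seq_len(nrow(panel)), panel$chrom)
  lapply(sp, function(ix) list(idx = ix, cM = panel$cM[ix]))
}

.hap_rows <- function(hs, id) {
  i <- match(id, hs$samples)
  if (is.na(i)) stop("unknown sample: ", id)
  c(2L * i - 1L, 2L * i)
}

#' Genotype matrix (0/1/2 alt-allele dosage) of a haplotype set
#' @param hs a `hapset`.
#' @export
as_genotypes <- function(hs) {
  n <- length(hs$samples)
  g <- hs$alleles[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
    hs$alleles[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  rownames(g) <- hs$samples
  g
}

#' Combine two haplotype sets over the same marker panel
#' @param a,b `hapset` objects sharing a panel.
#' @export
bind_hapsets <- function(a, b) {
  if (!identical(a$panel$marker, b$panel$marker))
    stop("haplotype sets use different marker panels")
  if (length(intersect(a$samples, b$samples)))
    stop("sample id spaces overlap")
  hapset(c(a$samples, b$samples), rbind(a$alleles, b$alleles),
         rbind(a$segs, b$segs), a$panel, a$map)
}

# One meiosis: crossovers are Poisson(chromosome length in Morgans),
# breakpoints uniform in cM (Haldane, no interference).
.sample_crossovers <- function(length_cM) {
  k <- stats::rpois(1L, length_cM / 100)
  if (k == 0L) numeric(0) else sort(stats::runif(k, 0, length_cM))
}

# Transmit one haplotype from a parent. par_alleles: 2 x m matrix for this
# chromosome; par_segs: list of two data.frame-like lists (start, end,
# founder); returns list(alleles, segs).
.transmit_chrom <- function(par_alleles, par_segs, cm_pos, length_cM) {
  breaks <- .sample_crossovers(length_cM)
  start <- sample.int(2L, 1L)
  src <- ((start - 1L + findInterval(cm_pos, breaks)) %% 2L) + 1L
  alleles <- ifelse(src == 1L, par_alleles[1L, ], par_alleles[2L, ])
  bounds <- c(0, breaks, length_cM)
  out_s <- numeric(0); out_e <- numeric(0); out_f <- character(0)
  for (i in seq_len(length(bounds) - 1L)) {
    s <- bounds[i]; e <- bounds[i + 1L]
    if (e <= s) next
    hs <- ((start - 1L + i - 1L) %% 2L) + 1L
    sg <- par_segs[[hs]]
    keep <- which(sg$end > s & sg$start < e)
    for (j in keep) {
      out_s <- c(out_s, max(sg$start[j], s))
      out_e <- c(out_e, min(sg$end[j], e))
      out_f <- c(out_f, sg$founder[j])
    }
  }
  # canonicalize: merge touching intervals with the same founder label
  if (length(out_s) > 1L) {
    o <- order(out_s)
    out_s <- out_s[o]; out_e <- out_e[o]; out_f <- out_f[o]
    ks <- out_s[1]; ke <- out_e[1]; kf <- out_f[1]
    ms <- numeric(0); me <- numeric(0); mf <- character(0)
    for (i in 2:length(out_s)) {
      if (out_f[i] == kf && abs(out_s[i] - ke) < 1e-12) {
        ke <- out_e[i]
      } else {
        ms <- c(ms, ks); me <- c(me, ke); mf <- c(mf, kf)
        ks <- out_s[i]; ke <- out_e[i]; kf <- out_f[i]
      }
    }
    out_s <- c(ms, ks); out_e <- c(me, ke); out_f <- c(mf, kf)
  }
  list(alleles = as.integer(alleles),
       segs = list(start = out_s, end = out_e, founder = out_f))
}

#' Gene-drop phased haplotypes down a pedigree
#'
#' Founders draw haplotype alleles independently from panel frequencies and
#' carry a single founder-segment label per chromosome (their own haplotype
#' id). Each non-founder receives one recombinant haplotype from each
#' parent; crossover counts per transmission are Poisson in the map length
#' (Morgans) with breakpoints uniform in cM, and segment labels are carried
#' through the mosaic, so true pairwise IBD is recoverable exactly.
#'
#' @param ped pedigree from [simulate_pedigree()].
#' @param map a `genetic_map`.
#' @param panel marker panel.
#' @param seed integer seed.
#' @return a `hapset` covering every pedigree member.
#' @export
drop_haplotypes <- function(ped, map, panel, seed) {
  set.seed(as.integer(seed))
  ped <- as.data.table(ped)[order(generation, id)]
  ci <- .chrom_index(panel)
  lens <- map_lengths(map)
  chroms <- names(ci)
  clen <- stats::setNames(lens$length_cM, lens$chrom)
  m <- nrow(panel)
  n <- nrow(ped)
  alleles <- matrix(0L, nrow = 2L * n, ncol = m)
  ids <- ped$id
  rowidx <- stats::setNames(seq_len(n), ids)
  # seg store: segstore[[id]][[hap]][[chrom]] = list(start, end, founder)
  segstore <- vector("list", n); names(segstore) <- ids

  for (i in seq_len(n)) {
    id <- ped$id[i]
    if (ped$founder[i]) {
      hs <- list(vector("list", length(chroms)), vector("list", length(chroms)))
      for (h in 1:2) {
        alleles[2L * i - 2L + h, ] <-
          as.integer(stats::rbinom(m, 1L, panel$freq))
        names(hs[[h]]) <- chroms
        for (ch in chroms)
          hs[[h]][[ch]] <- list(start = 0, end = unname(clen[ch]),
                                founder = sprintf("%s.%d", id, h))
      }
      segstore[[id]] <- hs
    } else {
      hs <- list(vector("list", length(chroms)), vector("list", length(chroms)))
      names(hs[[1]]) <- chroms; names(hs[[2]]) <- chroms
      parents <- c(ped$father[i], ped$mother[i])
      for (h in 1:2) {
        p <- parents[h]
        pr <- 2L * rowidx[[p]] - 1L
        for (ch in chroms) {
          tr <- .transmit_chrom(
            alleles[c(pr, pr + 1L), ci[[ch]]$idx, drop = FALSE],
            list(segstore[[p]][[1]][[ch]], segstore[[p]][[2]][[ch]]),
            ci[[ch]]$cM, unname(clen[ch]))
          alleles[2L * i - 2L + h, ci[[ch]]$idx] <- tr$alleles
          hs[[h]][[ch]] <- tr$segs
        }
      }
      segstore[[id]] <- hs
    }
  }

  segs <- rbindlist(lapply(ids, function(id) {
    rbindlist(lapply(1:2, function(h) {
      rbindlist(lapply(chroms, function(ch) {
        sg <- segstore[[id]][[h]][[ch]]
        data.table(sample = id, hap = h, chrom = ch,
                   start_cM = sg$start, end_cM = sg$end, founder = sg$founder)
      }))
    }))
  }))
  hapset(ids, alleles, segs, panel, map)
}

#' Simulate an unrelated background cohort
#'
#' Haplotypes are drawn independently from panel frequencies; every
#' haplotype gets its own founder label, so true IBD between any two
#' background samples (or with the pedigree) is empty by construction.
#'
#' @param n_samples cohort size.
#' @param panel marker panel.
#' @param map a `genetic_map` (carried for coordinates).
#' @param seed integer seed.
#' @param prefix id prefix (kept disjoint from pedigree ids).
#' @export
simulate_background <- function(n_samples, panel, map, seed, prefix = "B") {
  set.seed(as.integer(seed))
  m <- nrow(panel)
  ids <- sprintf("%s%05d", prefix, seq_len(n_samples))
  alleles <- matrix(stats::rbinom(2L * n_samples * m, 1L,
                                  rep(panel$freq, each = 2L * n_samples)),
                    nrow = 2L * n_samples, ncol = m)
  storage.mode(alleles) <- "integer"
  lens <- map_lengths(map)
  segs <- CJ(sample = ids, hap = 1:2, chrom = lens$chrom)
  segs <- merge(segs, lens[, .(chrom, start_cM, end_cM = length_cM)],
                by = "chrom")[, .(sample, hap, chrom, start_cM = 0,
                                  end_cM, founder = sprintf("%s.%d", sample, hap))]
  hapset(ids, alleles, segs, panel, map)
}

#' Define a focal allele locus
#'
#' @param chrom chromosome id.
#' @param bp physical position of the variant.
#' @param window_start,window_end physical bounds of the locus window
#'   (the gene region over which at-locus IBD overlap is measured).
#' @param origin_hap founder haplotype id (e.g. `"I0001.1"`) on which the
#'   allele arose.
#' @export
focal_allele <- function(chrom, bp, window_start, window_end, origin_hap) {
  if (!(bp >= window_start && bp <= window_end))
    stop("focal position must lie inside its locus window")
  structure(list(chrom = as.character(chrom), bp = bp,
                 window_start = window_start, window_end = window_end,
                 origin_hap = origin_hap), class = "focal_allele")
}

#' Plant a rare dominant allele on one founder haplotype
#'
#' After gene dropping, the marker nearest the focal position is overwritten
#' so that a haplotype carries the alt allele iff its founder-segment label
#' at the focal genetic position traces to the originating founder
#' haplotype. Carrier status is therefore exactly the label truth.
#'
#' @param ped pedigree data.table.
#' @param hs `hapset` over the pedigree.
#' @param allele a [focal_allele()].
#' @return list(hapset, pedigree (with logical `carrier` column),
#'   carriers (ids), focal_marker (column index)).
#' @export
plant_focal_allele <- function(ped, hs, allele) {
  panel <- hs$panel
  lens <- map_lengths(hs$map)
  if (!allele$chrom %in% lens$chrom ||
      allele$bp < lens[chrom == allele$chrom]$start_bp ||
      allele$bp > lens[chrom == allele$chrom]$end_bp)
    stop("focal position outside map span")
  cand <- which(panel$chrom == allele$chrom)
  fm <- cand[which.min(abs(panel$bp[cand] - allele$bp))]
  fcM <- panel$cM[fm]
  cov <- hs$segs[chrom == allele$chrom & start_cM <= fcM & end_cM > fcM]
  # chromosome-end edge: position exactly at the end falls in the last tile
  if (fcM >= max(hs$segs[chrom == allele$chrom]$end_cM))
    cov <- hs$segs[chrom == allele$chrom & end_cM >= fcM & start_cM < fcM]
  carrier_hap <- cov[founder == allele$origin_hap, .(sample, hap)]
  hs$alleles[, fm] <- 0L
  if (nrow(carrier_hap)) {
    ri <- 2L * match(carrier_hap$sample, hs$samples) - 2L + carrier_hap$hap
    hs$alleles[ri, fm] <- 1L
  }
  ped <- as.data.table(ped)
  ped[, carrier := id %in% carrier_hap$sample]
  list(hapset = hs, pedigree = ped[],
       carriers = intersect(ped[carrier == TRUE]$id, hs$samples),
       focal_marker = fm)
}

#' Apply symmetric genotyping error to emitted alleles
#'
#' Flips each haplotype allele independently with probability `rate`,
#' after truth capture: founder-segment labels (the IBD oracle) are left
#' untouched, so error exercises the detector's mismatch tolerance without
#' contaminating truth.
#'
#' @param hs a `hapset`.
#' @param rate per-allele flip probability.
#' @param seed integer seed.
#' @export
add_genotyping_error <- function(hs, rate, seed) {
  if (rate <= 0) return(hs)
  set.seed(as.integer(seed))
  ncell <- length(hs$alleles)
  nflip <- stats::rbinom(1L, ncell, rate)
  if (nflip > 0L) {
    pos <- sample.int(ncell, nflip)
    hs$alleles[pos] <- 1L - hs$alleles[pos]
  }
  hs
}

#' True IBD segments between two samples, from founder-segment labels
#'
#' Intersects the two samples' label intervals that name the same founder
#' haplotype (over all four haplotype pairings) and merges the union into
#' maximal shared intervals. This is exact truth, independent of genotypes.
#'
#' @param hs a `hapset`.
#' @param a,b sample ids.
#' @param min_cM drop merged intervals shorter than this.
#' @return data.table(chrom, start_cM, end_cM, length_cM).
#' @export
true_ibd_segments <- function(hs, a, b, min_cM = 0) {
  sa <- hs$segs[sample == a]
  sb <- hs$segs[sample == b]
  j <- merge(sa, sb, by = c("chrom", "founder"),
             allow.cartesian = TRUE, suffixes = c(".a", ".b"))
  if (nrow(j) == 0L)
    return(data.table(chrom = character(), start_cM = numeric(),
                      end_cM = numeric(), length_cM = numeric()))
  j[, `:=`(s = pmax(start_cM.a, start_cM.b), e = pmin(end_cM.a, end_cM.b))]
  j <- j[e > s]
  if (nrow(j) == 0L)
    return(data.table(chrom = character(), start_cM = numeric(),
                      end_cM = numeric(), length_cM = numeric()))
  out <- j[, {
    o <- order(s); ss <- s[o]; ee <- e[o]
    ms <- ss[1]; me <- ee[1]; rs <- numeric(0); re <- numeric(0)
    for (i in seq_along(ss)[-1]) {
      if (ss[i] <= me + 1e-12) me <- max(me, ee[i])
      else { rs <- c(rs, ms); re <- c(re, me); ms <- ss[i]; me <- ee[i] }
    }
    .(start_cM = c(rs, ms), end_cM = c(re, me))
  }, by = chrom]
  out[, length_cM := end_cM - start_cM]
  out[length_cM >= min_cM][order(chrom, start_cM)]
}

#' Genome-wide true IBD fraction for a sample pair
#'
#' The sharing convention of relative matching: shared length is summed over
#' all four haplotype pairings (regions IBD on both homologs count twice)
#' and divided by twice the map length. Under this convention full siblings
#' share 0.5 in expectation and a pair separated by M meioses through a
#' couple shares `2 * 2^-M`, the model inverted by [estimate_meioses()].
#'
#' @inheritParams true_ibd_segments
#' @export
true_ibd_fraction <- function(hs, a, b) {
  tot <- sum(map_lengths(hs$map)$length_cM)
  sa <- hs$segs[sample == a]
  sb <- hs$segs[sample == b]
  j <- merge(sa, sb, by = c("chrom", "founder"),
             allow.cartesian = TRUE, suffixes = c(".a", ".b"))
  if (nrow(j) == 0L) return(0)
  j[, ov := pmax(0, pmin(end_cM.a, end_cM.b) - pmax(start_cM.a, start_cM.b))]
  sum(j$ov) / (2 * tot)
}

#' Simulate a relative pair of known meioses separation
#'
#' Gene-drops a [relative_pair_pedigree()] and returns the pair's true
#' genome-wide IBD fraction (both-ancestor paths, i.e. k = 2 common
#' ancestors for balanced outbred relationships).
#'
#' @param m meioses separation.
#' @param map,panel coordinate backbone (labels only; marker count is
#'   irrelevant to truth IBD, so a sparse panel is fine).
#' @param seed integer seed.
#' @return list(fraction, pair, hapset).
#' @export
simulate_meioses_pair <- function(m, map, panel, seed) {
  rp <- relative_pair_pedigree(m)
  hs <- drop_haplotypes(rp$ped, map, panel, seed)
  list(fraction = true_ibd_fraction(hs, rp$pair[1], rp$pair[2]),
       pair = rp$pair, hapset = hs)
}
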