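# IBD-sharing network, meioses estimation from total shared IBD, and
# carrier imputation by degree of at-locus sharing with known carriers.

#' Build an IBD-sharing network from a segment table
#'
#' One undirected edge per pair that shares at least one segment, carrying
#' the pair's total genome-wide shared cM, its summed at-locus overlap, and
#' the meioses separation estimated from the shared fraction.
#'
#' @param segments segment table from [detect_ibd()].
#' @param window locus window from [locus_window_cM()], or NULL to skip
#'   at-locus totals.
#' @param total_map_cM total map length in cM (denominator of the shared
#'   fraction fed to [estimate_meioses()]).
#' @param n_common_ancestors passed to [estimate_meioses()].
#' @return object of class `ibd_network`: list(edges, nodes).
#' @export
build_network <- function(segments, window = NULL, total_map_cM = NULL,
                          n_common_ancestors = 2) {
  if (nrow(segments) == 0L) {
    edges <- data.table(id_a = character(), id_b = character(),
                        shared_cM = numeric(), at_locus_cM = numeric(),
                        meioses = integer())
    return(structure(list(edges = edges, nodes = character()),
                     class = "ibd_network"))
  }
  seg <- copy(segments)
  seg[, overlap_cM := if (is.null(window)) 0 else locus_overlap(seg, window)]
  edges <- seg[, .(shared_cM = sum(length_cM),
                   at_locus_cM = sum(overlap_cM)), by = .(id_a, id_b)]
  if (!is.null(total_map_cM)) {
    edges[, meioses := vapply(shared_cM / (2 * total_map_cM), function(f)
      estimate_meioses(f, n_common_ancestors), NA_integer_)]
  } else {
    edges[, meioses := NA_integer_]
  }
  structure(list(edges = edges[order(id_a, id_b)],
                 nodes = sort(unique(c(edges$id_a, edges$id_b)))),
            class = "ibd_network")
}

#' @export
print.ibd_network <- function(x, ...) {
  cat("<ibd_network> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' Convert an IBD network to an igraph object
#' @param net an `ibd_network`.
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = data.frame(name = net$nodes))
}

#' Export an IBD network as edge-list CSV and GraphML
#' @param net an `ibd_network`.
#' @param csv_path,graphml_path output files (NULL to skip either).
#' @export
export_network <- function(net, csv_path = NULL, graphml_path = NULL) {
  if (!is.null(csv_path)) fwrite(net$edges, csv_path)
  if (!is.null(graphml_path))
    igraph::write_graph(as_igraph(net), graphml_path, format = "graphml")
  invisible(net)
}

#' Estimate meioses separation from a genome-wide shared fraction
#'
#' Inverts the expected-sharing model `f = k * 2^(-M)` for a pair related
#' through `k` common ancestors (k = 2, a couple, is the default;
#' single-common-ancestor paths use k = 1): `M = round(log2(k / f))`.
#'
#' @param shared_fraction fraction of the genome shared, in (0, 1] (see
#'   [true_ibd_fraction()] for the convention).
#' @param n_common_ancestors 1 or 2.
#' @return integer meioses estimate; `NA` (beyond resolution / unrelated)
#'   when the fraction is 0.
#' @export
estimate_meioses <- function(shared_fraction, n_common_ancestors = 2) {
  if (!n_common_ancestors %in% c(1, 2))
    stop("n_common_ancestors must be 1 or 2")
  if (shared_fraction < 0 || shared_fraction > 1)
    stop("shared_fraction must be in [0, 1]")
  if (shared_fraction == 0) return(NA_integer_)
  as.integer(round(log2(n_common_ancestors / shared_fraction)))
}

#' Expected genome-wide shared fraction at a meioses separation
#'
#' The forward model inverted by [estimate_meioses()].
#' @param meioses meioses separation M.
#' @param n_common_ancestors 1 or 2.
#' @export
expected_shared_fraction <- function(meioses, n_common_ancestors = 2) {
  n_common_ancestors * 2^(-meioses)
}

#' Degree of at-locus sharing with known carriers
#'
#' For each sample in the at-locus match set, the exact subset of known
#' carriers with whom summed at-locus overlap exceeds the locus threshold.
#'
#' @param ms a `match_sets` object from [build_match_sets()].
#' @return data.table(sample, known) long-format sharing profile restricted
#'   to at-locus matches.
#' @export
degree_of_sharing <- function(ms) {
  prof <- ms$carrier_overlap[at_locus_cM > ms$thresholds["locus"] &
                               sample %in% ms$at_locus_matches,
                             .(sample, known, at_locus_cM)]
  prof[order(sample, known)]
}

#' Classify putative carriers from the sharing profile
#'
#' A sample sharing at-locus IBD with every known carrier is a
#' `putative_carrier`; with at least one but not all, `unlikely` (sharing is
#' presumed to ride the non-risk homolog); otherwise `not_at_locus`.
#'
#' @param ms a `match_sets` object.
#' @param samples optional universe of sample ids to classify (default: the
#'   at-locus matches only).
#' @return data.table(sample, class, degree).
#' @export
classify_carriers <- function(ms, samples = NULL) {
  prof <- degree_of_sharing(ms)
  deg <- prof[, .(degree = uniqueN(known)), by = sample]
  if (is.null(samples)) samples <- ms$at_locus_matches
  out <- data.table(sample = samples)
  out <- merge(out, deg, by = "sample", all.x = TRUE)
  out[is.na(degree), degree := 0L]
  nk <- length(ms$known_carriers)
  out[, class := fifelse(degree == nk, "putative_carrier",
                         fifelse(degree >= 1L, "unlikely", "not_at_locus"))]
  out[order(sample)]
}

#' Histogram of sharing degree
#' @param calls classification table from [classify_carriers()].
#' @return data.table(degree, count) for degrees >= 1.
#' @export
degree_histogram <- function(calls) {
  h <- as.data.table(calls)[degree >= 1L, .(count = .N), by = degree]
  h[order(degree)]
}

#' Evaluate carrier calls against truth
#'
#' Positives are the `putative_carrier` calls. PPV on zero positives is
#' reported as `NA` (not 0): a run that nominates nobody is uninformative
#' about precision.
#'
#' @param calls classification table from [classify_carriers()].
#' @param truth named logical vector (or data.frame with `id`, `carrier`)
#'   of true carrier status for every classified sample.
#' @return list(confusion, ppv, sensitivity, specificity).
#' @export
evaluate_calls <- function(calls, truth) {
  if (is.data.frame(truth)) truth <- stats::setNames(truth$carrier, truth$id)
  calls <- as.data.table(calls)
  pos <- calls$class == "putative_carrier"
  tr <- truth[calls$sample]
  if (anyNA(tr)) stop("truth missing for some classified samples")
  tp <- sum(pos & tr); fp <- sum(pos & !tr)
  fn <- sum(!pos & tr); tn <- sum(!pos & !tr)
  list(confusion = matrix(c(tp, fp, fn, tn), 2, 2,
                          dimnames = list(called = c("pos", "neg"),
                                          truth = c("carrier", "non"))),
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Penetrance as an integer percentage
#' @param affected number of affected adult carriers.
#' @param total total adult carriers (> 0).
#' @export
penetrance <- function(affected, total) {
  if (total <= 0 || affected < 0 || affected > total)
    stop("need 0 <= affected <= total, total > 0")
  as.integer(round(100 * affected / total))
}
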