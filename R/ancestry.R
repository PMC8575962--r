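# Enrichment of broad-scale ancestry proportions (one-sided Mann-Whitney U
# per region) and fine-scale community labels (upper-tail hypergeometric,
# Bonferroni-corrected) in a sample subset versus a database background.

#' One-sided Mann-Whitney U enrichment of ancestry proportions
#'
#' Per region, tests whether the in-group's assigned proportions are
#' stochastically greater than the background's. By default the in-group is
#' excluded from the background before testing (statistically cleaner);
#' `include_in_group = TRUE` restores the whole-database-baseline
#' convention. A region passes when p < alpha AND the in-group median
#' proportion is > 0. With no ties and combined n below `exact_n` the exact
#' rank-sum null is used; otherwise the normal approximation with tie
#' correction and continuity correction.
#'
#' @param in_group data.frame/data.table (sample, region, value) or a wide
#'   matrix of proportions with regions as columns; rows are samples.
#' @param background same layout as `in_group`.
#' @param alpha significance level (default 0.05, unadjusted).
#' @param include_in_group keep in-group samples inside the background.
#' @param exact_n combined-size bound below which the exact distribution is
#'   used (no ties only).
#' @return data.table(region, p_value, median_in, pass).
#' @export
test_ethnicities <- function(in_group, background, alpha = 0.05,
                             include_in_group = FALSE, exact_n = 25L) {
  gi <- .long_props(in_group)
  gb <- .long_props(background)
  if (!include_in_group && "sample" %in% names(gb) &&
      "sample" %in% names(gi))
    gb <- gb[!sample %in% unique(gi$sample)]
  regions <- unique(gi$region)
  out <- rbindlist(lapply(regions, function(r) {
    x <- gi[region == r]$value
    y <- gb[region == r]$value
    if (length(y) < 2L || length(x) < 2L) {
      message("region skipped (too few samples): ", r)
      return(NULL)
    }
    p <- mwu_greater_p(x, y, exact_n = exact_n)
    data.table(region = r, p_value = p, median_in = stats::median(x),
               pass = p < alpha && stats::median(x) > 0)
  }))
  if (nrow(out) == 0L)
    return(data.table(region = character(), p_value = numeric(),
                      median_in = numeric(), pass = logical()))
  out[order(p_value)]
}

.long_props <- function(x) {
  if (is.matrix(x)) {
    dt <- as.data.table(x, keep.rownames = "sample")
    dt <- melt(dt, id.vars = "sample", variable.name = "region",
               value.name = "value", variable.factor = FALSE)
    return(dt)
  }
  as.data.table(x)
}

#' One-sided (greater) Mann-Whitney U p-value
#'
#' Exact when there are no ties and `length(x) + length(y) < exact_n`;
#' otherwise normal approximation with tie and continuity correction.
#' @param x in-group values, `y` background values.
#' @param y background values.
#' @param exact_n combined-size bound for the exact path.
#' @export
mwu_greater_p <- function(x, y, exact_n = 25L) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && (n1 + n2) < exact_n)
    return(stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE))
  mu <- n1 * n2 / 2
  tie_tab <- table(r)
  sig2 <- (n1 * n2 / 12) *
    ((n1 + n2 + 1) - sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1)))
  if (sig2 <= 0) return(1)
  stats::pnorm((U - mu - 0.5) / sqrt(sig2), lower.tail = FALSE)
}

#' Upper-tail hypergeometric p-value (independent arithmetic)
#'
#' P(X >= k) computed by summing binomial-coefficient terms directly;
#' kept free of `phyper` so it can serve as that path's oracle in tests.
#' @param k in-group samples carrying the label.
#' @param n in-group size.
#' @param K background (universe) samples carrying the label.
#' @param N universe size.
#' @export
hyper_upper_p <- function(k, n, K, N) {
  if (k <= 0) return(1)
  js <- k:min(n, K)
  sum(exp(lchoose(K, js) + lchoose(N - K, n - js) - lchoose(N, n)))
}

#' Hypergeometric overrepresentation of community labels
#'
#' Per community, an upper-tail hypergeometric test of the in-group label
#' count against the universe, Bonferroni-corrected for `n_tested`
#' communities. A community passes when adjusted p < alpha AND fold
#' overrepresentation > min_fold. By default the universe is the background
#' with the in-group excluded; `include_in_group = TRUE` uses the
#' whole-database convention (in-group counted inside the baseline).
#'
#' @param in_group data.frame/list: per-sample sets of community labels.
#'   Accepts a data.table (sample, community) or a named list of character
#'   vectors.
#' @param background same layout.
#' @param n_tested Bonferroni denominator; default: number of distinct
#'   communities in the annotation universe.
#' @param alpha adjusted-p threshold (default 0.001).
#' @param min_fold minimum fold overrepresentation (default 1.5).
#' @param include_in_group see above.
#' @return data.table(community, k, n, K, N, p_value, adj_p, fold, pass).
#'   Fold is `NA` (and pass FALSE) for communities with no background
#'   carriers.
#' @export
test_communities <- function(in_group, background, n_tested = NULL,
                             alpha = 0.001, min_fold = 1.5,
                             include_in_group = FALSE) {
  gi <- .long_labels(in_group)
  gb <- .long_labels(background)
  if (!include_in_group) gb <- gb[!sample %in% unique(gi$sample)]
  universe <- rbind(gb, if (include_in_group) NULL else gi)
  n <- uniqueN(gi$sample)
  N <- uniqueN(universe$sample)
  comms <- sort(unique(universe$community))
  if (is.null(n_tested)) n_tested <- length(comms)
  out <- rbindlist(lapply(comms, function(cm) {
    k <- uniqueN(gi[community == cm]$sample)
    K <- uniqueN(universe[community == cm]$sample)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    bg_K <- uniqueN(gb[community == cm]$sample)
    bg_N <- uniqueN(gb$sample)
    fold <- if (bg_K == 0) NA_real_ else (k / n) / (bg_K / bg_N)
    data.table(community = cm, k = k, n = n, K = K, N = N, p_value = p,
               adj_p = min(1, p * n_tested), fold = fold,
               pass = !is.na(fold) && min(1, p * n_tested) < alpha &&
                 fold > min_fold)
  }))
  out[order(adj_p)]
}

.long_labels <- function(x) {
  if (is.data.frame(x)) return(as.data.table(x)[, .(sample, community)])
  rbindlist(lapply(names(x), function(s)
    if (length(x[[s]])) data.table(sample = s, community = x[[s]]) else NULL))
}

#' Fold overrepresentation of a label
#'
#' In-group carrier rate over background carrier rate: `(k/n) / (K/N)`.
#' @param k,n in-group carriers and size.
#' @param K,N background carriers and size.
#' @export
fold_overrepresentation <- function(k, n, K, N) {
  if (K == 0) return(NA_real_)
  (k / n) / (K / N)
}
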