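# Time-binned ancestral birth-location enrichment: per (time bin, rounded
# lat/lon cell), odds ratios of unique family-tree counts in an IBD subset
# versus the database background of tree birth records.

#' Default time bins for birth records
#'
#' Half-open on the left two bins, closed final bin:
#' `[1700,1800)`, `[1800,1850)`, `[1850,1910]`.
#' @export
default_time_bins <- function() {
  data.table(bin = c("1700-1800", "1800-1850", "1850-1910"),
             from = c(1700L, 1800L, 1850L), to = c(1800L, 1850L, 1910L))
}

#' Assign birth records to time bins
#'
#' Edge convention (documented and tested): the first two bins are
#' left-closed/right-open, the final bin includes its upper edge; 1800
#' falls in the second bin, 1910 in the third, years outside the range are
#' dropped (count reported via message).
#'
#' @param records data.table(tree_id, ancestor_id, year, lat, lon).
#' @param bins bin table as in [default_time_bins()].
#' @return input records with a `bin` column, out-of-range rows dropped.
#' @export
bin_records <- function(records, bins = default_time_bins()) {
  rec <- as.data.table(records)
  rec[, bin := NA_character_]
  for (i in seq_len(nrow(bins))) {
    last <- i == nrow(bins)
    sel <- rec$year >= bins$from[i] &
      (if (last) rec$year <= bins$to[i] else rec$year < bins$to[i])
    rec[sel, bin := bins$bin[i]]
  }
  dropped <- sum(is.na(rec$bin))
  if (dropped > 0) message(dropped, " record(s) outside bin range dropped")
  rec[!is.na(bin)]
}

#' Location enrichment odds ratios per time bin and map cell
#'
#' Records are aggregated to cells by rounding coordinates to `rounding`
#' decimals. Within each (bin, cell) a 2x2 table of UNIQUE family trees
#' (in-group at cell / in-group elsewhere in bin / background at cell /
#' background elsewhere) gives a cross-product odds ratio; any zero cell
#' triggers the Haldane-Anscombe 0.5 correction on all four cells. A cell
#' passes when OR >= min_or and it is supported by >= min_trees unique
#' in-group trees. Duplicated records within a tree never change counts.
#'
#' @param in_group binned records of the IBD subset (see [bin_records()]).
#' @param background binned records of the database background.
#' @param rounding decimals kept on lat/lon (2 = record precision,
#'   0 = integer-degree aggregation).
#' @param min_trees minimum unique in-group trees per cell.
#' @param min_or minimum odds ratio.
#' @return data.table(bin, lat, lon, n_in, n_bg, n_in_records,
#'   n_bg_records, odds_ratio, log2_or, pass).
#' @export
location_enrichment <- function(in_group, background, rounding = 2,
                                min_trees = 10, min_or = 4) {
  if (nrow(in_group) == 0L) {
    warning("empty in-group: no cells")
    return(data.table(bin = character(), lat = numeric(), lon = numeric(),
                      n_in = integer(), n_bg = integer(),
                      n_in_records = integer(), n_bg_records = integer(),
                      odds_ratio = numeric(), log2_or = numeric(),
                      pass = logical()))
  }
  gi <- .cells(in_group, rounding)
  gb <- .cells(background, rounding)
  tot_in <- gi[, .(tot_in = uniqueN(tree_id)), by = bin]
  tot_bg <- gb[, .(tot_bg = uniqueN(tree_id)), by = bin]
  ci <- gi[, .(n_in = uniqueN(tree_id), n_in_records = .N),
           by = .(bin, lat, lon)]
  cb <- gb[, .(n_bg = uniqueN(tree_id), n_bg_records = .N),
           by = .(bin, lat, lon)]
  cells <- merge(ci, cb, by = c("bin", "lat", "lon"), all.x = TRUE)
  cells[is.na(n_bg), `:=`(n_bg = 0L, n_bg_records = 0L)]
  cells <- merge(cells, tot_in, by = "bin")
  cells <- merge(cells, tot_bg, by = "bin", all.x = TRUE)
  cells[is.na(tot_bg), tot_bg := 0L]
  cells[, odds_ratio := {
    a <- n_in; b <- tot_in - n_in; c <- n_bg; d <- tot_bg - n_bg
    z <- a == 0 | b == 0 | c == 0 | d == 0
    a <- a + 0.5 * z; b <- b + 0.5 * z; c <- c + 0.5 * z; d <- d + 0.5 * z
    (a * d) / (b * c)
  }]
  cells[, log2_or := log2(odds_ratio)]
  cells[, pass := odds_ratio >= min_or & n_in >= min_trees]
  cells[, c("tot_in", "tot_bg") := NULL]
  cells[order(bin, -odds_ratio)]
}

.cells <- function(records, rounding) {
  r <- as.data.table(records)
  r[, .(bin, tree_id, lat = round(lat, rounding), lon = round(lon, rounding))]
}

#' Small-set enrichment mode (coarse cells, relaxed tree filter)
#'
#' The map mode for small subsets (e.g. putative carriers): coordinates are
#' aggregated to integer degrees and only `min_trees = 2` unique trees are
#' required, while the odds-ratio filter is kept.
#'
#' @inheritParams location_enrichment
#' @export
small_set_mode <- function(in_group, background, min_trees = 2,
                           rounding = 0, min_or = 4) {
  location_enrichment(in_group, background, rounding = rounding,
                      min_trees = min_trees, min_or = min_or)
}

#' Export enrichment cells as GeoJSON and CSV
#'
#' Features carry `log2_or` and `log10_n` (log10 of in-group record count)
#' attributes for map styling.
#'
#' @param cells table from [location_enrichment()].
#' @param geojson_path,csv_path output files (NULL to skip).
#' @param pass_only export only cells passing the filters.
#' @return the exported subset, invisibly.
#' @export
export_map <- function(cells, geojson_path = NULL, csv_path = NULL,
                       pass_only = TRUE) {
  sub <- if (pass_only) cells[pass == TRUE] else cells
  if (!is.null(csv_path)) fwrite(sub, csv_path)
  if (!is.null(geojson_path)) {
    features <- lapply(seq_len(nrow(sub)), function(i) {
      list(type = "Feature",
           geometry = list(type = "Point",
                           coordinates = c(sub$lon[i], sub$lat[i])),
           properties = list(bin = sub$bin[i], n_in = sub$n_in[i],
                             n_bg = sub$n_bg[i],
                             odds_ratio = sub$odds_ratio[i],
                             log2_or = sub$log2_or[i],
                             log10_n = log10(pmax(sub$n_in_records[i], 1))))
    })
    fc <- list(type = "FeatureCollection", features = features)
    jsonlite::write_json(fc, geojson_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(sub)
}

#' Read back a GeoJSON map export
#' @param path GeoJSON file from [export_map()].
#' @return data.table(bin, lat, lon, n_in, n_bg, odds_ratio, log2_or).
#' @export
read_map_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  rbindlist(lapply(fc$features, function(f)
    data.table(bin = f$properties$bin,
               lat = f$geometry$coordinates[[2]],
               lon = f$geometry$coordinates[[1]],
               n_in = f$properties$n_in, n_bg = f$properties$n_bg,
               odds_ratio = f$properties$odds_ratio,
               log2_or = f$properties$log2_or)))
}
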