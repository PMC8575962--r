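# Plain-text study IO. Formats: VCF 4.2 with phased GT for genotypes,
# 3-column tab-separated genetic map (chrom, bp, cM), 4-column pedigree,
# CSV annotations and birth records, and truth tables (carrier status,
# true IBD segments) so a written study round-trips losslessly.

#' Write phased genotypes as VCF 4.2
#'
#' GT-only body with `|`-separated alleles (true phase is emitted).
#' @param hs a `hapset`.
#' @param path output file (uncompressed .vcf).
#' @export
write_vcf <- function(hs, path) {
  panel <- hs$panel
  n <- length(hs$samples)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ibdtrace",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", hs$samples), collapse = "\t"))
  body <- data.table(CHROM = panel$chrom, POS = panel$bp, ID = panel$marker,
                     REF = panel$ref, ALT = panel$alt, QUAL = ".",
                     FILTER = "PASS", INFO = ".", FORMAT = "GT")
  for (j in seq_len(n)) {
    gt <- paste0(hs$alleles[2L * j - 1L, ], "|", hs$alleles[2L * j, ])
    set(body, j = hs$samples[j], value = gt)
  }
  writeLines(header, path)
  fwrite(body, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Read a phased VCF written by [write_vcf()]
#'
#' @param path VCF file.
#' @return list(panel = data.table(marker, chrom, bp, ref, alt),
#'   samples, alleles) -- genetic positions and frequencies live in the
#'   panel file, not the VCF.
#' @export
read_vcf_phased <- function(path) {
  hdr <- grep("^#CHROM", readLines(path, n = 200L))
  cols <- strsplit(readLines(path, n = hdr)[hdr], "\t")[[1]]
  dt <- fread(path, skip = hdr, header = FALSE, sep = "\t")
  setnames(dt, cols)
  samples <- cols[-(1:9)]
  al <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(dt))
  for (j in seq_along(samples)) {
    gt <- dt[[samples[j]]]
    al[2L * j - 1L, ] <- as.integer(substr(gt, 1L, 1L))
    al[2L * j, ] <- as.integer(substr(gt, 3L, 3L))
  }
  list(panel = data.table(marker = dt$ID, chrom = as.character(dt$`#CHROM`),
                          bp = dt$POS, ref = dt$REF, alt = dt$ALT),
       samples = samples, alleles = al)
}

#' Write a genetic map as 3-column tab-separated text
#' @param map a `genetic_map`.
#' @param path output file.
#' @export
write_map_file <- function(map, path) {
  fwrite(map$anchors[, .(chrom, bp, cM)], path, sep = "\t")
  invisible(path)
}

#' Read a genetic map file
#' @param path map file from [write_map_file()].
#' @export
read_map_file <- function(path) {
  genetic_map(fread(path, sep = "\t",
                    colClasses = list(character = "chrom")))
}

#' Write a full synthetic study to a directory
#'
#' Emits: `genotypes.vcf`, `genetic_map.tsv`, `panel.tsv` (marker panel
#' with founder frequencies), `pedigree.tsv`, `ethnicity.csv`,
#' `communities.csv`, `birth_records.csv`, `trees.csv`,
#' `truth_carriers.csv` and `truth_segments.tsv` (founder-segment labels,
#' the IBD truth). Everything round-trips through [read_study()].
#'
#' @param dir output directory (created).
#' @param hs a `hapset`.
#' @param ped pedigree table (optional).
#' @param annotations result of [annotate_samples()] (optional).
#' @param carriers character vector of true carrier ids (optional).
#' @export
write_study <- function(dir, hs, ped = NULL, annotations = NULL,
                        carriers = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create study directory: ", dir)
  write_vcf(hs, file.path(dir, "genotypes.vcf"))
  write_map_file(hs$map, file.path(dir, "genetic_map.tsv"))
  fwrite(hs$panel, file.path(dir, "panel.tsv"), sep = "\t")
  fwrite(hs$segs, file.path(dir, "truth_segments.tsv"), sep = "\t")
  if (!is.null(ped))
    fwrite(as.data.table(ped)[, .(id, father, mother, generation)],
           file.path(dir, "pedigree.tsv"), sep = "\t")
  if (!is.null(carriers))
    fwrite(data.table(id = hs$samples, carrier = hs$samples %in% carriers),
           file.path(dir, "truth_carriers.csv"))
  if (!is.null(annotations)) {
    fwrite(annotations$ethnicity, file.path(dir, "ethnicity.csv"))
    fwrite(annotations$communities, file.path(dir, "communities.csv"))
    fwrite(annotations$records, file.path(dir, "birth_records.csv"))
    fwrite(annotations$trees, file.path(dir, "trees.csv"))
  }
  invisible(dir)
}

#' Read a study directory written by [write_study()]
#' @param dir study directory.
#' @return list(hapset, pedigree, annotations, carriers) with absent
#'   components NULL.
#' @export
read_study <- function(dir) {
  vcf <- read_vcf_phased(file.path(dir, "genotypes.vcf"))
  map <- read_map_file(file.path(dir, "genetic_map.tsv"))
  panel <- fread(file.path(dir, "panel.tsv"), sep = "\t",
                 colClasses = list(character = c("marker", "chrom", "ref",
                                                 "alt")))
  setkey(panel, chrom, bp)
  segs <- fread(file.path(dir, "truth_segments.tsv"), sep = "\t",
                colClasses = list(character = c("sample", "chrom",
                                                "founder")))
  hs <- hapset(vcf$samples, vcf$alleles, segs, panel, map)
  rd <- function(f, ...) {
    p <- file.path(dir, f)
    if (file.exists(p)) fread(p, ...) else NULL
  }
  ped <- rd("pedigree.tsv", sep = "\t",
            colClasses = list(character = c("id", "father", "mother")))
  ann <- NULL
  eth <- rd("ethnicity.csv")
  if (!is.null(eth))
    ann <- list(ethnicity = eth, communities = rd("communities.csv"),
                records = rd("birth_records.csv"), trees = rd("trees.csv"))
  tc <- rd("truth_carriers.csv")
  list(hapset = hs, pedigree = ped, annotations = ann,
       carriers = if (is.null(tc)) NULL else tc[carrier == TRUE]$id)
}
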