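#' Construct a phased haplotype reference panel
#'
#' A `haplotype_panel` holds phased biallelic SNVs for labeled reference
#' haplotypes. It is the truth source from which continent-specific variants
#' (CSVs) and sub-continental population-specific variants (sCSVs) are
#' called.
#'
#' @param sites data.frame with columns `chrom`, `pos` (1-based bp), `ref`,
#'   `alt`. Positions must be strictly increasing within a chromosome and
#'   alleles single bases (biallelic SNVs only).
#' @param haplotypes integer matrix, sites x haplotypes, entries in \{0, 1\}
#'   (1 = alternate allele).
#' @param labels character vector, one population label per haplotype column.
#' @param group_map named character vector mapping each population to its
#'   continental group. Defaults to the identity (population = group).
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(sites, haplotypes, labels, group_map = NULL) {
  sites <- as.data.frame(sites)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(sites)))
  haplotypes <- as.matrix(haplotypes)
  storage.mode(haplotypes) <- "integer"
  if (nrow(haplotypes) != nrow(sites))
    stop("haplotype matrix must have one row per site")
  if (ncol(haplotypes) != length(labels))
    stop("every haplotype must have exactly one population label")
  if (any(is.na(haplotypes)) || !all(haplotypes %in% c(0L, 1L)))
    stop("haplotype entries must be 0 or 1")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  if (is.null(group_map)) {
    pops <- unique(labels)
    group_map <- stats::setNames(pops, pops)
  }
  if (!all(labels %in% names(group_map)))
    stop("unknown population label(s): ",
         paste(setdiff(labels, names(group_map)), collapse = ", "))
  structure(list(sites = sites, haplotypes = haplotypes,
                 labels = as.character(labels),
                 group_map = group_map),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", nrow(x$sites), "sites,",
      ncol(x$haplotypes), "haplotypes,",
      length(unique(x$labels)), "populations,",
      length(unique(x$group_map[x$labels])), "continental groups\n")
  invisible(x)
}

#' Populations or continental groups of a panel
#'
#' @param panel a `haplotype_panel`.
#' @param level `"continental"` (labels mapped through `group_map`) or
#'   `"population"`.
#' @return character vector, one entry per haplotype.
#' @export
panel_groups <- function(panel, level = c("continental", "population")) {
  level <- match.arg(level)
  if (level == "population") panel$labels
  else unname(panel$group_map[panel$labels])
}

#' Construct an unphased genotype matrix for admixed individuals
#'
#' @param sites site table as in [haplotype_panel()].
#' @param genotypes matrix, sites x individuals, values 0/1/2 (count of
#'   alternate alleles) or `NA` for missing. Missing is never conflated
#'   with 0: it means "no CSV observation possible at this site".
#' @param individuals character vector of individual ids.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, genotypes, individuals = NULL) {
  sites <- as.data.frame(sites)
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (nrow(genotypes) != nrow(sites))
    stop("genotype matrix must have one row per site")
  ok <- is.na(genotypes) | (genotypes >= 0L & genotypes <= 2L)
  if (!all(ok)) stop("genotypes must be 0, 1, 2 or NA")
  if (is.null(individuals)) {
    individuals <- colnames(genotypes)
    if (is.null(individuals)) individuals <- paste0("ind", seq_len(ncol(genotypes)))
  }
  colnames(genotypes) <- individuals
  structure(list(sites = sites, genotypes = genotypes,
                 individuals = as.character(individuals)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$sites), "sites,",
      length(x$individuals), "individuals\n")
  invisible(x)
}

#' Construct an ancestry track
#'
#' Piecewise-constant diploid (or haploid) ancestry along chromosomes.
#' Internally intervals are 1-based inclusive bp (VCF convention); on disk
#' they are written 0-based half-open (BED convention).
#'
#' @param df data.frame with columns `chrom`, `start`, `end` (1-based
#'   inclusive), `individual`, `anc1`, `anc2`. For haploid tracks set
#'   `anc2 = NA`. The pair (`anc1`, `anc2`) is unordered and stored sorted.
#' @return An object of class `ancestry_track`.
#' @export
ancestry_track <- function(df) {
  df <- as.data.frame(df)
  stopifnot(all(c("chrom", "start", "end", "individual", "anc1") %in% names(df)))
  if (!"anc2" %in% names(df)) df$anc2 <- NA_character_
  df$anc1 <- as.character(df$anc1); df$anc2 <- as.character(df$anc2)
  swap <- !is.na(df$anc2) & df$anc2 < df$anc1
  if (any(swap)) {
    tmp <- df$anc1[swap]; df$anc1[swap] <- df$anc2[swap]; df$anc2[swap] <- tmp
  }
  df <- df[order(df$individual, df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  for (key in split(seq_len(nrow(df)), list(df$individual, df$chrom), drop = TRUE)) {
    s <- df$start[key]; e <- df$end[key]
    if (any(e < s)) stop("interval end before start")
    if (length(key) > 1 && any(s[-1] <= e[-length(e)]))
      stop("overlapping intervals in ancestry track")
  }
  structure(df, class = c("ancestry_track", "data.frame"))
}

#' @export
print.ancestry_track <- function(x, ...) {
  cat("ancestry_track:", nrow(x), "segments,",
      length(unique(x$individual)), "individuals\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Write / read ancestry tracks as BED-like TSV
#'
#' Columns: chrom, start, end, individual, ancestry_pair. Intervals are
#' converted to 0-based half-open on write and back to 1-based inclusive on
#' read; the round trip is lossless.
#'
#' @param tracks an [ancestry_track()].
#' @param path file path.
#' @return `read_tracks` returns an `ancestry_track`; overlapping rows in
#'   the file are a hard error.
#' @export
write_tracks <- function(tracks, path) {
  df <- as.data.frame(tracks)
  pair <- ifelse(is.na(df$anc2), df$anc1, paste(df$anc1, df$anc2, sep = ","))
  out <- data.frame(chrom = df$chrom, start = df$start - 1L, end = df$end,
                    individual = df$individual, ancestry_pair = pair)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("character", "integer", "integer",
                                         "character", "character"))
  parts <- strsplit(df$ancestry_pair, ",", fixed = TRUE)
  ancestry_track(data.frame(
    chrom = df$chrom, start = df$start + 1L, end = df$end,
    individual = df$individual,
    anc1 = vapply(parts, `[`, "", 1L),
    anc2 = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, "")))
}

# ---- panel / genotype readers -------------------------------------------

read_labels_file <- function(path) {
  lab <- utils::read.table(path, header = FALSE, sep = "\t",
                           colClasses = "character")
  if (ncol(lab) < 2) stop("labels file needs at least 2 columns: id, population")
  names(lab)[1:2] <- c("id", "population")
  if (ncol(lab) >= 3) names(lab)[3] <- "group"
  lab
}

labels_group_map <- function(lab) {
  if ("group" %in% names(lab)) {
    gm <- tapply(lab$group, lab$population, function(g) unique(g))
    if (any(lengths(gm) > 1)) stop("population mapped to more than one group")
    stats::setNames(unlist(gm), names(gm))
  } else {
    pops <- unique(lab$population)
    stats::setNames(pops, pops)
  }
}

SNV_BASES <- c("A", "C", "G", "T")

# vcfR drops matrix dimensions for single-record files
as_fix_matrix <- function(fix) {
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  fix
}

as_gt_matrix <- function(gt, n_rec) {
  if (is.null(dim(gt))) {
    if (n_rec == 1L)
      gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
    else
      gt <- matrix(gt, ncol = 1)
  }
  gt
}

#' Read a phased reference panel
#'
#' Supports phased VCF (via the vcfR package) and a plain matrix dialect:
#' a header line of haplotype ids, then one row per site
#' `"chrom pos ref alt a1 a2 ..."` with alleles coded 0/1.
#'
#' Multiallelic and non-SNV records are skipped (the count is reported via
#' `attr(panel, "n_skipped")` and a message). Unphased GT fields in VCF mode
#' are a hard error naming the first offending record.
#'
#' @param path VCF or matrix file.
#' @param labels_path TSV of `id<TAB>population[<TAB>continental_group]`.
#'   In VCF mode ids are sample names (each sample contributes 2
#'   haplotypes); in matrix mode ids are haplotype ids.
#' @param format `"auto"`, `"vcf"` or `"matrix"`.
#' @return a [haplotype_panel()].
#' @export
read_panel <- function(path, labels_path, format = c("auto", "vcf", "matrix")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "matrix"
  lab <- read_labels_file(labels_path)
  gm <- labels_group_map(lab)
  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF panels requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as_fix_matrix(vcfR::getFIX(v))
    gt <- as_gt_matrix(vcfR::extract.gt(v, element = "GT"), nrow(fix))
    keep <- fix[, "REF"] %in% SNV_BASES & fix[, "ALT"] %in% SNV_BASES
    n_skipped <- sum(!keep)
    if (n_skipped > 0)
      message("read_panel: skipped ", n_skipped, " multiallelic/non-SNV record(s)")
    fix <- fix[keep, , drop = FALSE]
    gt <- gt[keep, , drop = FALSE]
    bad <- grepl("/", gt, fixed = TRUE)
    if (any(bad)) {
      idx <- arrayInd(which(bad)[1], dim(gt))
      stop("unphased GT '", gt[bad][1], "' at ", fix[idx[1], "CHROM"], ":",
           fix[idx[1], "POS"], " sample ", colnames(gt)[idx[2]])
    }
    samples <- colnames(gt)
    missing_lab <- setdiff(samples, lab$id)
    if (length(missing_lab) > 0)
      stop("sample(s) missing from labels file: ",
           paste(missing_lab, collapse = ", "))
    a1 <- suppressWarnings(matrix(as.integer(sub("\\|.*", "", gt)), nrow = nrow(gt)))
    a2 <- suppressWarnings(matrix(as.integer(sub(".*\\|", "", gt)), nrow = nrow(gt)))
    if (any(is.na(a1)) || any(is.na(a2)))
      stop("missing or malformed GT in panel VCF (panels must be fully called)")
    haps <- matrix(0L, nrow = nrow(gt), ncol = 2 * length(samples))
    haps[, seq(1, ncol(haps), by = 2)] <- a1
    haps[, seq(2, ncol(haps), by = 2)] <- a2
    labels <- rep(lab$population[match(samples, lab$id)], each = 2)
    sites <- data.frame(chrom = fix[, "CHROM"],
                        pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"])
  } else {
    header <- strsplit(readLines(path, n = 1), "[ \t]+")[[1]]
    body <- utils::read.table(path, header = FALSE, skip = 1)
    if (ncol(body) != 4 + length(header))
      stop("matrix panel: column count does not match header haplotype ids")
    names(body)[1:4] <- c("chrom", "pos", "ref", "alt")
    keep <- body$ref %in% SNV_BASES & body$alt %in% SNV_BASES
    n_skipped <- sum(!keep)
    if (n_skipped > 0)
      message("read_panel: skipped ", n_skipped, " multiallelic/non-SNV record(s)")
    body <- body[keep, , drop = FALSE]
    missing_lab <- setdiff(header, lab$id)
    if (length(missing_lab) > 0)
      stop("haplotype id(s) missing from labels file: ",
           paste(missing_lab, collapse = ", "))
    haps <- as.matrix(body[, -(1:4), drop = FALSE])
    labels <- lab$population[match(header, lab$id)]
    sites <- body[, 1:4]
  }
  ord <- order(sites$chrom, sites$pos)
  panel <- haplotype_panel(sites[ord, , drop = FALSE],
                           haps[ord, , drop = FALSE], labels, gm)
  attr(panel, "n_skipped") <- n_skipped
  panel
}

#' Write a panel in the plain matrix dialect
#'
#' @param panel a [haplotype_panel()].
#' @param path output file.
#' @param labels_path optional path for the companion labels TSV.
#' @export
write_panel_matrix <- function(panel, path, labels_path = NULL) {
  ids <- paste0("h", seq_len(ncol(panel$haplotypes)))
  writeLines(paste(ids, collapse = "\t"), path)
  body <- cbind(panel$sites, as.data.frame(panel$haplotypes))
  utils::write.table(body, path, sep = "\t", quote = FALSE, append = TRUE,
                     row.names = FALSE, col.names = FALSE)
  if (!is.null(labels_path)) {
    lab <- data.frame(id = ids, population = panel$labels,
                      group = unname(panel$group_map[panel$labels]))
    utils::write.table(lab, labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read unphased genotypes of admixed individuals
#'
#' VCF mode accepts phased or unphased GT; missing genotypes ("./." or ".")
#' become `NA`. Matrix mode: header of individual ids then
#' `"chrom pos ref alt g1 g2 ..."` with g in 0/1/2 or "." for missing.
#'
#' @inheritParams read_panel
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "matrix")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "matrix"
  if (format == "vcf") {
    if (!requireNamespace("vcfR", quietly = TRUE))
      stop("reading VCF genotypes requires the vcfR package")
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as_fix_matrix(vcfR::getFIX(v))
    gt <- as_gt_matrix(vcfR::extract.gt(v, element = "GT"), nrow(fix))
    keep <- fix[, "REF"] %in% SNV_BASES & fix[, "ALT"] %in% SNV_BASES
    if (any(!keep))
      message("read_genotypes: skipped ", sum(!keep), " multiallelic/non-SNV record(s)")
    fix <- fix[keep, , drop = FALSE]
    gt <- gt[keep, , drop = FALSE]
    g <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
    alleles1 <- sub("[/|].*", "", gt)
    alleles2 <- sub(".*[/|]", "", gt)
    called <- !is.na(gt) & alleles1 != "." & alleles2 != "."
    g[called] <- as.integer(alleles1[called]) + as.integer(alleles2[called])
    sites <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                        ref = fix[, "REF"], alt = fix[, "ALT"])
    ord <- order(sites$chrom, sites$pos)
    genotype_matrix(sites[ord, , drop = FALSE], g[ord, , drop = FALSE],
                    colnames(gt))
  } else {
    header <- strsplit(readLines(path, n = 1), "[ \t]+")[[1]]
    body <- utils::read.table(path, header = FALSE, skip = 1,
                              na.strings = ".")
    names(body)[1:4] <- c("chrom", "pos", "ref", "alt")
    g <- as.matrix(body[, -(1:4), drop = FALSE])
    ord <- order(body$chrom, body$pos)
    genotype_matrix(body[ord, 1:4], g[ord, , drop = FALSE], header)
  }
}

#' Write genotypes in the plain matrix dialect
#' @param genotypes a [genotype_matrix()].
#' @param path output file.
#' @export
write_genotypes_matrix <- function(genotypes, path) {
  writeLines(paste(genotypes$individuals, collapse = "\t"), path)
  g <- genotypes$genotypes
  g[is.na(g)] <- "."
  body <- cbind(genotypes$sites, as.data.frame(g))
  utils::write.table(body, path, sep = "\t", quote = FALSE, append = TRUE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Remove strand-ambiguous sites
#'
#' Drops sites whose ref/alt pair is \{A,T\} or \{C,G\} (orientation
#' insensitive); these cannot be reconciled across strand conventions.
#' Site order is preserved.
#'
#' @param panel a [haplotype_panel()] or [genotype_matrix()].
#' @return the filtered object, with `attr(, "n_removed")` set.
#' @export
filter_strand_ambiguous <- function(panel) {
  pair <- paste(pmin(panel$sites$ref, panel$sites$alt),
                pmax(panel$sites$ref, panel$sites$alt))
  drop <- pair %in% c("A T", "C G")
  out <- subset_sites(panel, !drop)
  attr(out, "n_removed") <- sum(drop)
  out
}

#' Subset an object to a logical or integer site index
#' @param x a [haplotype_panel()] or [genotype_matrix()].
#' @param idx logical or integer index over sites.
#' @return object of the same class restricted to `idx`.
#' @export
subset_sites <- function(x, idx) {
  if (inherits(x, "haplotype_panel")) {
    haplotype_panel(x$sites[idx, , drop = FALSE],
                    x$haplotypes[idx, , drop = FALSE], x$labels, x$group_map)
  } else if (inherits(x, "genotype_matrix")) {
    genotype_matrix(x$sites[idx, , drop = FALSE],
                    x$genotypes[idx, , drop = FALSE], x$individuals)
  } else stop("unsupported class")
}

#' Harmonize genotype sites against a reference panel
#'
#' Matches sites by (chrom, pos, ref, alt). Records whose ref/alt are
#' swapped relative to the panel are either flipped (genotype g becomes
#' 2 - g, with a message) or dropped, deterministically per `on_swap`.
#' Sites absent from the panel are dropped: they cannot be CSVs under the
#' panel and carry no ancestry information in this model.
#'
#' @param panel a [haplotype_panel()].
#' @param genotypes a [genotype_matrix()].
#' @param on_swap `"flip"` or `"drop"`.
#' @return a list with elements `panel` and `genotypes` on the shared,
#'   identically ordered site set.
#' @export
harmonize_sites <- function(panel, genotypes, on_swap = c("flip", "drop")) {
  on_swap <- match.arg(on_swap)
  key <- function(s) paste(s$chrom, s$pos, s$ref, s$alt)
  skey <- function(s) paste(s$chrom, s$pos, s$alt, s$ref)
  pk <- key(panel$sites)
  gk <- key(genotypes$sites)
  gk_sw <- skey(genotypes$sites)
  direct <- match(gk, pk)
  swapped <- match(gk_sw, pk)
  use_sw <- is.na(direct) & !is.na(swapped)
  if (any(use_sw)) {
    if (on_swap == "flip") {
      message("harmonize_sites: flipped ", sum(use_sw), " allele-swapped record(s)")
      genotypes$genotypes[use_sw, ] <- 2L - genotypes$genotypes[use_sw, ]
      genotypes$sites$ref[use_sw] <- panel$sites$ref[swapped[use_sw]]
      genotypes$sites$alt[use_sw] <- panel$sites$alt[swapped[use_sw]]
      direct[use_sw] <- swapped[use_sw]
    } # else: left NA, dropped below
  }
  keep_g <- !is.na(direct)
  g2 <- subset_sites(genotypes, keep_g)
  p2 <- subset_sites(panel, direct[keep_g])
  list(panel = p2, genotypes = g2)
}

# ---- CSV table and read-count TSV round trips ---------------------------

#' Write / read a CSV/sCSV table as TSV
#'
#' Columns: chrom, pos, ref, alt, csv_allele, group, then one `freq_<group>`
#' column per group at the table's level.
#'
#' @param tab a `csv_table` (see [call_csvs()]).
#' @param path file path.
#' @export
write_csv_table <- function(tab, path) {
  groups <- attr(tab, "groups")
  df <- as.data.frame(tab)
  freq <- as.data.frame(attr(tab, "freqs"))
  names(freq) <- paste0("freq_", groups)
  out <- cbind(df[, c("chrom", "pos", "ref", "alt", "csv_allele", "group")], freq)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_csv_table
#' @param sites site table the records should be indexed against (optional;
#'   if omitted, `site` indices refer to the rows of the file itself).
#' @param level stored level of the table.
#' @export
read_csv_table <- function(path, sites = NULL, level = "continental") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = NA, stringsAsFactors = FALSE)
  fcols <- grep("^freq_", names(df))
  groups <- sub("^freq_", "", names(df)[fcols])
  freqs <- as.matrix(df[, fcols, drop = FALSE])
  colnames(freqs) <- groups
  site <- if (is.null(sites)) seq_len(nrow(df))
          else match(paste(df$chrom, df$pos, df$ref, df$alt),
                     paste(sites$chrom, sites$pos, sites$ref, sites$alt))
  new_csv_table(data.frame(site = site, chrom = df$chrom, pos = df$pos,
                           ref = df$ref, alt = df$alt,
                           csv_allele = df$csv_allele, group = df$group),
                freqs, groups, level)
}

#' Write / read per-site read counts as TSV
#'
#' Long format: chrom, pos, individual, ref_count, alt_count.
#'
#' @param counts list with `ref` and `alt` matrices (sites x individuals)
#'   plus `sites` and `individuals`, as returned by [simulate_reads()].
#' @param path file path.
#' @export
write_read_counts <- function(counts, path) {
  n_ind <- length(counts$individuals)
  n_site <- nrow(counts$sites)
  out <- data.frame(
    chrom = rep(counts$sites$chrom, n_ind),
    pos = rep(counts$sites$pos, n_ind),
    individual = rep(counts$individuals, each = n_site),
    ref_count = as.vector(counts$ref),
    alt_count = as.vector(counts$alt))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_read_counts
#' @export
read_read_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  inds <- unique(df$individual)
  key <- paste(df$chrom, df$pos)
  ukey <- unique(key)
  sites_first <- !duplicated(key)
  sites <- data.frame(chrom = df$chrom[sites_first], pos = df$pos[sites_first])
  ref <- matrix(0L, nrow(sites), length(inds),
                dimnames = list(NULL, inds))
  alt <- ref
  i <- match(key, ukey)
  j <- match(df$individual, inds)
  ref[cbind(i, j)] <- df$ref_count
  alt[cbind(i, j)] <- df$alt_count
  list(sites = sites, ref = ref, alt = alt, individuals = inds)
}
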