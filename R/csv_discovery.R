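new_csv_table <- function(records, freqs, groups, level) {
  rownames(records) <- NULL
  freqs <- as.matrix(freqs)
  colnames(freqs) <- groups
  structure(records, freqs = freqs, groups = groups, level = level,
            class = c("csv_table", "data.frame"))
}

#' @export
print.csv_table <- function(x, ...) {
  cat("csv_table (", attr(x, "level"), "): ", nrow(x), " records, groups: ",
      paste(attr(x, "groups"), collapse = ", "), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

group_allele_counts <- function(panel, level) {
  grp <- panel_groups(panel, level)
  ug <- sort(unique(grp))
  ind <- outer(grp, ug, "==") * 1
  alt <- panel$haplotypes %*% ind            # sites x groups
  n <- colSums(ind)
  list(alt = alt, n = n, groups = ug)
}

#' Call continent- or population-specific variants from a labeled panel
#'
#' An allele (ref or alt) is specific to a group when it is observed
#' (count >= `min_count`) in exactly one group at the requested level and
#' absent from all others. Both alleles at a site may qualify independently
#' (fixed differences yield two records with different source groups).
#'
#' @param panel a [haplotype_panel()] with at least 2 groups at `level`;
#'   a group with zero haplotypes is a hard error (absence cannot be
#'   asserted).
#' @param level `"continental"` for CSVs, `"population"` for sCSVs.
#' @param min_count presence threshold; the definition uses 1 (any observed
#'   copy counts as presence).
#' @return a `csv_table`: data.frame of (site, chrom, pos, ref, alt,
#'   csv_allele, group) with a per-group frequency matrix of the specific
#'   allele in `attr(, "freqs")`.
#' @export
call_csvs <- function(panel, level = c("continental", "population"),
                      min_count = 1L) {
  level <- match.arg(level)
  cnt <- group_allele_counts(panel, level)
  if (length(cnt$groups) < 2)
    stop("need at least 2 groups at level '", level, "'")
  if (any(cnt$n == 0))
    stop("group with zero haplotypes: cannot assert allele absence")
  nmat <- matrix(cnt$n, nrow(cnt$alt), length(cnt$n), byrow = TRUE)
  freq_alt <- cnt$alt / nmat
  freq_ref <- (nmat - cnt$alt) / nmat
  csvs_from_freqs(panel$sites, freq_alt, freq_ref, cnt$groups, level,
                  counts_alt = cnt$alt, counts_n = cnt$n,
                  min_count = min_count)
}

# Core specificity rule on frequency (or count) matrices: an allele is
# group-specific iff it is present in exactly one group. When counts are
# supplied, presence is count >= min_count; otherwise presence is freq > 0.
csvs_from_freqs <- function(sites, freq_alt, freq_ref, groups, level,
                            counts_alt = NULL, counts_n = NULL,
                            min_count = 1L) {
  if (!is.null(counts_alt)) {
    pres_alt <- counts_alt >= min_count
    pres_ref <- (matrix(counts_n, nrow(counts_alt), length(counts_n),
                        byrow = TRUE) - counts_alt) >= min_count
  } else {
    pres_alt <- freq_alt > 0
    pres_ref <- freq_ref > 0
  }
  one_rec <- function(pres, freq, allele) {
    hits <- which(rowSums(pres) == 1L)
    if (length(hits) == 0)
      return(list(rec = NULL, freq = NULL))
    src <- max.col(pres[hits, , drop = FALSE], ties.method = "first")
    list(rec = data.frame(site = hits,
                          chrom = sites$chrom[hits], pos = sites$pos[hits],
                          ref = sites$ref[hits], alt = sites$alt[hits],
                          csv_allele = allele, group = groups[src]),
         freq = freq[hits, , drop = FALSE])
  }
  a <- one_rec(pres_alt, freq_alt, "alt")
  r <- one_rec(pres_ref, freq_ref, "ref")
  rec <- rbind(a$rec, r$rec)
  freqs <- rbind(a$freq, r$freq)
  if (is.null(rec)) {
    rec <- data.frame(site = integer(), chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      csv_allele = character(), group = character())
    freqs <- matrix(0, 0, length(groups))
  } else {
    ord <- order(rec$pos, rec$csv_allele)
    rec <- rec[ord, , drop = FALSE]
    freqs <- freqs[ord, , drop = FALSE]
  }
  new_csv_table(rec, freqs, groups, level)
}

#' Per-group allele frequencies of a panel
#'
#' @param panel a [haplotype_panel()].
#' @param level grouping level.
#' @return list with `alt` and `ref` (sites x groups frequency matrices),
#'   `n` haplotypes per group and `groups`.
#' @export
panel_frequencies <- function(panel, level = c("continental", "population")) {
  level <- match.arg(level)
  cnt <- group_allele_counts(panel, level)
  nmat <- matrix(cnt$n, nrow(cnt$alt), length(cnt$n), byrow = TRUE)
  alt <- cnt$alt / nmat
  ref <- (nmat - cnt$alt) / nmat
  colnames(alt) <- colnames(ref) <- cnt$groups
  list(alt = alt, ref = ref, n = cnt$n, groups = cnt$groups)
}

panel_span_mb <- function(sites) {
  spans <- tapply(sites$pos, sites$chrom,
                  function(p) max(p) - min(p) + 1)
  sum(spans) / 1e6
}

#' Estimate informative and spurious group-specific variant densities
#'
#' For each group k, each group-k haplotype is held out in turn (or a
#' disjoint `target` panel is used), the specific variants are re-called,
#' and the group-j specific alleles carried by the evaluated haplotype are
#' counted and normalized by span in megabases. The diagonal of the
#' resulting matrix is the informative density N_k (expected group-k
#' variants per group-k haplotype per Mb); off-diagonal mass is the
#' spurious rate.
#'
#' @param panel training [haplotype_panel()] (>= 2 haplotypes per group for
#'   leave-one-out).
#' @param level grouping level.
#' @param target optional disjoint evaluation panel with the same sites and
#'   group levels; when supplied, variants are called once on `panel` and
#'   counted on `target` haplotypes.
#' @param span_bp region length used for normalization; defaults to the
#'   covered span of the site table.
#' @return list with `counts` (target group x source group, per haplotype
#'   per Mb), `N` (named diagonal), `spurious_rate` (named off-diagonal row
#'   sums), `span_mb` and `n_haplotypes`.
#' @export
estimate_density <- function(panel, level = c("continental", "population"),
                             target = NULL, span_bp = NULL) {
  level <- match.arg(level)
  span_mb <- if (is.null(span_bp)) panel_span_mb(panel$sites)
             else span_bp / 1e6
  if (span_mb * 1e6 < 1) stop("span must be at least 1 bp")
  if (is.null(target)) {
    D <- loo_carriage_counts(panel, level)
  } else {
    tab <- call_csvs(panel, level)
    grp_t <- panel_groups(target, level)
    ug <- sort(unique(grp_t))
    if (!all(ug %in% attr(tab, "groups")))
      stop("target panel has groups absent from the training panel")
    src_groups <- attr(tab, "groups")
    D <- matrix(0, length(ug), length(src_groups),
                dimnames = list(ug, src_groups))
    for (h in seq_along(grp_t)) {
      a <- target$haplotypes[, h]
      carried <- ifelse(tab$csv_allele == "alt", a[tab$site] == 1L,
                        a[tab$site] == 0L)
      cc <- table(factor(tab$group[carried], levels = src_groups))
      D[grp_t[h], ] <- D[grp_t[h], ] + as.numeric(cc)
    }
    D <- D / as.vector(table(factor(grp_t, levels = ug)))
  }
  D <- D / span_mb
  list(counts = D, N = stats::setNames(diag(D), rownames(D)),
       spurious_rate = stats::setNames(rowSums(D) - diag(D), rownames(D)),
       span_mb = span_mb,
       n_haplotypes = if (is.null(target)) ncol(panel$haplotypes)
                      else ncol(target$haplotypes))
}

# Leave-one-out carriage count matrix (target group x source group), mean
# specific-allele carriage per held-out haplotype (not yet per Mb).
loo_carriage_counts <- function(panel, level) {
  grp <- panel_groups(panel, level)
  ug <- sort(unique(grp))
  G <- length(ug)
  if (G < 2) stop("need at least 2 groups at level '", level, "'")
  cnt <- group_allele_counts(panel, level)
  if (any(cnt$n < 2))
    stop("leave-one-out requires >= 2 haplotypes per group")
  D <- matrix(0, G, G, dimnames = list(ug, ug))
  n_by <- table(factor(grp, levels = ug))
  for (h in seq_along(grp)) {
    gi <- match(grp[h], ug)
    a <- panel$haplotypes[, h]
    altc <- cnt$alt
    altc[, gi] <- altc[, gi] - a
    nvec <- cnt$n
    nvec[gi] <- nvec[gi] - 1L
    refc <- matrix(nvec, nrow(altc), G, byrow = TRUE) - altc
    pres_alt <- altc > 0
    pres_ref <- refc > 0
    alt_csv <- rowSums(pres_alt) == 1L
    ref_csv <- rowSums(pres_ref) == 1L
    # source group of each specific allele, carried status of haplotype h
    if (any(alt_csv)) {
      src <- max.col(pres_alt[alt_csv, , drop = FALSE], ties.method = "first")
      carried <- a[alt_csv] == 1L
      tab <- tabulate(src[carried], nbins = G)
      D[gi, ] <- D[gi, ] + tab
    }
    if (any(ref_csv)) {
      src <- max.col(pres_ref[ref_csv, , drop = FALSE], ties.method = "first")
      carried <- a[ref_csv] == 0L
      tab <- tabulate(src[carried], nbins = G)
      D[gi, ] <- D[gi, ] + tab
    }
  }
  D / as.numeric(n_by)
}

#' Observed specific-variant sequence of one individual
#'
#' Walks the sites in position order and reports those where the individual
#' carries at least one copy of a group-specific allele, each tagged with
#' the allele's source group. Copy number is collapsed: a homozygous
#' carrier yields one observation, because the HMM emission model is
#' defined over the identity of the observed variant, not its dosage.
#' Missing genotypes yield no observation.
#'
#' @param g integer vector of alt-allele counts over the sites underlying
#'   `csv_table` (0/1/2, `NA` = missing; 0/1 for a haploid with
#'   `ploidy = 1`).
#' @param csv_table a `csv_table` from [call_csvs()].
#' @param ploidy 2 for genotypes, 1 for a single haplotype.
#' @return data.frame (class `csv_observations`) with columns `site`,
#'   `pos`, `group`, ordered by position.
#' @export
observe_csvs <- function(g, csv_table, ploidy = 2L) {
  gi <- g[csv_table$site]
  carried <- ifelse(csv_table$csv_allele == "alt", gi >= 1L,
                    gi <= ploidy - 1L)
  carried[is.na(carried)] <- FALSE
  obs <- data.frame(site = csv_table$site[carried],
                    pos = csv_table$pos[carried],
                    group = csv_table$group[carried])
  obs <- obs[order(obs$pos), , drop = FALSE]
  rownames(obs) <- NULL
  class(obs) <- c("csv_observations", "data.frame")
  obs
}
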