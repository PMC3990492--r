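#' Leave-one-out sCSV carriage profile across populations
#'
#' For each haplotype in turn: remove it, re-call population-specific
#' variants (sCSVs) on the remaining haplotypes, and count the sCSVs of
#' every population carried by the held-out haplotype. Returns the
#' population x population matrix of mean counts (rows = population of the
#' held-out haplotype, columns = source population of the carried sCSVs)
#' and a row-max-normalized version (each row divided by its maximum, so a
#' diagonal of 1 means own-population sCSVs dominate).
#'
#' @param panel a [haplotype_panel()] with >= 2 haplotypes per population.
#' @param per_mb if TRUE (default) counts are normalized by span in Mb.
#' @return list with `counts`, `normalized`, `span_mb`.
#' @export
loo_profile <- function(panel, per_mb = TRUE) {
  D <- loo_carriage_counts(panel, "population")
  span_mb <- panel_span_mb(panel$sites)
  if (per_mb) D <- D / span_mb
  norm <- D / apply(D, 1, max)
  list(counts = D, normalized = norm, span_mb = span_mb)
}

#' Assign a haplotype segment to a population by sCSV counts
#'
#' Counts the sCSVs of each population carried by the haplotype within
#' `[start, end]` and assigns the population with the strictly maximal
#' count; ties and all-zero segments are `"unassigned"` (scored as
#' incorrect downstream).
#'
#' @param obs haploid `csv_observations` for the haplotype (from
#'   [observe_csvs()] with `ploidy = 1` against an sCSV table).
#' @param start,end segment bounds in bp (inclusive).
#' @param populations population universe for the count vector (defaults to
#'   those present in `obs`).
#' @return list with `assigned` (population name or `"unassigned"`) and
#'   `counts` (named vector).
#' @export
assign_segment <- function(obs, start, end, populations = NULL) {
  if (is.null(populations)) populations <- sort(unique(obs$group))
  inside <- obs$pos >= start & obs$pos <= end
  counts <- table(factor(obs$group[inside], levels = populations))
  counts <- stats::setNames(as.integer(counts), populations)
  mx <- max(counts)
  if (mx == 0 || sum(counts == mx) > 1)
    return(list(assigned = "unassigned", counts = counts))
  list(assigned = populations[which.max(counts)], counts = counts)
}

# sCSV observations of a single held-out haplotype under LOO recall.
# Shares the count-adjustment logic of loo_carriage_counts but returns the
# observation positions rather than totals.
loo_observations <- function(panel, hap_index) {
  grp <- panel_groups(panel, "population")
  ug <- sort(unique(grp))
  cnt <- group_allele_counts(panel, "population")
  gi <- match(grp[hap_index], ug)
  a <- panel$haplotypes[, hap_index]
  altc <- cnt$alt
  altc[, gi] <- altc[, gi] - a
  nvec <- cnt$n
  nvec[gi] <- nvec[gi] - 1L
  if (nvec[gi] < 1) stop("population of size 1: cannot hold out and recall")
  refc <- matrix(nvec, nrow(altc), length(ug), byrow = TRUE) - altc
  obs <- NULL
  for (allele in c("alt", "ref")) {
    pres <- if (allele == "alt") altc > 0 else refc > 0
    is_scsv <- rowSums(pres) == 1L
    carried <- if (allele == "alt") a == 1L else a == 0L
    hit <- which(is_scsv & carried)
    if (length(hit) > 0) {
      src <- max.col(pres[hit, , drop = FALSE], ties.method = "first")
      obs <- rbind(obs, data.frame(site = hit, pos = panel$sites$pos[hit],
                                   group = ug[src]))
    }
  }
  if (is.null(obs))
    obs <- data.frame(site = integer(), pos = integer(), group = character())
  obs <- obs[order(obs$pos), , drop = FALSE]
  rownames(obs) <- NULL
  class(obs) <- c("csv_observations", "data.frame")
  obs
}

#' Leave-one-out segment-assignment accuracy sweep
#'
#' For every haplotype, re-calls sCSVs with that haplotype held out, draws
#' `n_per_hap` random segments with lengths uniform in
#' `[min_mb, max_mb]` Mb, assigns each by maximal sCSV count, and records
#' correctness at the population level and rolled up to the continental
#' level (an assignment is continentally correct when the assigned
#' population maps to the true population's continental group).
#'
#' @param panel a [haplotype_panel()].
#' @param min_mb,max_mb segment length range in Mb (defaults 0.05-30).
#' @param n_per_hap segments drawn per held-out haplotype.
#' @param seed RNG seed.
#' @return data.frame with one row per segment: haplotype, true population
#'   and group, segment bounds and length, assigned population, and logical
#'   `correct_pop` / `correct_group` (unassigned counts as incorrect; the
#'   unassigned state is kept in `assigned`).
#' @export
segment_sweep <- function(panel, min_mb = 0.05, max_mb = 30, n_per_hap = 10,
                          seed = 1L) {
  stopifnot(min_mb > 0, max_mb >= min_mb)
  set.seed(seed)
  pos_range <- range(panel$sites$pos)
  grp <- panel_groups(panel, "population")
  rows <- vector("list", ncol(panel$haplotypes))
  for (h in seq_len(ncol(panel$haplotypes))) {
    obs <- loo_observations(panel, h)
    len <- stats::runif(n_per_hap, min_mb, max_mb) * 1e6
    len <- pmin(len, pos_range[2] - pos_range[1] + 1)
    start <- floor(stats::runif(n_per_hap, pos_range[1],
                                pmax(pos_range[1], pos_range[2] - len + 1)))
    end <- floor(start + len - 1)
    assigned <- character(n_per_hap)
    for (s in seq_len(n_per_hap))
      assigned[s] <- assign_segment(obs, start[s], end[s],
                                    sort(unique(grp)))$assigned
    true_pop <- grp[h]
    true_grp <- unname(panel$group_map[true_pop])
    asg_grp <- ifelse(assigned == "unassigned", NA_character_,
                      unname(panel$group_map[assigned]))
    rows[[h]] <- data.frame(
      haplotype = h, true_pop = true_pop, true_group = true_grp,
      start = start, end = end, length_mb = (end - start + 1) / 1e6,
      assigned = assigned,
      correct_pop = assigned == true_pop,
      correct_group = !is.na(asg_grp) & asg_grp == true_grp)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' sCSV enrichment in homozygous-ancestry regions of an admixed cohort
#'
#' Restricts each individual to regions where the diploid track is
#' homozygous for the continental pair `pair` and counts carried sCSVs of
#' every population in those regions, normalized per megabase per
#' haplotype (each diploid region contributes two haplotypes of that
#' ancestry).
#'
#' @param genotypes a [genotype_matrix()].
#' @param tracks diploid [ancestry_track()] (calls or consensus).
#' @param scsv_table population-level `csv_table`.
#' @param pair continental group of the homozygous regions (e.g. `"AFR"`);
#'   the group of a population is taken from `group_map`.
#' @param group_map named population -> continental group map.
#' @return list with `per_mb_per_hap` (named vector over populations),
#'   `total_mb` (summed region length in Mb over individuals) and
#'   `n_regions`. Empty region sets are an error.
#' @export
enrichment_counts <- function(genotypes, tracks, scsv_table, pair,
                              group_map) {
  df <- as.data.frame(tracks)
  hom <- df$anc1 == pair & df$anc2 == pair
  df <- df[hom, , drop = FALSE]
  if (nrow(df) == 0) stop("no homozygous ", pair, " regions in tracks")
  pops <- attr(scsv_table, "groups")
  counts <- stats::setNames(numeric(length(pops)), pops)
  total_mb <- 0
  for (i in seq_along(genotypes$individuals)) {
    seg <- df[df$individual == genotypes$individuals[i], , drop = FALSE]
    if (nrow(seg) == 0) next
    obs <- observe_csvs(genotypes$genotypes[, i], scsv_table)
    for (s in seq_len(nrow(seg))) {
      inside <- obs$pos >= seg$start[s] & obs$pos <= seg$end[s]
      tab <- table(factor(obs$group[inside], levels = pops))
      counts <- counts + as.numeric(tab)
    }
    total_mb <- total_mb + sum(seg$end - seg$start + 1) / 1e6
  }
  if (total_mb <= 0) stop("zero-length region set")
  list(per_mb_per_hap = counts / total_mb / 2,
       total_mb = total_mb, n_regions = nrow(df))
}
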