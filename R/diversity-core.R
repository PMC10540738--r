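#' Pre-filter and subsample genotypes for core-collection work
#'
#' Applied in order: accessions with more than `ind_missing_max` missing
#' calls are removed, then markers with more than `snp_missing_max` missing,
#' then a seeded random `marker_fraction` subsample of markers is taken, and
#' remaining missing calls are imputed with the marker's most frequent code
#' (major-allele fill). The result has no missing entries.
#'
#' @param g a [genotype_matrix()]
#' @param ind_missing_max accession missingness cap (default 0.30)
#' @param snp_missing_max marker missingness cap (default 0.10)
#' @param marker_fraction random marker subsample fraction (default 0.20)
#' @param seed RNG seed for the subsample
#' @return a fully observed [genotype_matrix()]
#' @export
prefilter_and_sample <- function(g, ind_missing_max = 0.30,
                                 snp_missing_max = 0.10,
                                 marker_fraction = 0.20, seed = 1L) {
  g1 <- subset_genotypes(g, accessions = rowMeans(is.na(g$codes)) <= ind_missing_max)
  g2 <- subset_genotypes(g1, markers = colMeans(is.na(g1$codes)) <= snp_missing_max)
  set.seed(seed)
  m <- ncol(g2$codes)
  take <- sort(sample.int(m, max(1L, round(marker_fraction * m))))
  g3 <- subset_genotypes(g2, markers = take)
  if (!nrow(g3$codes) || !ncol(g3$codes)) stop("empty genotype set after filtering")
  codes <- g3$codes
  for (j in seq_len(ncol(codes))) {
    x <- codes[, j]
    if (anyNA(x)) {
      tab <- table(x)
      codes[is.na(x), j] <- as.integer(names(tab)[which.max(tab)])
    }
  }
  genotype_matrix(codes, g3$map)
}

#' Diversity profile of a genotype panel
#'
#' Per-marker nucleotide diversity `pi = 2 p (1 - p) n / (n - 1)` (p from
#' observed allele counts, n = non-missing accessions) and MAF; SNP density
#' in 1-Mb bins; classical-scaling MDS of the pairwise IBS distance
#' (1 - IBS similarity); and a summary of the centered-IBS kinship
#' distribution.
#'
#' @param g a [genotype_matrix()]
#' @param mds_axes number of MDS axes (default 3)
#' @return list(pi, maf (named per marker), density (chrom, bin_mb, n_snps),
#'   mds (accession x axes), kinship_summary)
#' @export
diversity_profile <- function(g, mds_axes = 3L) {
  n_obs <- colSums(!is.na(g$codes))
  p <- colMeans(g$codes, na.rm = TRUE) / 2
  pi <- ifelse(n_obs > 1, 2 * p * (1 - p) * n_obs / (n_obs - 1), NA_real_)
  names(pi) <- colnames(g$codes)
  maf <- pmin(p, 1 - p)
  bins <- data.frame(chrom = g$map$chrom, bin_mb = floor(g$map$pos / 1e6))
  density <- stats::aggregate(rep(1L, nrow(bins)),
                              by = list(chrom = bins$chrom, bin_mb = bins$bin_mb),
                              FUN = sum)
  names(density)[3] <- "n_snps"
  K_ibs <- kinship(g, "ibs_emma")
  D <- 1 - K_ibs
  mds <- stats::cmdscale(stats::as.dist(D), k = mds_axes)
  rownames(mds) <- rownames(g$codes)
  Kc <- kinship(g, "centered_ibs")
  off <- Kc[upper.tri(Kc)]
  list(pi = pi, maf = maf, density = density, mds = mds,
       kinship_summary = c(mean = mean(off), stats::quantile(off,
         c(0.05, 0.25, 0.5, 0.75, 0.95))))
}

#' Principal coordinates of the IBS distance
#' @param g a [genotype_matrix()]
#' @param axes number of axes retained (default 3)
#' @return accession x axes coordinate matrix
#' @export
pcoa_coords <- function(g, axes = 3L) {
  K <- kinship(g, "ibs_emma")
  stats::cmdscale(stats::as.dist(1 - K), k = axes)
}

farthest_point_sample <- function(coords, n_select) {
  n <- nrow(coords)
  n_select <- min(n_select, n)
  centroid <- colMeans(coords)
  d_cent <- sqrt(rowSums(sweep(coords, 2L, centroid)^2))
  sel <- which.max(d_cent)
  mind <- sqrt(rowSums(sweep(coords, 2L, coords[sel, ])^2))
  while (length(sel) < n_select) {
    cand <- which.max(mind)
    sel <- c(sel, cand)
    d_new <- sqrt(rowSums(sweep(coords, 2L, coords[cand, ])^2))
    mind <- pmin(mind, d_new)
  }
  rownames(coords)[sel]
}

#' Select a mixed-strategy core collection
#'
#' Three sub-cores united and deduplicated: a genetic sub-core by greedy
#' farthest-point (maximin) sampling on the first three PCoA axes (seeded at
#' the accession farthest from the centroid); a phenotypic sub-core taking
#' the `n_extreme` highest and lowest accessions per quantitative trait plus
#' seeded random picks per qualitative category (proportional to category
#' share of the phenotypic budget); and a geographic fill adding one random
#' accession from every region not yet represented.
#'
#' @param g a fully observed [genotype_matrix()] (see
#'   [prefilter_and_sample()])
#' @param quantitative named list of per-accession numeric vectors
#' @param qualitative named list of per-accession category vectors
#' @param geography named region labels per accession
#' @param fraction overall target fraction (guidance 0.05-0.20); drives the
#'   genetic sub-core size unless `n_genetic` is given
#' @param n_genetic genetic sub-core size
#' @param n_extreme accessions taken from each phenotypic tail (default 10)
#' @param phenotypic_budget total qualitative picks (default 20)
#' @param seed RNG seed
#' @return list(selected, sources = data.frame(accession, source),
#'   sizes = per-source counts, pcoa = coordinates used)
#' @export
select_core <- function(g, quantitative = list(), qualitative = list(),
                        geography = NULL, fraction = 0.15,
                        n_genetic = NULL, n_extreme = 10L,
                        phenotypic_budget = 20L, seed = 1L) {
  acc <- rownames(g$codes)
  n <- length(acc)
  if (fraction <= 0 || fraction > 1) stop("infeasible fraction")
  coords <- pcoa_coords(g, 3L)
  if (is.null(n_genetic)) n_genetic <- max(1L, round(fraction * n / 2))
  set.seed(seed)
  genetic <- farthest_point_sample(coords, n_genetic)
  phenotypic <- character(0)
  for (tr in names(quantitative)) {
    v <- quantitative[[tr]][acc]
    v <- v[!is.na(v)]
    srt <- names(sort(v))
    phenotypic <- c(phenotypic, utils::head(srt, n_extreme),
                    utils::tail(srt, n_extreme))
  }
  for (tr in names(qualitative)) {
    v <- qualitative[[tr]][acc]
    v <- v[!is.na(v)]
    share <- table(v) / length(v)
    for (catg in names(share)) {
      k <- ceiling(share[[catg]] * phenotypic_budget)
      pool <- names(v)[v == catg]
      phenotypic <- c(phenotypic, sample(pool, min(k, length(pool))))
    }
  }
  phenotypic <- unique(phenotypic)
  geographic <- character(0)
  if (!is.null(geography)) {
    covered <- unique(geography[unique(c(genetic, phenotypic))])
    for (rg in setdiff(unique(geography), covered)) {
      pool <- acc[geography[acc] == rg]
      geographic <- c(geographic, sample(pool, 1L))
    }
  }
  src_df <- function(ids, src) {
    if (!length(ids)) return(NULL)
    data.frame(accession = ids, source = src, stringsAsFactors = FALSE)
  }
  sources <- rbind(
    src_df(genetic, "genetic_subcore"),
    src_df(setdiff(phenotypic, genetic), "phenotypic_subcore"),
    src_df(setdiff(geographic, c(genetic, phenotypic)), "geographic_fill"))
  sources <- sources[!duplicated(sources$accession), ]
  list(selected = sources$accession, sources = sources,
       sizes = table(sources$source), pcoa = coords)
}

#' Replace a discarded accession by its nearest PCoA neighbour
#' @param selection a [select_core()] result
#' @param dropped accession id to drop (must be selected)
#' @param pcoa coordinate matrix (defaults to the selection's own)
#' @return updated selection with the replacement tagged "replacement"
#' @export
replace_accession <- function(selection, dropped, pcoa = selection$pcoa) {
  if (!(dropped %in% selection$selected)) stop("accession not in selection")
  keep <- setdiff(selection$selected, dropped)
  candidates <- setdiff(rownames(pcoa), selection$selected)
  if (!length(candidates)) stop("no replacement candidates")
  d <- sqrt(rowSums(sweep(pcoa[candidates, , drop = FALSE], 2L,
                          pcoa[dropped, ])^2))
  repl <- candidates[which.min(d)]
  sources <- selection$sources[selection$sources$accession != dropped, ]
  sources <- rbind(sources, data.frame(accession = repl, source = "replacement"))
  list(selected = c(keep, repl), sources = sources,
       sizes = table(sources$source), pcoa = pcoa,
       replacement_distance = min(d))
}

#' Representativeness diagnostics of a core against the full collection
#'
#' Per quantitative trait a Wilcoxon rank-sum test of core versus full
#' collection (flagged at `alpha`); per qualitative trait a chi-squared test
#' of category distribution core versus non-core with standardized Pearson
#' residuals; plus pi and MAF spectrum comparisons.
#'
#' @param core accession ids (subset of the panel)
#' @param g the full panel [genotype_matrix()]
#' @param quantitative,qualitative named lists of per-accession traits
#' @param alpha flag level (default 0.001)
#' @return list(quantitative (trait, p, flag), qualitative (trait, p, flag,
#'   residuals), pi_shift, maf_shift)
#' @export
representativeness_report <- function(core, g, quantitative = list(),
                                      qualitative = list(), alpha = 0.001) {
  acc <- rownames(g$codes)
  if (!all(core %in% acc)) stop("core must be a subset of the panel")
  qt <- do.call(rbind, lapply(names(quantitative), function(tr) {
    v <- quantitative[[tr]]
    p <- tryCatch(stats::wilcox.test(v[core], v[acc])$p.value,
                  error = function(e) NA_real_)
    data.frame(trait = tr, p = p, flag = !is.na(p) && p < alpha)
  }))
  ql <- lapply(names(qualitative), function(tr) {
    v <- qualitative[[tr]]
    tab <- table(factor(acc %in% core, levels = c(TRUE, FALSE),
                        labels = c("core", "rest")), v[acc])
    ct <- suppressWarnings(stats::chisq.test(tab))
    list(trait = tr, p = ct$p.value, flag = ct$p.value < alpha,
         residuals = ct$stdres)
  })
  names(ql) <- names(qualitative)
  gc_ <- subset_genotypes(g, accessions = core)
  p_full <- colMeans(g$codes, na.rm = TRUE) / 2
  p_core <- colMeans(gc_$codes, na.rm = TRUE) / 2
  n_f <- colSums(!is.na(g$codes)); n_c <- colSums(!is.na(gc_$codes))
  pi_full <- mean(2 * p_full * (1 - p_full) * n_f / pmax(n_f - 1, 1), na.rm = TRUE)
  pi_core <- mean(2 * p_core * (1 - p_core) * n_c / pmax(n_c - 1, 1), na.rm = TRUE)
  list(quantitative = qt, qualitative = ql,
       pi_shift = pi_core - pi_full,
       maf_shift = mean(pmin(p_core, 1 - p_core), na.rm = TRUE) -
         mean(pmin(p_full, 1 - p_full), na.rm = TRUE))
}
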