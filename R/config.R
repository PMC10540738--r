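#' Pipeline run configuration
#'
#' Bundles every tunable threshold of the pipeline with its standard default:
#' SNP filters (MAF >= 5%, <= 25% missing per marker and per accession,
#' heterozygous fraction < 5%), the interchromosomal LD r-squared baseline
#' (0.4456), the candidate-region window (< 2 Mb from the lead SNP) and the
#' locus merge gap (<= 100 kb), the gene-action contrast alpha (0.05), the
#' mean-stability correlation display cutoff (p < 0.01), and the minimum
#' allelic-class count (> 3 accessions).
#'
#' @param seed integer RNG seed
#' @param maf_min minimum minor allele frequency retained
#' @param snp_missing_max maximum missing fraction per marker
#' @param ind_missing_max maximum missing fraction per accession
#' @param het_max maximum heterozygous-call fraction per marker
#' @param r2_baseline interchromosomal LD r-squared baseline used to extend
#'   candidate regions; `NA` means recompute from the data
#' @param region_window_bp half-window around a lead SNP (strict `<`)
#' @param locus_gap_bp maximum gap for merging LD blocks into loci (`<=`)
#' @param contrast_alpha alpha for inheritance-mode contrasts
#' @param corr_p p-value mask for mean-stability correlations
#' @param min_class_n allelic classes need more than this many accessions
#' @param environments environment labels
#' @param out_dir output directory for pipeline TSVs
#' @return a `run_config` list
#' @export
run_config <- function(seed = 1L, maf_min = 0.05, snp_missing_max = 0.25,
                       ind_missing_max = 0.25, het_max = 0.05,
                       r2_baseline = 0.4456, region_window_bp = 2e6,
                       locus_gap_bp = 1e5, contrast_alpha = 0.05,
                       corr_p = 0.01, min_class_n = 3L,
                       environments = c("E1", "E2", "E3", "E4"),
                       out_dir = ".") {
  cfg <- list(seed = as.integer(seed), maf_min = maf_min,
              snp_missing_max = snp_missing_max,
              ind_missing_max = ind_missing_max, het_max = het_max,
              r2_baseline = r2_baseline,
              region_window_bp = as.numeric(region_window_bp),
              locus_gap_bp = as.numeric(locus_gap_bp),
              contrast_alpha = contrast_alpha, corr_p = corr_p,
              min_class_n = as.integer(min_class_n),
              environments = environments, out_dir = out_dir)
  props <- c("maf_min", "snp_missing_max", "ind_missing_max", "het_max",
             "contrast_alpha", "corr_p")
  for (p in props)
    if (!is.na(cfg[[p]]) && (cfg[[p]] < 0 || cfg[[p]] > 1))
      stop(p, " must lie in [0, 1]")
  if (cfg$region_window_bp <= 0 || cfg$locus_gap_bp <= 0)
    stop("window/gap must be positive")
  structure(cfg, class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Unknown keys are rejected; missing keys keep their defaults.
#' @param path JSON file path
#' @return a [run_config()]
#' @export
read_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Write a run configuration to JSON
#' @param cfg a [run_config()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
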