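#' Run the full MET stability-genetics pipeline
#'
#' Executes the stages in order — SNP filtering, variance decomposition and
#' BLUPs, stability indices, kinship and the Meff-corrected threshold, GWAS
#' on trait means and stability, GWEIS on interaction effects, LD candidate
#' regions / loci / QTL grouping, gene-action and QTI classification — and
#' writes TSV tables plus a machine-readable JSON summary. With identical
#' inputs, config and seed the outputs are identical.
#'
#' @param cfg a [run_config()]
#' @param genotypes a [genotype_matrix()]; when `NULL` the synthetic
#'   `scenario` is generated
#' @param met a [met_table()]; when `NULL`, generated from `scenario`
#' @param scenario a [scenario_spec()] used when data are not supplied
#' @param scan_method passed to [lmm_scan()] ("exact" or "approx")
#' @param write write TSV/JSON outputs under `cfg$out_dir`
#' @return list with per-stage results and the summary list
#' @export
run_pipeline <- function(cfg = run_config(), genotypes = NULL, met = NULL,
                         scenario = NULL, scan_method = "approx",
                         write = TRUE) {
  set.seed(cfg$seed)
  truth <- NULL
  if (is.null(genotypes)) {
    if (is.null(scenario))
      scenario <- scenario_spec(seed = cfg$seed, environments = cfg$environments)
    genotypes <- gen_genotypes(scenario)
    if (is.null(met)) {
      sim <- gen_met_phenotypes(genotypes, scenario)
      met <- sim$met
      truth <- sim$truth
    }
  }
  if (is.null(met)) stop("phenotypes required when genotypes are supplied")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  filt <- tryCatch(filter_snps(genotypes, cfg), error = function(e) NULL)
  if (is.null(filt)) {
    summary <- list(seed = cfg$seed, testable_snps = 0L, n_mta = 0L,
                    note = "no testable SNPs after filtering")
    empty_mta <- data.frame(marker = character(), chrom = character(),
                            pos = integer(), trait = character(),
                            analysis = character(), beta = numeric(),
                            se = numeric(), p = numeric(), maf = numeric(),
                            n = integer())
    if (write) write_pipeline_outputs(cfg$out_dir, list(mtas = empty_mta,
                                                        summary = summary))
    return(list(summary = summary, mtas = empty_mta))
  }
  G <- filt$genotypes
  specs <- attr(met, "trait_specs")
  traits_rep <- names(specs)[vapply(specs, function(s)
    s$kind == "replicated_quantitative", logical(1))]
  fits <- stage("anova", lapply(traits_rep, function(tr)
    fit_met_mixed(met, tr, lrt = FALSE)))
  names(fits) <- traits_rep
  stab <- stage("stability", lapply(fits, function(f) waasb(f$blup_ge)))
  K <- stage("kinship", kinship(G, "ibs_emma"))
  thr <- stage("threshold", significance_threshold(G, alpha = 0.05))
  scans <- list()
  for (tr in traits_rep) {
    gw <- stage("gweis", gweis_two_stage(met, tr, G, K, method = scan_method))
    st_scan <- stage("gwas-stability",
                     lmm_scan(stab[[tr]]$waasb, G, K, method = scan_method,
                              analysis = "stability", trait = tr))
    scans[[tr]] <- c(list(gw$mean_scan, st_scan), unname(gw$gei_scans))
  }
  all_scan <- do.call(rbind, unlist(scans, recursive = FALSE))
  mtas <- all_scan[all_scan$p < thr$cutoff, , drop = FALSE]
  loci <- qtls <- NULL
  gene_actions <- list()
  if (nrow(mtas)) {
    baseline <- if (is.na(cfg$r2_baseline))
      stage("baseline", interchrom_r2_baseline(G)) else cfg$r2_baseline
    regions <- stage("qtl", lapply(unique(mtas$marker), function(mk)
      candidate_region(G, mk, baseline, cfg$region_window_bp)))
    loci <- stage("qtl", build_loci(G, regions, baseline, cfg$locus_gap_bp))
    mtas <- stage("qtl", assign_mta_loci(mtas, loci))
    grouped <- stage("qtl", group_qtls(mtas))
    qtls <- grouped$qtls
    ga_rows <- list()
    for (i in seq_len(nrow(qtls))) {
      tr <- qtls$trait[i]
      markers <- strsplit(qtls$markers[i], ",")[[1]]
      for (mk in markers) {
        codes <- G$codes[, mk]
        res <- if (qtls$class[i] == "QTI")
          list(mode = NA_character_, a = NA_real_, d = NA_real_,
               direction = NA_character_,
               qti = qti_effect_profile(fits[[tr]]$blup_ge, codes,
                                        alpha = cfg$contrast_alpha,
                                        min_class_n = cfg$min_class_n)$type)
        else {
          y <- if (qtls$class[i] == "meanQTL") fits[[tr]]$blup_g
          else stab[[tr]]$waasb
          r <- gene_action(y, codes, alpha = cfg$contrast_alpha,
                           min_class_n = cfg$min_class_n)
          list(mode = r$mode, a = r$a, d = r$d, direction = r$direction,
               qti = NA_character_)
        }
        ga_rows[[length(ga_rows) + 1L]] <- data.frame(
          qtl = paste(qtls$trait[i], qtls$class[i], qtls$locus_id[i], sep = "_"),
          trait = tr, class = qtls$class[i], marker = mk, mode = res$mode,
          a = res$a, d = res$d, direction = res$direction,
          qti_type = res$qti, stringsAsFactors = FALSE)
      }
    }
    gene_actions <- do.call(rbind, ga_rows)
  }
  summary <- list(
    seed = cfg$seed,
    n_accessions = nrow(G$codes), testable_snps = ncol(G$codes),
    meff = thr$meff, p_cutoff = thr$cutoff,
    n_mta = nrow(mtas), n_loci = if (is.null(loci)) 0L else nrow(loci),
    n_qtl = if (is.null(qtls)) 0L else nrow(qtls),
    qtl_classes = if (is.null(qtls)) NULL else as.list(table(qtls$class)))
  out <- list(genotypes = G, filter_report = filt$report, fits = fits,
              stability = stab, kinship = K, threshold = thr,
              scans = all_scan, mtas = mtas, loci = loci, qtls = qtls,
              gene_actions = gene_actions, truth = truth, summary = summary)
  if (write) write_pipeline_outputs(cfg$out_dir, out)
  out
}

write_pipeline_outputs <- function(out_dir, res) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(obj, name) {
    if (is.null(obj) || !nrow(as.data.frame(obj))) {
      return(invisible(NULL))
    }
    data.table::fwrite(as.data.frame(obj), file.path(out_dir, name),
                       sep = "\t", quote = FALSE, na = "NA")
  }
  if (!is.null(res$fits)) {
    vc_all <- do.call(rbind, lapply(names(res$fits), function(tr)
      cbind(trait = tr, res$fits[[tr]]$vc,
            H2 = res$fits[[tr]]$H2, mu = res$fits[[tr]]$mu)))
    wr(vc_all, "variance_components.tsv")
    blupg <- do.call(rbind, lapply(names(res$fits), function(tr)
      data.frame(trait = tr, accession = names(res$fits[[tr]]$blup_g),
                 blup_g = unname(res$fits[[tr]]$blup_g))))
    wr(blupg, "blup_g.tsv")
  }
  if (!is.null(res$stability)) {
    stab_tab <- do.call(rbind, lapply(names(res$stability), function(tr)
      data.frame(trait = tr, accession = names(res$stability[[tr]]$waasb),
                 index = unname(res$stability[[tr]]$waasb), method = "WAASB",
                 standardized = scale_unit_variance(res$stability[[tr]]$waasb))))
    wr(stab_tab, "stability.tsv")
  }
  wr(res$mtas, "mta.tsv")
  wr(res$qtls, "qtl.tsv")
  wr(res$gene_actions, "gene_action.tsv")
  if (!is.null(res$loci) && nrow(res$loci)) {
    bed <- data.frame(chrom = res$loci$chrom, start = res$loci$start - 1L,
                      end = res$loci$end, name = res$loci$locus_id)
    data.table::fwrite(bed, file.path(out_dir, "loci.bed"), sep = "\t",
                       quote = FALSE, col.names = FALSE)
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 10)
  invisible(NULL)
}
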