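#' Planted QTL specification
#'
#' Declares a causal marker for the synthetic phenotype generator in the
#' classical F2 parametrization: the reference homozygote (code 0) adds `+a`
#' to the trait, the alternate homozygote (code 2) adds `-a`, and the
#' heterozygote adds `d`. Per-environment multipliers scale the whole
#' genotypic value and encode the QTL-by-environment truth: all equal = no
#' interaction; same sign but unequal = magnitude change; some zero =
#' conditional neutrality; sign change = antagonistic pleiotropy.
#'
#' @param marker marker index or id within the genotype matrix
#' @param trait trait name the QTL acts on
#' @param a additive genotypic value (trait units)
#' @param d dominance genotypic value (trait units)
#' @param env_multipliers numeric vector, one scalar per environment
#' @param action optional truth label; derived from `(a, d)` when `NULL` and
#'   checked for consistency when given
#' @param qti_type optional truth label; derived from `env_multipliers`
#' @return a `planted_qtl` object
#' @export
planted_qtl <- function(marker, trait, a, d = 0, env_multipliers = c(1, 1, 1, 1),
                        action = NULL, qti_type = NULL) {
  derived_action <- derive_action(a, d)
  if (is.null(action)) action <- derived_action
  else if (action != derived_action)
    stop("action '", action, "' inconsistent with a=", a, ", d=", d,
         " (derived '", derived_action, "')")
  derived_qti <- derive_qti_type(env_multipliers)
  if (is.null(qti_type)) qti_type <- derived_qti
  else if (qti_type != derived_qti)
    stop("qti_type '", qti_type, "' inconsistent with env_multipliers")
  structure(list(marker = marker, trait = trait, a = a, d = d,
                 env_multipliers = env_multipliers, action = action,
                 qti_type = qti_type), class = "planted_qtl")
}

derive_action <- function(a, d) {
  if (abs(d) > abs(a)) return("overdominant")
  if (abs(a) < .Machine$double.eps) return("additive")
  r <- d / a
  if (abs(r) <= 0.25) "additive"
  else if (abs(r - 1) <= 0.25) "dominant"
  else if (abs(r + 1) <= 0.25) "recessive"
  else stop("d/a ratio ", signif(r, 3), " matches no canonical gene action")
}

derive_qti_type <- function(m) {
  nz <- m[m != 0]
  if (length(unique(m)) == 1L) "none"
  else if (length(nz) && min(nz) < 0 && max(nz) > 0) "antagonistic"
  else if (any(m == 0)) "conditional_neutral"
  else "magnitude"
}

#' Synthetic MET scenario
#'
#' The defaults emulate the stated world of a GBS-genotyped European
#' traditional tomato panel: ~200 inbred accessions x 3000 SNPs with
#' MAF >= 5% on 12 chromosomes, blockwise LD, low heterozygosity, trials in
#' 4 environments with 3 replicate plants, and phenotypes from the additive
#' variance-component model `Y = mu + G + E + GxE + error` with planted QTLs
#' entering through per-environment multipliers.
#'
#' @param n_accessions,n_snps,n_chromosomes panel dimensions
#' @param block_size_mean mean LD block length in markers (Poisson + 1)
#' @param ld_r2 target pairwise dosage r-squared within a block
#' @param maf_range block allele-frequency range (uniform draw)
#' @param missing_rate fraction of genotype calls set missing
#' @param het_rate fraction of calls flipped to heterozygous (inbred-like)
#' @param environments environment labels (>= 3 for stability indices)
#' @param replicates plants per accession x environment
#' @param mu grand mean (trait units)
#' @param sigma2_g,sigma2_e,sigma2_ge,sigma2_eps variance components of the
#'   polygenic genotype, environment, interaction and residual terms
#' @param traits replicated quantitative trait names to simulate
#' @param qtls list of [planted_qtl()] objects
#' @param structure optional `list(prop =, shift =)` switching on a
#'   two-subpopulation allele-frequency shift (to exercise kinship correction)
#' @param seed integer seed; identical seed + scenario give identical data
#' @return a `scenario_spec` list
#' @export
scenario_spec <- function(n_accessions = 200L, n_snps = 3000L,
                          n_chromosomes = 12L, block_size_mean = 8,
                          ld_r2 = 0.6, maf_range = c(0.05, 0.5),
                          missing_rate = 0.03, het_rate = 0.02,
                          environments = c("E1", "E2", "E3", "E4"),
                          replicates = 3L, mu = 10,
                          sigma2_g = 4, sigma2_e = 1, sigma2_ge = 1,
                          sigma2_eps = 1, traits = "T1", qtls = list(),
                          structure = NULL, seed = 1L) {
  if (length(environments) < 3L)
    stop("stability indices need at least three environments")
  if (any(c(sigma2_g, sigma2_e, sigma2_ge, sigma2_eps) < 0))
    stop("variance components must be >= 0")
  if (maf_range[1] > maf_range[2] || maf_range[1] < 0 || maf_range[2] > 0.5)
    stop("infeasible maf_range")
  if (ld_r2 < 0 || ld_r2 > 1) stop("ld_r2 must lie in [0, 1]")
  for (q in qtls) {
    if (length(q$env_multipliers) != length(environments))
      stop("planted QTL env_multipliers must match environments")
  }
  structure(list(n_accessions = as.integer(n_accessions),
                 n_snps = as.integer(n_snps),
                 n_chromosomes = as.integer(n_chromosomes),
                 block_size_mean = block_size_mean, ld_r2 = ld_r2,
                 maf_range = maf_range, missing_rate = missing_rate,
                 het_rate = het_rate, environments = environments,
                 replicates = as.integer(replicates), mu = mu,
                 sigma2_g = sigma2_g, sigma2_e = sigma2_e,
                 sigma2_ge = sigma2_ge, sigma2_eps = sigma2_eps,
                 traits = traits, qtls = qtls, structure = structure,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

#' Generate a blockwise-LD genotype matrix
#'
#' Markers are organized in LD blocks: within a block every marker copies a
#' shared "core" gamete with probability `theta = ld_r2^(1/4)` and is redrawn
#' independently otherwise, which makes the expected pairwise dosage
#' r-squared within the block equal to `ld_r2` (and exactly 1 when
#' `ld_r2 = 1`). Blocks are independent. Accessions are inbred-like: calls
#' are homozygous except for a `het_rate` fraction flipped to heterozygous,
#' and a `missing_rate` fraction set missing.
#'
#' @param scenario a [scenario_spec()]
#' @return a [genotype_matrix()]; when the scenario enables population
#'   structure, the per-accession subpopulation labels are attached as the
#'   `subpop` attribute (truth for kinship-correction tests)
#' @export
gen_genotypes <- function(scenario) {
  set.seed(scenario$seed)
  n <- scenario$n_accessions
  m <- scenario$n_snps
  n_chr <- scenario$n_chromosomes
  theta <- scenario$ld_r2^(1 / 4)
  per_chr <- diff(round(seq(0, m, length.out = n_chr + 1L)))
  subpop <- NULL
  if (!is.null(scenario$structure))
    subpop <- stats::rbinom(n, 1L, scenario$structure$prop)
  codes <- matrix(0L, n, m)
  chrom <- character(m); pos <- integer(m); block <- character(m)
  col <- 0L
  for (ch in seq_len(n_chr)) {
    mc <- per_chr[ch]
    if (mc == 0L) next
    gaps <- sample(20000:80000, mc, replace = TRUE)
    pos[col + seq_len(mc)] <- cumsum(gaps)
    chrom[col + seq_len(mc)] <- sprintf("chr%02d", ch)
    left <- mc
    blk <- 0L
    while (left > 0L) {
      blk <- blk + 1L
      bs <- min(left, 1L + stats::rpois(1L, max(scenario$block_size_mean - 1, 0)))
      block[col + seq_len(bs)] <- sprintf("chr%02d_b%03d", ch, blk)
      p <- stats::runif(1L, scenario$maf_range[1], scenario$maf_range[2])
      if (is.null(subpop)) {
        core <- stats::rbinom(n, 1L, p)
        redraw_p <- rep(p, n)
      } else {
        sh <- scenario$structure$shift
        p_sub <- pmin(pmax(p + ifelse(subpop == 1L, sh, -sh), 0.01), 0.99)
        core <- stats::rbinom(n, 1L, p_sub)
        redraw_p <- p_sub
      }
      for (k in seq_len(bs)) {
        keep <- stats::rbinom(n, 1L, theta) == 1L
        allele <- ifelse(keep, core, stats::rbinom(n, 1L, redraw_p))
        codes[, col + k] <- 2L * allele
      }
      col <- col + bs
      left <- left - bs
    }
  }
  ncell <- n * m
  if (scenario$het_rate > 0) {
    n_het <- round(scenario$het_rate * ncell)
    if (n_het > 0) codes[sample.int(ncell, n_het)] <- 1L
  }
  if (scenario$missing_rate > 0) {
    n_mis <- round(scenario$missing_rate * ncell)
    if (n_mis > 0) codes[sample.int(ncell, n_mis)] <- NA_integer_
  }
  rownames(codes) <- sprintf("ACC%03d", seq_len(n))
  colnames(codes) <- sprintf("S%05d", seq_len(m))
  map <- data.frame(marker_id = colnames(codes), chrom = chrom, pos = pos,
                    ref = "A", alt = "B", block = block)
  g <- genotype_matrix(codes, map)
  if (!is.null(subpop))
    attr(g, "subpop") <- stats::setNames(subpop, rownames(codes))
  g
}

qtl_genotypic_value <- function(codes_col, a, d) {
  v <- numeric(length(codes_col))
  v[!is.na(codes_col) & codes_col == 0L] <- a
  v[!is.na(codes_col) & codes_col == 2L] <- -a
  v[!is.na(codes_col) & codes_col == 1L] <- d
  v  # missing calls contribute no planted effect
}

resolve_marker <- function(g, marker) {
  if (is.character(marker)) {
    idx <- match(marker, colnames(g$codes))
    if (is.na(idx)) stop("unknown marker: ", marker)
    idx
  } else {
    if (marker < 1L || marker > ncol(g$codes)) stop("unknown marker index ", marker)
    as.integer(marker)
  }
}

#' Generate replicated MET phenotypes with planted QTLs
#'
#' Each observation is
#' `mu + G_i + sum_q value_q(code_i) * mult_qj + E_j + GE_ij + eps_ijk`
#' with the polygenic genotype, environment, interaction and residual terms
#' drawn i.i.d. Normal at the scenario's variances. The returned truth table
#' records every planted effect and its labels.
#'
#' @param genotypes a [genotype_matrix()] from [gen_genotypes()]
#' @param scenario the matching [scenario_spec()]
#' @return list with `met` (a [met_table()]) and `truth` (data.frame of
#'   planted QTLs: trait, marker, chrom, pos, a, d, action, qti_type, and one
#'   `mult_<env>` column per environment)
#' @export
gen_met_phenotypes <- function(genotypes, scenario) {
  set.seed(scenario$seed + 500000L)
  n <- nrow(genotypes$codes)
  acc <- rownames(genotypes$codes)
  envs <- scenario$environments
  e <- length(envs)
  k <- scenario$replicates
  specs <- list()
  recs <- vector("list", length(scenario$traits))
  for (ti in seq_along(scenario$traits)) {
    tr <- scenario$traits[ti]
    specs[[tr]] <- trait_spec(tr, "replicated_quantitative")
    G <- stats::rnorm(n, 0, sqrt(scenario$sigma2_g))
    E <- stats::rnorm(e, 0, sqrt(scenario$sigma2_e))
    GE <- matrix(stats::rnorm(n * e, 0, sqrt(scenario$sigma2_ge)), n, e)
    qv <- matrix(0, n, e)
    for (q in scenario$qtls) {
      if (q$trait != tr) next
      idx <- resolve_marker(genotypes, q$marker)
      val <- qtl_genotypic_value(genotypes$codes[, idx], q$a, q$d)
      qv <- qv + outer(val, q$env_multipliers)
    }
    eps <- array(stats::rnorm(n * e * k, 0, sqrt(scenario$sigma2_eps)), c(n, e, k))
    y <- array(scenario$mu, c(n, e, k)) +
      array(rep(G, e * k), c(n, e, k)) +
      array(rep(rep(E, each = n), k), c(n, e, k)) +
      array(rep(GE + qv, k), c(n, e, k)) + eps
    recs[[ti]] <- data.frame(
      accession = rep(acc, times = e * k),
      environment = rep(rep(envs, each = n), times = k),
      replicate = rep(seq_len(k), each = n * e),
      trait = tr, value = as.vector(y), stringsAsFactors = FALSE)
  }
  truth <- truth_table(genotypes, scenario)
  list(met = met_table(do.call(rbind, recs), specs), truth = truth)
}

truth_table <- function(genotypes, scenario) {
  envs <- scenario$environments
  if (!length(scenario$qtls)) {
    out <- data.frame(trait = character(), marker = character(),
                      chrom = character(), pos = integer(), a = numeric(),
                      d = numeric(), action = character(),
                      qti_type = character(), stringsAsFactors = FALSE)
    for (ev in envs) out[[paste0("mult_", ev)]] <- numeric()
    return(out)
  }
  rows <- lapply(scenario$qtls, function(q) {
    idx <- resolve_marker(genotypes, q$marker)
    row <- data.frame(trait = q$trait, marker = colnames(genotypes$codes)[idx],
                      chrom = genotypes$map$chrom[idx],
                      pos = genotypes$map$pos[idx], a = q$a, d = q$d,
                      action = q$action, qti_type = q$qti_type,
                      stringsAsFactors = FALSE)
    for (j in seq_along(envs))
      row[[paste0("mult_", envs[j])]] <- q$env_multipliers[j]
    row
  })
  do.call(rbind, rows)
}

#' Generate an ordinal qualitative trait from a latent threshold model
#'
#' The latent variable follows the MET model without an interaction term
#' (`mu + G_i + planted effects + E_j + eps_ij`); categories are cut at
#' equally spaced latent quantiles, giving one value per accession x
#' environment.
#'
#' @param genotypes a [genotype_matrix()]
#' @param scenario a [scenario_spec()]; planted QTLs whose `trait` equals
#'   `name` act on the latent scale (their first environment multiplier is
#'   used: the latent model has no GEI)
#' @param name trait name
#' @param categories ordered category labels (>= 2)
#' @return list with `met` (a [met_table()] of the categorical trait) and
#'   `latent` (accession x environment matrix of latent values)
#' @export
gen_qualitative_trait <- function(genotypes, scenario, name = "Q1",
                                  categories = c("low", "mid", "high")) {
  if (length(categories) < 2L) stop("need >= 2 categories")
  set.seed(scenario$seed + 600000L)
  n <- nrow(genotypes$codes)
  acc <- rownames(genotypes$codes)
  envs <- scenario$environments
  e <- length(envs)
  G <- stats::rnorm(n, 0, sqrt(scenario$sigma2_g))
  E <- stats::rnorm(e, 0, sqrt(scenario$sigma2_e))
  eps <- matrix(stats::rnorm(n * e, 0, sqrt(scenario$sigma2_eps)), n, e)
  qeff <- numeric(n)
  for (q in scenario$qtls) {
    if (q$trait != name) next
    idx <- resolve_marker(genotypes, q$marker)
    qeff <- qeff + qtl_genotypic_value(genotypes$codes[, idx], q$a, q$d) *
      q$env_multipliers[1]
  }
  latent <- scenario$mu + outer(G + qeff, rep(1, e)) +
    outer(rep(1, n), E) + eps
  dimnames(latent) <- list(acc, envs)
  cuts <- stats::quantile(latent, probs = seq_len(length(categories) - 1L) /
                            length(categories))
  cat_idx <- matrix(findInterval(latent, cuts) + 1L, n, e)
  recs <- data.frame(
    accession = rep(acc, e), environment = rep(envs, each = n),
    replicate = 1L, trait = name,
    value = categories[as.vector(cat_idx)], stringsAsFactors = FALSE)
  sp <- list(trait_spec(name, "qualitative", categories = categories))
  list(met = met_table(recs, sp), latent = latent)
}
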