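#' Filter SNPs and accessions for association analysis
#'
#' Rules applied in order: (1) drop accessions with more than
#' `ind_missing_max` missing markers; (2) drop markers with more than
#' `snp_missing_max` missing accessions; (3) drop markers with
#' MAF < `maf_min` (the boundary MAF is kept); (4) drop markers with a
#' heterozygous-call fraction >= `het_max` (the biologically coherent reading
#' of a "homozygous fraction" filter on inbred lines; the literal reading is
#' available via `literal_hom_filter`).
#'
#' @param g a [genotype_matrix()]
#' @param cfg a [run_config()] supplying the thresholds
#' @param literal_hom_filter drop markers with *homozygous* fraction
#'   >= `het_max` instead (the printed rule read literally)
#' @return list(genotypes = filtered [genotype_matrix()], report = data.frame
#'   of per-rule removal counts)
#' @export
filter_snps <- function(g, cfg = run_config(), literal_hom_filter = FALSE) {
  n0 <- nrow(g$codes); m0 <- ncol(g$codes)
  acc_miss <- rowMeans(is.na(g$codes))
  keep_acc <- acc_miss <= cfg$ind_missing_max
  g1 <- subset_genotypes(g, accessions = keep_acc)
  snp_miss <- colMeans(is.na(g1$codes))
  keep1 <- snp_miss <= cfg$snp_missing_max
  g2 <- subset_genotypes(g1, markers = keep1)
  maf <- marker_maf(g2)
  keep2 <- !is.na(maf) & maf >= cfg$maf_min
  g3 <- subset_genotypes(g2, markers = keep2)
  frac <- marker_het(g3)
  if (literal_hom_filter) frac <- 1 - frac
  keep3 <- frac < cfg$het_max
  g4 <- subset_genotypes(g3, markers = keep3)
  if (ncol(g4$codes) == 0L || nrow(g4$codes) == 0L)
    stop("no markers/accessions left after filtering")
  report <- data.frame(
    rule = c("accession_missing", "marker_missing", "maf", "het_fraction"),
    removed = c(n0 - nrow(g1$codes), m0 - ncol(g2$codes),
                ncol(g2$codes) - ncol(g3$codes),
                ncol(g3$codes) - ncol(g4$codes)))
  list(genotypes = g4, report = report)
}

#' Identity-by-state kinship matrix
#'
#' `ibs_emma` (default): `K_ij` is the mean over markers non-missing in both
#' accessions of `1 - |g_i - g_j| / 2`, the additive-heterozygote IBS used as
#' the random-effect covariance in the mixed-model scan. `centered_ibs`:
#' VanRaden-style centered dosage cross-product (mean-imputed), used for
#' structure summaries and MDS.
#'
#' @param g a (filtered) [genotype_matrix()]
#' @param variant "ibs_emma" or "centered_ibs"
#' @return symmetric accession x accession matrix with attribute `variant`;
#'   `ibs_emma` values lie in `[0, 1]` with unit diagonal
#' @export
kinship <- function(g, variant = c("ibs_emma", "centered_ibs")) {
  variant <- match.arg(variant)
  codes <- g$codes
  if (variant == "ibs_emma") {
    obs <- !is.na(codes)
    n_shared <- tcrossprod(obs * 1)
    if (any(n_shared == 0))
      stop("accession pair with zero shared markers: kinship undefined")
    I0 <- (codes == 0L) & obs; I1 <- (codes == 1L) & obs; I2 <- (codes == 2L) & obs
    I0 <- I0 * 1; I1 <- I1 * 1; I2 <- I2 * 1
    absdiff <- tcrossprod(I0, I1) + tcrossprod(I1, I0) +
      tcrossprod(I1, I2) + tcrossprod(I2, I1) +
      2 * (tcrossprod(I0, I2) + tcrossprod(I2, I0))
    K <- 1 - absdiff / (2 * n_shared)
  } else {
    M <- codes
    cm <- colMeans(M, na.rm = TRUE)
    for (j in seq_len(ncol(M))) M[is.na(M[, j]), j] <- cm[j]
    W <- sweep(M, 2L, cm)
    p <- cm / 2
    denom <- 2 * sum(p * (1 - p))
    K <- tcrossprod(W) / denom
  }
  K <- (K + t(K)) / 2
  attr(K, "variant") <- variant
  K
}

emma_reml_delta <- function(ystar, Xstar, d, lower = -10, upper = 10) {
  n <- length(ystar); q <- ncol(Xstar)
  negll <- function(logdelta) {
    delta <- exp(logdelta)
    w <- 1 / (d + delta)
    XtWX <- crossprod(Xstar * w, Xstar)
    XtWy <- crossprod(Xstar * w, ystar)
    beta <- solve(XtWX, XtWy)
    r <- ystar - Xstar %*% beta
    rss <- sum(w * r^2)
    0.5 * ((n - q) * log(rss) + sum(log(d + delta)) +
             determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- stats::optimize(negll, c(lower, upper), tol = 1e-6)
  # guard against edge optima
  for (edge in c(lower, upper))
    if (negll(edge) < opt$objective) opt <- list(minimum = edge, objective = negll(edge))
  exp(opt$minimum)
}

gls_test <- function(ystar, Xstar, d, delta) {
  n <- length(ystar); q <- ncol(Xstar)
  w <- 1 / (d + delta)
  XtWX <- crossprod(Xstar * w, Xstar)
  beta <- solve(XtWX, crossprod(Xstar * w, ystar))
  r <- ystar - Xstar %*% beta
  sigma2 <- sum(w * r^2) / (n - q)
  covb <- sigma2 * solve(XtWX)
  se <- sqrt(diag(covb))
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = n - q, lower.tail = FALSE)
  list(beta = as.vector(beta), se = se, t = as.vector(tval), p = as.vector(p))
}

#' Single-marker mixed-model association scan
#'
#' For each marker, fits `y = mu + beta * x + g + e` with the kinship matrix
#' as the covariance of the polygenic random effect, by REML on data rotated
#' through a one-time eigendecomposition of K (EMMA-style exact per-marker
#' variance-ratio optimization by default; a single null-model estimate is
#' reused when `method = "approx"`). Marker dosages enter additively
#' (heterozygote = 1); missing dosages are mean-imputed within the scan while
#' `n` reports the non-missing count. With `K = identity` the scan reduces
#' exactly to ordinary least squares.
#'
#' @param y named per-accession response vector
#' @param g a [genotype_matrix()] (accessions matched to `names(y)`)
#' @param K kinship matrix from [kinship()]
#' @param method "exact" or "approx"
#' @param analysis label stored in the result (e.g. "mean", "stability",
#'   "gei:E1")
#' @param trait trait label stored in the result
#' @return data.frame: marker, chrom, pos, trait, analysis, beta, se, p, maf,
#'   n; skipped (constant) markers are absent
#' @export
lmm_scan <- function(y, g, K, method = c("exact", "approx"),
                     analysis = "mean", trait = "trait") {
  method <- match.arg(method)
  acc <- intersect(rownames(g$codes), names(y)[!is.na(y)])
  if (length(acc) < 5L) stop("too few accessions with response values")
  y <- y[acc]
  codes <- g$codes[acc, , drop = FALSE]
  K <- K[acc, acc]
  if (stats::sd(y) == 0) {
    warning("constant response: all p-values set to 1")
    maf <- marker_maf(genotype_matrix(codes, g$map))
    return(data.frame(marker = g$map$marker_id, chrom = g$map$chrom,
                      pos = g$map$pos, trait = trait, analysis = analysis,
                      beta = 0, se = NA_real_, p = 1, maf = maf,
                      n = colSums(!is.na(codes)), row.names = NULL))
  }
  eig <- eigen(K, symmetric = TRUE)
  d <- pmax(eig$values, 1e-10)
  Ut <- t(eig$vectors)
  ystar <- as.vector(Ut %*% y)
  one_star <- Ut %*% rep(1, length(y))
  delta0 <- NULL
  if (method == "approx")
    delta0 <- emma_reml_delta(ystar, one_star, d)
  out <- vector("list", ncol(codes))
  for (m in seq_len(ncol(codes))) {
    x <- codes[, m]
    n_used <- sum(!is.na(x))
    xm <- mean(x, na.rm = TRUE)
    if (is.nan(xm)) next
    x[is.na(x)] <- xm
    if (stats::sd(x) == 0) next  # monomorphic: skipped
    Xstar <- cbind(one_star, Ut %*% x)
    delta <- if (method == "approx") delta0 else emma_reml_delta(ystar, Xstar, d)
    fit <- gls_test(ystar, Xstar, d, delta)
    p_obs <- x[x %in% c(0, 1, 2)]
    pa <- xm / 2
    out[[m]] <- data.frame(marker = g$map$marker_id[m], chrom = g$map$chrom[m],
                           pos = g$map$pos[m], trait = trait,
                           analysis = analysis, beta = fit$beta[2],
                           se = fit$se[2], p = fit$p[2],
                           maf = min(pa, 1 - pa), n = n_used,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-stage genome-wide environment interaction scan (GWEIS)
#'
#' Stage 1 fits the fixed two-way model
#' `Y_ij = mu + G_i + E_j + (GE)_ij` by least squares on the accession x
#' environment cell means, extracting the genotype-mean vector and the
#' per-environment interaction-effect vectors (on balanced data each
#' accession's interaction effects sum to zero). Stage 2 runs [lmm_scan()]
#' on the mean vector (meanQTL candidates, tagged "mean") and on each
#' environment's interaction vector (QTI candidates, tagged "gei:<env>").
#'
#' @param met a [met_table()]
#' @param trait replicated quantitative trait observed in >= 2 environments
#' @param g a [genotype_matrix()]
#' @param K kinship matrix
#' @param method passed to [lmm_scan()]
#' @return list(mean_scan, gei_scans (named list per environment),
#'   stage1 = list(mean_vector, ge_matrix))
#' @export
gweis_two_stage <- function(met, trait, g, K, method = c("exact", "approx")) {
  method <- match.arg(method)
  cells <- trait_cell_means(met, trait)
  keep <- rowSums(!is.na(cells)) > 0L
  dropped <- rownames(cells)[!keep]
  if (length(dropped))
    message("dropped accession(s) with no observations: ",
            paste(dropped, collapse = ", "))
  cells <- cells[keep, , drop = FALSE]
  if (ncol(cells) < 2L) stop("need >= 2 environments")
  long <- data.frame(y = as.vector(cells),
                     gf = factor(rep(rownames(cells), ncol(cells))),
                     ef = factor(rep(colnames(cells), each = nrow(cells))))
  long <- long[!is.na(long$y), ]
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  fit <- stats::lm(y ~ gf + ef, data = long)
  pr <- stats::predict(fit, newdata = expand.grid(
    gf = levels(long$gf), ef = levels(long$ef)))
  fitted_main <- matrix(pr, nrow = nlevels(long$gf),
                        dimnames = list(levels(long$gf), levels(long$ef)))
  acc_mean <- rowMeans(fitted_main)
  ge <- cells - fitted_main[rownames(cells), colnames(cells)]
  ge[is.na(cells)] <- NA
  mean_scan <- lmm_scan(acc_mean, g, K, method = method, analysis = "mean",
                        trait = trait)
  gei_scans <- lapply(colnames(ge), function(ev) {
    v <- ge[, ev]; names(v) <- rownames(ge)
    lmm_scan(v, g, K, method = method, analysis = paste0("gei:", ev),
             trait = trait)
  })
  names(gei_scans) <- colnames(ge)
  list(mean_scan = mean_scan, gei_scans = gei_scans,
       stage1 = list(mean_vector = acc_mean, ge_matrix = ge))
}

#' Multiple-testing threshold from the effective number of independent tests
#'
#' Li-Ji effective number of tests: per chromosome, the eigenvalues of the
#' marker correlation matrix contribute `I(lambda >= 1) + (lambda -
#' floor(lambda))` each; chromosome contributions are summed to `Meff` and
#' the Sidak cutoff `1 - (1 - alpha)^(1/Meff)` is returned (Bonferroni
#' `alpha / Meff` by flag).
#'
#' @param g a (filtered) [genotype_matrix()]
#' @param alpha family-wise error rate
#' @param bonferroni use `alpha / Meff` instead of the Sidak form
#' @return list(meff, cutoff, per_chromosome = named vector)
#' @export
significance_threshold <- function(g, alpha = 0.05, bonferroni = FALSE) {
  chroms <- unique(g$map$chrom)
  meff_c <- stats::setNames(numeric(length(chroms)), chroms)
  for (ch in chroms) {
    idx <- which(g$map$chrom == ch)
    if (length(idx) == 1L) { meff_c[ch] <- 1; next }
    M <- g$codes[, idx, drop = FALSE]
    cm <- colMeans(M, na.rm = TRUE)
    for (j in seq_len(ncol(M))) M[is.na(M[, j]), j] <- cm[j]
    sds <- apply(M, 2L, stats::sd)
    M <- M[, sds > 0, drop = FALSE]
    if (ncol(M) == 0L) { meff_c[ch] <- 0; next }
    if (ncol(M) == 1L) { meff_c[ch] <- 1; next }
    C <- stats::cor(M)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    ev <- round(pmax(ev, 0), 10)  # exact-duplicate eigenvalues hit integers
    meff_c[ch] <- sum((ev >= 1) + (ev - floor(ev)))
  }
  meff <- sum(meff_c)
  cutoff <- if (bonferroni) alpha / meff else 1 - (1 - alpha)^(1 / meff)
  list(meff = meff, cutoff = cutoff, per_chromosome = meff_c)
}

#' Genomic inflation factor (lambda_GC) of a p-value vector
#' @param p p-values
#' @return median chi-squared statistic over its null expectation
#' @export
genomic_inflation <- function(p) {
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}
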