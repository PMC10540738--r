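#' Allelic-class marginal means for a marker
#'
#' Least-squares class means of a per-accession response for the three
#' allelic states AA (code 0), AB (1), BB (2), with standard errors from the
#' pooled residual variance. Classes shared by no more than `min_class_n`
#' accessions are dropped; with fewer than two classes left the marker is
#' not analysable.
#'
#' @param response named per-accession values (BLUPg or a stability index)
#' @param codes named per-accession dosage codes for one marker
#' @param min_class_n classes are kept when their count is strictly greater
#'   than this (default 3)
#' @return list(means, se, n (all named by class among "AA","AB","BB"),
#'   sigma2 (pooled residual variance), df, analysable)
#' @export
class_means <- function(response, codes, min_class_n = 3L) {
  acc <- intersect(names(response), names(codes))
  y <- response[acc]; x <- codes[acc]
  ok <- !is.na(y) & !is.na(x)
  y <- y[ok]; x <- x[ok]
  if (!length(y)) stop("all observations missing")
  lab <- c("AA", "AB", "BB")[x + 1]
  cnt <- table(factor(lab, levels = c("AA", "AB", "BB")))
  keep <- names(cnt)[cnt > min_class_n]
  sel <- lab %in% keep
  y <- y[sel]; lab <- lab[sel]
  if (length(keep) < 2L)
    return(list(means = NULL, se = NULL, n = as.vector(cnt[keep]),
                sigma2 = NA_real_, df = NA_real_, analysable = FALSE))
  means <- tapply(y, lab, mean)[keep]
  n <- as.vector(table(factor(lab, levels = keep)))
  names(n) <- keep
  df <- length(y) - length(keep)
  sigma2 <- sum((y - means[lab])^2) / df
  se <- sqrt(sigma2 / n)
  list(means = means, se = se, n = n, sigma2 = sigma2, df = df,
       analysable = TRUE)
}

contrast_t <- function(cm, w) {
  # t-test of sum(w * means) = 0 with pooled variance
  est <- sum(w * cm$means)
  se <- sqrt(cm$sigma2 * sum(w^2 / cm$n))
  t <- est / se
  p <- 2 * stats::pt(abs(t), df = cm$df, lower.tail = FALSE)
  list(estimate = est, p = p)
}

#' Classify a marker's mode of inheritance from allelic-class means
#'
#' Sequential contrast scheme on the marginal means: the additive null
#' `AB - (AA+BB)/2 = 0` is tested first; if retained, the mode is additive.
#' If rejected, the dominant and recessive nulls are tested with roles set
#' by the sign of the allelic effect (when BB > AA, `AB - BB = 0` is the
#' dominant model and `AB - AA = 0` the recessive one; mirrored otherwise).
#' When all nulls are rejected and AB exceeds both homozygote means the mode
#' is overdominant; an AB below both homozygotes is reported non-conclusive
#' (no underdominance class), as is a tie between retained models with
#' conflicting signs. Reports `a = (AA - BB)/2`, `d = AB - (AA + BB)/2` and
#' the minor-allele effect direction.
#'
#' @param cm a [class_means()] result with all three classes (two homozygote
#'   classes give "additive" by default with `d_testable = FALSE`)
#' @param alpha contrast significance level
#' @param maf_class which homozygote carries the minor allele ("AA" or "BB");
#'   used for the direction of effect
#' @return list(mode, a, d, direction, d_testable, contrasts)
#' @export
classify_mode <- function(cm, alpha = 0.05, maf_class = "BB") {
  if (!isTRUE(cm$analysable))
    return(list(mode = "not_analysable", a = NA_real_, d = NA_real_,
                direction = NA_character_, d_testable = FALSE,
                contrasts = NULL))
  classes <- names(cm$means)
  has_het <- "AB" %in% classes
  AA <- unname(cm$means["AA"]); BB <- unname(cm$means["BB"])
  AB <- if (has_het) unname(cm$means["AB"]) else NA_real_
  direction <- NA_character_
  if (all(c("AA", "BB") %in% classes)) {
    minor_mean <- if (maf_class == "BB") BB else AA
    major_mean <- if (maf_class == "BB") AA else BB
    direction <- if (minor_mean >= major_mean) "increases" else "decreases"
  }
  if (!has_het || !all(c("AA", "BB") %in% classes)) {
    a <- if (all(c("AA", "BB") %in% classes)) (AA - BB) / 2 else NA_real_
    return(list(mode = "additive", a = a, d = NA_real_,
                direction = direction, d_testable = FALSE, contrasts = NULL))
  }
  a <- (AA - BB) / 2
  d <- AB - (AA + BB) / 2
  w_add <- c(AA = -0.5, AB = 1, BB = -0.5)[classes]
  add <- contrast_t(cm, w_add)
  contrasts <- list(additive = add$p)
  if (add$p >= alpha)
    return(list(mode = "additive", a = a, d = d, direction = direction,
                d_testable = TRUE, contrasts = contrasts))
  b_positive <- BB > AA
  w_ab_bb <- c(AA = 0, AB = 1, BB = -1)[classes]
  w_ab_aa <- c(AA = -1, AB = 1, BB = 0)[classes]
  if (b_positive) {
    dom <- contrast_t(cm, w_ab_bb); rec <- contrast_t(cm, w_ab_aa)
  } else {
    dom <- contrast_t(cm, w_ab_aa); rec <- contrast_t(cm, w_ab_bb)
  }
  contrasts$dominant <- dom$p; contrasts$recessive <- rec$p
  dom_ok <- dom$p >= alpha; rec_ok <- rec$p >= alpha
  mode <- if (dom_ok && rec_ok) "non_conclusive"
  else if (dom_ok) "dominant"
  else if (rec_ok) "recessive"
  else if (AB > max(AA, BB)) "overdominant"
  else "non_conclusive"
  list(mode = mode, a = a, d = d, direction = direction, d_testable = TRUE,
       contrasts = contrasts)
}

#' Gene action of one marker against one response
#'
#' Convenience wrapper: [class_means()] then [classify_mode()], taking the
#' minor-allele homozygote from observed allele counts.
#'
#' @param response named per-accession response
#' @param codes named per-accession dosages for the marker
#' @param alpha contrast level
#' @param min_class_n minimum class count (strict `>`)
#' @return a [classify_mode()] result plus `class_means`
#' @export
gene_action <- function(response, codes, alpha = 0.05, min_class_n = 3L) {
  cm <- class_means(response, codes, min_class_n = min_class_n)
  p_alt <- mean(codes, na.rm = TRUE) / 2
  maf_class <- if (p_alt <= 0.5) "BB" else "AA"
  res <- classify_mode(cm, alpha = alpha, maf_class = maf_class)
  res$class_means <- cm
  res
}

#' Per-environment allelic-effect profile and QTI type
#'
#' Fits `BLUPge_ij = b0 + b1 * SNP_i + E_j + (SNP x E)_ij + eps` on the two
#' homozygote classes, tests the homozygote difference (BB - AA) within each
#' environment by one-way ANOVA at `alpha`, and assigns the interaction
#' type: opposite significant signs in two environments = QTL5 (antagonistic
#' pleiotropy); a mix of significant and non-significant environments =
#' QTL4 (conditional neutrality); all environments significant with the same
#' sign = QTL3 (magnitude change) provided the SNP x E interaction term is
#' itself significant, otherwise the marker has a consistent effect and no
#' QTI type. A Hotelling-type T-squared comparing the homozygote mean
#' vectors across environments is reported as a supporting statistic.
#'
#' @param blup_ge genotype x environment BLUP matrix
#' @param codes named per-accession dosages
#' @param alpha per-environment test level
#' @param min_class_n homozygote classes need more than this many accessions
#' @return list(type, effects (BB - AA per environment), p_env,
#'   significant, interaction_p, hotelling, note)
#' @export
qti_effect_profile <- function(blup_ge, codes, alpha = 0.05, min_class_n = 3L) {
  acc <- intersect(rownames(blup_ge), names(codes))
  x <- codes[acc]
  hom <- !is.na(x) & x %in% c(0, 2)
  acc <- acc[hom]; x <- x[hom]
  n_aa <- sum(x == 0); n_bb <- sum(x == 2)
  if (n_aa <= min_class_n || n_bb <= min_class_n)
    return(list(type = "non_conclusive", effects = NULL, p_env = NULL,
                significant = NULL, interaction_p = NA_real_,
                hotelling = NULL, note = "homozygote class too small"))
  B <- blup_ge[acc, , drop = FALSE]
  envs <- colnames(B)
  long <- data.frame(y = as.vector(B),
                     snp = factor(rep(ifelse(x == 0, "AA", "BB"), ncol(B))),
                     e = factor(rep(envs, each = nrow(B))))
  fit <- stats::aov(y ~ snp + e + snp:e, data = long)
  atab <- summary(fit)[[1]]
  rn <- trimws(rownames(atab))
  interaction_p <- atab[rn == "snp:e", "Pr(>F)"]
  effects <- p_env <- stats::setNames(numeric(length(envs)), envs)
  excluded <- character(0)
  for (ev in envs) {
    ya <- B[x == 0, ev]; yb <- B[x == 2, ev]
    ya <- ya[!is.na(ya)]; yb <- yb[!is.na(yb)]
    if (!length(ya) || !length(yb)) {
      effects[ev] <- NA; p_env[ev] <- NA; excluded <- c(excluded, ev); next
    }
    effects[ev] <- mean(yb) - mean(ya)
    p_env[ev] <- summary(stats::aov(y ~ g, data = data.frame(
      y = c(ya, yb), g = factor(rep(c("AA", "BB"), c(length(ya), length(yb))))
    )))[[1]][1, "Pr(>F)"]
  }
  use <- !is.na(p_env)
  sig <- p_env < alpha & use
  note <- if (length(excluded))
    paste("environments excluded:", paste(excluded, collapse = ",")) else NA_character_
  sig_eff <- effects[which(sig)]
  type <- if (sum(sig) >= 2L && min(sig_eff) < 0 && max(sig_eff) > 0) "QTL5"
  else if (any(sig) && any(!sig & use)) "QTL4"
  else if (all(sig[use]) && sum(use) >= 2L) {
    if (!is.na(interaction_p) && interaction_p < alpha) "QTL3"
    else { note <- "consistent_effect"; "non_conclusive" }
  } else "non_conclusive"
  # Hotelling-type T2 on per-environment class means
  hot <- tryCatch({
    Ma <- B[x == 0, , drop = FALSE]; Mb <- B[x == 2, , drop = FALSE]
    diffm <- colMeans(Mb, na.rm = TRUE) - colMeans(Ma, na.rm = TRUE)
    Sp <- ((n_aa - 1) * stats::cov(Ma, use = "pairwise") +
             (n_bb - 1) * stats::cov(Mb, use = "pairwise")) / (n_aa + n_bb - 2)
    t2 <- (n_aa * n_bb / (n_aa + n_bb)) *
      drop(t(diffm) %*% solve(Sp, diffm))
    pdim <- ncol(B); ntot <- n_aa + n_bb
    fstat <- t2 * (ntot - pdim - 1) / (pdim * (ntot - 2))
    pval <- stats::pf(fstat, pdim, ntot - pdim - 1, lower.tail = FALSE)
    list(t2 = t2, p = pval)
  }, error = function(e) NULL)
  list(type = type, effects = effects, p_env = p_env, significant = sig,
       interaction_p = interaction_p, hotelling = hot, note = note)
}

#' QTL-level consensus of per-SNP gene-action results
#'
#' Unanimous mode and direction across member SNPs carry over to the QTL;
#' any disagreement makes the estimate non-conclusive.
#'
#' @param modes character vector of member-SNP modes
#' @param directions character vector of member-SNP effect directions
#' @return list(mode, direction)
#' @export
qtl_consensus <- function(modes, directions = NULL) {
  modes <- modes[!is.na(modes)]
  if (!length(modes)) return(list(mode = "not_analysable", direction = NA_character_))
  mode <- if (length(unique(modes)) == 1L) modes[1] else "non_conclusive"
  direction <- NA_character_
  if (!is.null(directions)) {
    dd <- directions[!is.na(directions)]
    direction <- if (length(dd) && length(unique(dd)) == 1L) dd[1]
    else if (length(dd)) "non_conclusive" else NA_character_
  }
  list(mode = mode, direction = direction)
}
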