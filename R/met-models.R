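#' REML variance decomposition and BLUPs for a replicated MET trait
#'
#' Fits the combined-trial mixed model
#' `Y_ijk = mu + G_i + E_j + (GxE)_ij + eps_ijk` twice by REML:
#' once with the grand mean fixed and genotype, environment and interaction
#' random (the variance-component run reported in the decomposition), and
#' once with environment fixed and genotype and interaction random, from
#' which the BLUPs (`BLUPg`, `BLUPge`) and the broad-sense heritability
#' `H2 = s2_g / (s2_g + s2_ge + s2_eps)` are extracted. Unbalanced designs
#' (missing plots) are handled natively by REML.
#'
#' @param met a [met_table()]
#' @param trait a replicated quantitative trait name
#' @param lrt compute per-component likelihood-ratio tests (refits the
#'   all-random model once per component)
#' @param boundary use the 0.5*chi2_0 + 0.5*chi2_1 boundary mixture for LRT
#'   p-values instead of the literal one-df chi-squared
#' @return list with elements
#'   `vc` (data.frame: component, sigma2, percent, lrt_stat, lrt_p),
#'   `mu`, `H2`, `blup_g` (named vector), `blup_ge` (genotype x environment
#'   matrix), `trait`, and `converged`.
#' @export
fit_met_mixed <- function(met, trait, lrt = TRUE, boundary = FALSE) {
  sp <- attr(met, "trait_specs")[[trait]]
  if (is.null(sp) || sp$kind != "replicated_quantitative")
    stop("trait must be replicated_quantitative")
  d <- met[met$trait == trait & !is.na(met$value), ]
  d <- data.frame(y = as.numeric(d$value), g = factor(d$accession),
                  e = factor(d$environment))
  if (nlevels(d$e) < 2L) stop("degenerate design: need >= 2 environments")
  if (nlevels(d$g) < 2L) stop("degenerate design: need >= 2 accessions")
  ctl <- lme4::lmerControl(check.conv.singular = "ignore",
                           calc.derivs = FALSE)
  if (stats::var(d$y) == 0) {
    vc <- data.frame(component = c("genotype", "environment", "gxe", "residual"),
                     sigma2 = 0, percent = NA_real_, lrt_stat = NA_real_,
                     lrt_p = NA_real_)
    bg <- stats::setNames(rep(0, nlevels(d$g)), levels(d$g))
    bge <- matrix(0, nlevels(d$g), nlevels(d$e),
                  dimnames = list(levels(d$g), levels(d$e)))
    return(list(vc = vc, mu = d$y[1], H2 = NA_real_, blup_g = bg,
                blup_ge = bge, trait = trait, converged = TRUE))
  }
  full <- suppressMessages(
    lme4::lmer(y ~ 1 + (1 | g) + (1 | e) + (1 | g:e), data = d, REML = TRUE,
               control = ctl))
  vcs <- as.data.frame(lme4::VarCorr(full))
  get_vc <- function(grp) {
    v <- vcs$vcov[vcs$grp == grp]
    if (length(v)) v else 0
  }
  s2 <- c(genotype = get_vc("g"), environment = get_vc("e"),
          gxe = get_vc("g:e"), residual = get_vc("Residual"))
  percent <- 100 * s2 / sum(s2)
  lrt_stat <- lrt_p <- rep(NA_real_, 4L)
  if (lrt) {
    drops <- list(genotype = y ~ 1 + (1 | e) + (1 | g:e),
                  environment = y ~ 1 + (1 | g) + (1 | g:e),
                  gxe = y ~ 1 + (1 | g) + (1 | e))
    ll_full <- as.numeric(stats::logLik(full))
    for (i in seq_along(drops)) {
      red <- suppressMessages(
        lme4::lmer(drops[[i]], data = d, REML = TRUE, control = ctl))
      res <- lrt_component(full, red, boundary = boundary)
      lrt_stat[i] <- res$statistic
      lrt_p[i] <- res$p
    }
  }
  vc <- data.frame(component = names(s2), sigma2 = unname(s2),
                   percent = unname(percent), lrt_stat = lrt_stat,
                   lrt_p = lrt_p)
  # BLUP parametrization: environment fixed, genotype and interaction random
  fitb <- suppressMessages(
    lme4::lmer(y ~ e + (1 | g) + (1 | g:e), data = d, REML = TRUE,
               control = ctl))
  re <- lme4::ranef(fitb)
  bg <- stats::setNames(re$g[[1]], rownames(re$g))
  bge <- matrix(0, nlevels(d$g), nlevels(d$e),
                dimnames = list(levels(d$g), levels(d$e)))
  ge_nm <- do.call(rbind, strsplit(rownames(re$`g:e`), ":", fixed = TRUE))
  bge[cbind(ge_nm[, 1], ge_nm[, 2])] <- re$`g:e`[[1]]
  vcb <- as.data.frame(lme4::VarCorr(fitb))
  s2b <- c(g = vcb$vcov[vcb$grp == "g"], ge = vcb$vcov[vcb$grp == "g:e"],
           eps = vcb$vcov[vcb$grp == "Residual"])
  H2 <- heritability(s2b["g"], s2b["ge"], s2b["eps"])
  conv <- is.null(full@optinfo$conv$lme4$messages) &&
    is.null(fitb@optinfo$conv$lme4$messages)
  list(vc = vc, mu = unname(lme4::fixef(full)[1]), H2 = H2, blup_g = bg,
       blup_ge = bge, trait = trait, converged = conv,
       sigma2_blup_fit = s2b)
}

#' Broad-sense heritability across environments
#'
#' `H2 = s2_g / (s2_g + s2_ge + s2_eps)`; the environment main-effect
#' variance is deliberately excluded.
#'
#' @param sigma2_g,sigma2_ge,sigma2_eps variance components
#' @return H2 in `[0, 1]`, or `NA` when the denominator is zero
#' @export
heritability <- function(sigma2_g, sigma2_ge, sigma2_eps) {
  den <- sigma2_g + sigma2_ge + sigma2_eps
  if (den <= 0) return(NA_real_)
  unname(sigma2_g / den)
}

#' Likelihood-ratio test of a dropped variance component
#'
#' `statistic = 2 * (logLik_full - logLik_reduced)` clipped at zero, with the
#' p-value from a one-df chi-squared by default (the conventional boundary
#' mixture halves it via `boundary = TRUE`). Both fits must be REML with the
#' same fixed-effect structure, otherwise their likelihoods are not
#' comparable.
#'
#' @param full,reduced `lmerMod` fits, `reduced` nesting `full` with one
#'   random component dropped
#' @param boundary use the 50:50 chi2_0/chi2_1 mixture
#' @return list(statistic, p)
#' @export
lrt_component <- function(full, reduced, boundary = FALSE) {
  if (!isTRUE(all.equal(stats::formula(full, fixed.only = TRUE),
                        stats::formula(reduced, fixed.only = TRUE))))
    stop("fixed-effect structures differ: REML likelihoods not comparable")
  stat <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                        as.numeric(stats::logLik(reduced))))
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (boundary) p <- p / 2
  if (stat == 0) p <- 1
  list(statistic = stat, p = p)
}

#' Closed-form balanced-design ANOVA variance components
#'
#' Method-of-moments solution of the expected mean squares for a balanced
#' two-way design with replicates; used as an independent oracle for the
#' REML fit (they coincide when all components are interior).
#'
#' @param met a [met_table()]
#' @param trait trait name
#' @return named vector (genotype, environment, gxe, residual)
#' @export
anova_moments <- function(met, trait) {
  d <- met[met$trait == trait & !is.na(met$value), ]
  y <- as.numeric(d$value)
  g <- factor(d$accession); e <- factor(d$environment)
  ng <- nlevels(g); ne <- nlevels(e)
  k <- nrow(d) / (ng * ne)
  if (abs(k - round(k)) > 1e-9) stop("design is not balanced")
  fit <- stats::aov(y ~ g * e)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  names(ms) <- trimws(rownames(summary(fit)[[1]]))
  mse <- ms[["Residuals"]]
  s2_ge <- max(0, (ms[["g:e"]] - mse) / k)
  s2_g <- max(0, (ms[["g"]] - ms[["g:e"]]) / (k * ne))
  s2_e <- max(0, (ms[["e"]] - ms[["g:e"]]) / (k * ng))
  c(genotype = s2_g, environment = s2_e, gxe = s2_ge, residual = mse)
}

#' Fixed-effects two-way ANOVA for accession-mean traits
#'
#' Type-III tests of genotype and environment in the additive fixed model
#' (no interaction term, which is inestimable with one value per cell), plus
#' the accession x environment mean table for interaction plotting.
#' Qualitative traits are accepted when their categories are integer-coded.
#'
#' @param met a [met_table()]
#' @param trait an accession-mean quantitative (or integer-scored
#'   qualitative) trait
#' @return list(anova = data.frame(term, df, sum_sq, f, p),
#'   cell_means = long data.frame(accession, environment, mean))
#' @export
fixed_anova <- function(met, trait) {
  d <- met[met$trait == trait & !is.na(met$value), ]
  v <- suppressWarnings(as.numeric(d$value))
  if (any(is.na(v))) stop("trait must be numeric or integer-scored")
  d <- data.frame(y = v, g = factor(d$accession), e = factor(d$environment))
  if (nlevels(d$g) < 2L || nlevels(d$e) < 2L)
    stop("need >= 2 levels of genotype and environment")
  cells <- stats::aggregate(y ~ g + e, data = d, FUN = mean)
  names(cells) <- c("accession", "environment", "mean")
  if (stats::var(d$y) == 0) {
    an <- data.frame(term = c("genotype", "environment"), df = NA_real_,
                     sum_sq = 0, f = NA_real_, p = 1)
    return(list(anova = an, cell_means = cells))
  }
  op <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(op))
  fit <- stats::lm(y ~ g + e, data = d)
  dr <- stats::drop1(fit, ~., test = "F")  # marginal (type III) SS
  an <- data.frame(term = c("genotype", "environment"),
                   df = dr$Df[-1], sum_sq = dr$`Sum of Sq`[-1],
                   f = dr$`F value`[-1], p = dr$`Pr(>F)`[-1])
  list(anova = an, cell_means = cells)
}
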