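#' WAASB stability index
#'
#' Weighted average of absolute IPCA scores from the singular value
#' decomposition of the genotype x environment matrix of interaction BLUPs:
#' `WAASB_i = sum_k |IPCA_ik| * EP_k / sum_k EP_k`, with genotype scores
#' `U * Lambda`, `EP_k = lambda_k^2 / sum lambda^2`, and all
#' `p = min(g - 1, e - 1)` axes retained. The genotype with the lowest value
#' is the most stable.
#'
#' @param blup_ge genotype x environment matrix of interaction BLUPs (from
#'   [fit_met_mixed()])
#' @return list(waasb = named vector sorted by genotype order,
#'   scores = genotype x axis IPCA matrix, ep = explained proportions,
#'   ranking = genotype ids sorted most-stable first)
#' @export
waasb <- function(blup_ge) {
  blup_ge <- as.matrix(blup_ge)
  if (ncol(blup_ge) < 3L)
    stop("WAASB needs at least three environments")
  g <- nrow(blup_ge); e <- ncol(blup_ge)
  p <- min(g - 1L, e - 1L)
  sv <- svd(blup_ge)
  lam <- sv$d[seq_len(p)]
  scores <- sv$u[, seq_len(p), drop = FALSE] %*% diag(lam, p, p)
  rownames(scores) <- rownames(blup_ge)
  tot <- sum(sv$d^2)
  if (tot == 0) {
    w <- stats::setNames(rep(0, g), rownames(blup_ge))
    return(list(waasb = w, scores = scores, ep = rep(0, p),
                ranking = names(w)))
  }
  ep <- lam^2 / tot
  w <- as.vector(abs(scores) %*% ep) / sum(ep)
  names(w) <- rownames(blup_ge)
  list(waasb = w, scores = scores, ep = ep,
       ranking = names(sort(w)))
}

#' GGE average-environment-coordination (AEC) stability
#'
#' Centers the genotype x environment mean table by environment (removing
#' `mu + E_j`), takes the SVD, and under genotype-focused singular value
#' partitioning (genotype scores `U * Lambda`, environment scores `V`)
#' defines the average environment as the mean of the environment PC1-PC2
#' scores. The AEC abscissa is the line through the origin and that point;
#' a genotype's stability is the perpendicular distance of its 2-D score to
#' that line (shorter projection onto the AEC ordinate = more stable). Axis
#' signs are fixed by forcing the average-environment PC1 coordinate (and,
#' for axis 2, the first environment's coordinate) non-negative.
#'
#' @param means complete genotype x environment matrix of trait means;
#'   missing cells are imputed by environment means (flagged in the result)
#' @return list(projection = named per-genotype AEC-ordinate distance,
#'   genotype_scores, environment_scores (2 columns each),
#'   avg_env = average-environment coordinates, singular_values,
#'   imputed = logical, rank_deficient = logical,
#'   ranking = genotype ids most-stable first)
#' @export
gge_aec_stability <- function(means) {
  means <- as.matrix(means)
  if (ncol(means) < 3L) stop("AEC stability needs at least three environments")
  imputed <- FALSE
  if (anyNA(means)) {
    imputed <- TRUE
    for (j in seq_len(ncol(means))) {
      mj <- means[, j]
      mj[is.na(mj)] <- mean(mj, na.rm = TRUE)
      means[, j] <- mj
    }
  }
  centered <- sweep(means, 2L, colMeans(means))
  sv <- svd(centered)
  rank2 <- sum(sv$d > max(dim(centered)) * max(sv$d) * .Machine$double.eps)
  rank_deficient <- rank2 < 2L
  k <- max(1L, min(2L, rank2))
  U <- sv$u[, seq_len(2L), drop = FALSE]
  V <- sv$v[, seq_len(2L), drop = FALSE]
  lam <- sv$d[seq_len(2L)]
  gs <- U %*% diag(lam, 2L, 2L)   # genotype-focused: genotype carries lambda
  es <- V
  avg_env <- colMeans(es)
  if (avg_env[1] < 0) { gs[, 1] <- -gs[, 1]; es[, 1] <- -es[, 1]; avg_env[1] <- -avg_env[1] }
  if (es[1, 2] < 0) { gs[, 2] <- -gs[, 2]; es[, 2] <- -es[, 2] }
  avg_env <- colMeans(es)
  len <- sqrt(sum(avg_env^2))
  if (len == 0 || k < 2L) {
    proj <- if (k < 2L) rep(0, nrow(gs)) else sqrt(rowSums(gs^2))
  } else {
    u <- avg_env / len
    proj <- abs(gs[, 1] * u[2] - gs[, 2] * u[1])
  }
  names(proj) <- rownames(means)
  rownames(gs) <- rownames(means)
  rownames(es) <- colnames(means)
  list(projection = proj, genotype_scores = gs, environment_scores = es,
       avg_env = avg_env, singular_values = sv$d, imputed = imputed,
       rank_deficient = rank_deficient, ranking = names(sort(proj)))
}

#' Mean-stability correlation matrix with significance mask and clustering
#'
#' Pairwise Pearson correlations between per-genotype summaries (trait means
#' or BLUPg, and stability indices); entries with p-values at or above
#' `corr_p` are masked to `NA`, and variables are ordered by complete-linkage
#' hierarchical clustering on the `1 - r` distance.
#'
#' @param summaries data.frame or matrix, one row per genotype, one column
#'   per summary (>= 3 columns)
#' @param corr_p significance mask cutoff (default 0.01)
#' @return list(r, p, masked, order (column order after clustering))
#' @export
correlate_mean_stability <- function(summaries, corr_p = 0.01) {
  x <- as.matrix(summaries)
  if (ncol(x) < 3L) stop("need at least three summaries to correlate")
  nv <- ncol(x)
  r <- p <- matrix(NA_real_, nv, nv, dimnames = list(colnames(x), colnames(x)))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(nv - 1L)) {
    for (j in (i + 1L):nv) {
      ok <- stats::complete.cases(x[, i], x[, j])
      xi <- x[ok, i]; xj <- x[ok, j]
      if (sum(ok) < 3L || stats::sd(xi) == 0 || stats::sd(xj) == 0) next
      ct <- stats::cor.test(xi, xj)
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  masked <- r
  masked[is.na(p) | p >= corr_p] <- NA_real_
  diag(masked) <- 1
  dmat <- 1 - r
  dmat[is.na(dmat)] <- 2  # undefined correlations treated as maximally distant
  hc <- stats::hclust(stats::as.dist(dmat), method = "complete")
  list(r = r, p = p, masked = masked, order = colnames(x)[hc$order])
}

#' Scale values to unit variance
#' @param values numeric vector with >= 2 distinct values
#' @param center also center to mean zero
#' @return vector with standard deviation 1
#' @export
scale_unit_variance <- function(values, center = FALSE) {
  s <- stats::sd(values, na.rm = TRUE)
  if (is.na(s) || s == 0) stop("constant input cannot be scaled to unit variance")
  out <- values / s
  if (center) out <- out - mean(out, na.rm = TRUE)
  out
}
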