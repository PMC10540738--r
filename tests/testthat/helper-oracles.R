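# Independent literal-formula oracles used to cross-check the implementation.
# These deliberately re-derive each quantity from its definition and share no
# code with the package internals.

oracle_waasb <- function(M) {
  p <- min(nrow(M) - 1L, ncol(M) - 1L)
  sv <- svd(M)
  ipca <- sv$u[, 1:p, drop = FALSE] %*% diag(sv$d[1:p], p, p)
  ep <- sv$d[1:p]^2 / sum(sv$d^2)
  sapply(seq_len(nrow(M)), function(i)
    sum(abs(ipca[i, ] * ep)) / sum(ep))
}

oracle_aec <- function(M) {
  C <- sweep(M, 2, colMeans(M))
  sv <- svd(C)
  gs <- sv$u[, 1:2] %*% diag(sv$d[1:2])
  es <- sv$v[, 1:2]
  ae <- colMeans(es)
  # distance from the 2-D genotype point to the line through the origin
  # with direction ae (sign of the axes cancels in the distance)
  u <- ae / sqrt(sum(ae^2))
  abs(gs[, 1] * u[2] - gs[, 2] * u[1])
}

oracle_ibs_kinship <- function(codes) {
  n <- nrow(codes)
  K <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    ok <- !is.na(codes[i, ]) & !is.na(codes[j, ])
    K[i, j] <- mean(1 - abs(codes[i, ok] - codes[j, ok]) / 2)
  }
  K
}

oracle_meff <- function(codes, chrom) {
  total <- 0
  for (ch in unique(chrom)) {
    M <- codes[, chrom == ch, drop = FALSE]
    for (j in seq_len(ncol(M))) M[is.na(M[, j]), j] <- mean(M[, j], na.rm = TRUE)
    M <- M[, apply(M, 2, sd) > 0, drop = FALSE]
    if (ncol(M) == 0) next
    if (ncol(M) == 1) { total <- total + 1; next }
    ev <- eigen(cor(M), symmetric = TRUE, only.values = TRUE)$values
    ev <- pmax(ev, 0)
    total <- total + sum(ifelse(ev >= 1, 1, 0) + (ev - floor(ev)))
  }
  total
}

# direct haplotype counting for phase-known (fully homozygous) samples
oracle_counting_ld <- function(x, y) {
  stopifnot(all(x %in% c(0, 2)), all(y %in% c(0, 2)))
  pAB <- mean(x == 0 & y == 0)
  pA <- mean(x == 0); pB <- mean(y == 0)
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
  else min(pA * pB, (1 - pA) * (1 - pB))
  list(dprime = abs(D / dmax), r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

# exhaustive solid-spine search over all contiguous runs
oracle_spine_blocks <- function(dp, threshold = 0.8) {
  m <- nrow(dp)
  ok <- function(i, j) {
    ks <- i:j
    all(dp[i, ks[-1]] >= threshold) && all(dp[ks[-length(ks)], j] >= threshold)
  }
  blocks <- list(); i <- 1
  while (i < m) {
    js <- rev((i + 1):m)
    hit <- js[vapply(js, function(j) ok(i, j), logical(1))]
    if (!length(hit)) { i <- i + 1; next }
    blocks[[length(blocks) + 1]] <- i:hit[1]
    i <- hit[1] + 1
  }
  blocks
}

# balanced two-way interval-union merge oracle
oracle_merge <- function(iv, gap) {
  iv <- iv[order(iv$start), , drop = FALSE]
  res <- iv[1, c("start", "end")]
  for (i in seq_len(nrow(iv))[-1]) {
    last <- nrow(res)
    if (iv$start[i] <= res$end[last] + gap) res$end[last] <- max(res$end[last], iv$end[i])
    else res <- rbind(res, iv[i, c("start", "end")])
  }
  res
}

# tiny deterministic genotype fixture builder
fixture_genotypes <- function(codes, chrom = NULL, pos = NULL) {
  m <- ncol(codes)
  colnames(codes) <- paste0("M", seq_len(m))
  if (is.null(chrom)) chrom <- rep("chr01", m)
  if (is.null(pos)) pos <- seq(1e5, by = 1e5, length.out = m)
  genotype_matrix(codes, data.frame(marker_id = paste0("M", seq_len(m)),
                                    chrom = chrom, pos = pos,
                                    ref = "A", alt = "B"))
}
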