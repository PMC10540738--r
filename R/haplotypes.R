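#' Two-locus linkage disequilibrium (D-prime and r-squared)
#'
#' Haplotype frequencies are estimated by expectation-maximization over the
#' phase-ambiguous double heterozygotes; `D = p_AB - p_A * p_B`,
#' `D' = D / Dmax` with the standard sign-dependent Dmax, and
#' `r2 = D^2 / (p_A p_a p_B p_b)`. Alleles are counted on the reference
#' strand (allele "A" = reference at each locus).
#'
#' @param x,y dosage vectors for the two markers (0/1/2, NA allowed)
#' @param tol EM convergence tolerance on the log-likelihood
#' @return list(dprime (absolute value), r2, D, freqs (pAB, pAb, paB, pab))
#' @export
dprime <- function(x, y, tol = 1e-6) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (!length(x) || stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("monomorphic marker: D' undefined")
  # haplotype counts on 2N chromosomes; cell (x, y) of the genotype table
  tab <- table(factor(x, levels = 0:2), factor(y, levels = 0:2))
  n <- sum(tab)
  # counts of unambiguous haplotypes (A = ref allele at each marker)
  # genotype pair (i, j): i alt copies at locus 1, j at locus 2
  hap <- c(AB = 0, Ab = 0, aB = 0, ab = 0)  # A/a = ref/alt at locus1; B/b locus2
  add <- function(h, k) hap[h] <<- hap[h] + k
  for (i in 0:2) for (j in 0:2) {
    k <- tab[i + 1, j + 1]
    if (!k) next
    if (i == 1 && j == 1) next  # double het: ambiguous
    # copies at locus1: (2 - i) ref, i alt; resolve per chromosome
    if (i == 0 && j == 0) add("AB", 2 * k)
    else if (i == 0 && j == 2) add("Ab", 2 * k)
    else if (i == 2 && j == 0) add("aB", 2 * k)
    else if (i == 2 && j == 2) add("ab", 2 * k)
    else if (i == 0 && j == 1) { add("AB", k); add("Ab", k) }
    else if (i == 2 && j == 1) { add("aB", k); add("ab", k) }
    else if (i == 1 && j == 0) { add("AB", k); add("aB", k) }
    else if (i == 1 && j == 2) { add("Ab", k); add("ab", k) }
  }
  ndh <- tab[2, 2]  # double heterozygotes contribute AB/ab or Ab/aB
  f <- rep(0.25, 4); names(f) <- names(hap)
  ll_old <- -Inf
  repeat {
    # E-step: split each double het between the two phase resolutions
    w_cis <- f["AB"] * f["ab"]
    w_trans <- f["Ab"] * f["aB"]
    tot <- w_cis + w_trans
    cis <- if (tot > 0) w_cis / tot else 0.5
    cnt <- hap
    cnt["AB"] <- cnt["AB"] + ndh * cis; cnt["ab"] <- cnt["ab"] + ndh * cis
    cnt["Ab"] <- cnt["Ab"] + ndh * (1 - cis); cnt["aB"] <- cnt["aB"] + ndh * (1 - cis)
    f <- cnt / (2 * n)
    ll <- sum(hap * log(pmax(f, 1e-300))) +
      ndh * log(max(2 * (f["AB"] * f["ab"] + f["Ab"] * f["aB"]), 1e-300))
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  pA <- f["AB"] + f["Ab"]; pB <- f["AB"] + f["aB"]
  D <- unname(f["AB"] - pA * pB)
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
  else min(pA * pB, (1 - pA) * (1 - pB))
  dp <- if (dmax == 0) 0 else abs(D / dmax)
  r2 <- if (pA %in% c(0, 1) || pB %in% c(0, 1)) 0 else
    D^2 / (pA * (1 - pA) * pB * (1 - pB))
  list(dprime = unname(min(dp, 1)), r2 = unname(r2), D = D,
       freqs = stats::setNames(as.vector(f), names(f)))
}

haploview_filters <- function(g, idx, maf_min = 0.001, hwe_p = 0.001,
                              missing_max = 0.75) {
  keep <- logical(length(idx))
  for (k in seq_along(idx)) {
    x <- g$codes[, idx[k]]
    miss <- mean(is.na(x))
    if (miss >= missing_max) next
    x <- x[!is.na(x)]
    p <- mean(x) / 2
    if (min(p, 1 - p) < maf_min) next
    if (hwe_exact_p(sum(x == 1), sum(x == 0), sum(x == 2)) < hwe_p) next
    keep[k] <- TRUE
  }
  idx[keep]
}

# exact Hardy-Weinberg test (small n) / chi-squared fallback
hwe_exact_p <- function(n_ab, n_aa, n_bb) {
  n <- n_ab + n_aa + n_bb
  if (n == 0) return(1)
  if (n <= 100) {
    n_a <- 2 * n_aa + n_ab
    n_b <- 2 * n_bb + n_ab
    rare <- min(n_a, n_b)
    hets <- seq(rare %% 2, rare, by = 2)
    logprob <- vapply(hets, function(h) {
      hom_r <- (rare - h) / 2
      hom_c <- n - h - hom_r
      lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) +
        h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) -
        lgamma(2 * n + 1)
    }, numeric(1))
    prob <- exp(logprob - max(logprob))
    prob <- prob / sum(prob)
    sum(prob[prob <= prob[hets == n_ab] + 1e-12])
  } else {
    p <- (2 * n_aa + n_ab) / (2 * n)
    e <- c(n * p^2, 2 * n * p * (1 - p), n * (1 - p)^2)
    o <- c(n_aa, n_ab, n_bb)
    if (any(e == 0)) return(1)
    stats::pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
  }
}

#' Solid-spine haplotype blocks
#'
#' Markers failing the Haploview-style filters (MAF < 0.001, Hardy-Weinberg
#' exact p < 0.001, missingness >= 75%) are excluded; a block is a maximal
#' run of consecutive markers in which the first and the last marker each
#' have D-prime at or above the threshold with every intermediate marker
#' (and with each other). Only pairs spaced under `max_span_bp` are eligible.
#' Non-overlapping blocks are reported left to right, preferring longer
#' blocks at equal starts.
#'
#' @param g a [genotype_matrix()]
#' @param markers marker ids (same chromosome, position order)
#' @param dprime_threshold spine D-prime threshold, default 0.8
#' @param max_span_bp pair spacing window, default 1 Mb
#' @param maf_min,hwe_p,missing_max marker exclusion filters (Haploview-style
#'   defaults). Note the exact Hardy-Weinberg filter at its default excludes
#'   fully inbred markers (an excess-homozygosity departure); set `hwe_p = 0`
#'   for inbred-line panels.
#' @return list of blocks: each list(markers, chrom, start, end)
#' @export
solid_spine_blocks <- function(g, markers, dprime_threshold = 0.8,
                               max_span_bp = 1e6, maf_min = 0.001,
                               hwe_p = 0.001, missing_max = 0.75) {
  idx <- match(markers, g$map$marker_id)
  if (anyNA(idx)) stop("unknown marker id")
  idx <- idx[order(g$map$pos[idx])]
  idx <- haploview_filters(g, idx, maf_min = maf_min, hwe_p = hwe_p,
                           missing_max = missing_max)
  if (length(idx) < 2L) stop("fewer than two markers after filtering")
  m <- length(idx)
  dp <- matrix(NA_real_, m, m)
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (g$map$pos[idx[j]] - g$map$pos[idx[i]] >= max_span_bp) { dp[i, j] <- 0; next }
    dp[i, j] <- dprime(g$codes[, idx[i]], g$codes[, idx[j]])$dprime
  }
  spine_ok <- function(i, j) {
    ks <- i:j
    all(dp[i, ks[-1]] >= dprime_threshold) &&
      all(dp[ks[-length(ks)], j] >= dprime_threshold)
  }
  blocks <- list()
  i <- 1L
  while (i < m) {
    best_j <- NA_integer_
    for (j in m:(i + 1L)) if (spine_ok(i, j)) { best_j <- j; break }
    if (is.na(best_j)) { i <- i + 1L; next }
    sel <- idx[i:best_j]
    blocks[[length(blocks) + 1L]] <- list(
      markers = g$map$marker_id[sel], chrom = g$map$chrom[sel[1]],
      start = min(g$map$pos[sel]), end = max(g$map$pos[sel]))
    i <- best_j + 1L
  }
  blocks
}

enumerate_diplotypes <- function(codes_row) {
  het <- which(codes_row == 1L)
  base1 <- base2 <- ifelse(codes_row == 2L, 1L, 0L)
  if (!length(het)) return(list(list(h1 = base1, h2 = base2)))
  if (length(het) > 12L) return(NULL)  # combinatorial guard
  n_conf <- 2L^(length(het) - 1L)
  out <- vector("list", n_conf)
  for (c_ in seq_len(n_conf) - 1L) {
    bits <- as.integer(intToBits(c_))[seq_len(max(length(het) - 1L, 1L))]
    a1 <- base1; a2 <- base2
    a1[het[1]] <- 1L; a2[het[1]] <- 0L  # fix first het to break symmetry
    if (length(het) > 1L) for (k in 2:length(het)) {
      a1[het[k]] <- bits[k - 1L]
      a2[het[k]] <- 1L - bits[k - 1L]
    }
    out[[c_ + 1L]] <- list(h1 = a1, h2 = a2)
  }
  out
}

hap_string <- function(alleles, ref, alt) {
  paste(ifelse(alleles == 0L, ref, alt), collapse = "")
}

#' Assign block haplotypes to accessions
#'
#' Accessions homozygous at every block marker carry two copies of a single
#' haplotype; accessions heterozygous at exactly one marker carry one copy
#' of each resolved haplotype; multi-heterozygous accessions are resolved by
#' the EM-estimated haplotype frequencies and assigned only when the best
#' diplotype's posterior exceeds `posterior_min` (otherwise left
#' unassigned). Accessions with a missing call in the block are unassigned.
#'
#' @param g a [genotype_matrix()]
#' @param block a block from [solid_spine_blocks()] (or a list with a
#'   `markers` element)
#' @param posterior_min EM posterior needed to phase a multi-het accession
#' @param max_iter,tol EM controls
#' @return list(assignments = data.frame(accession, haplotype, copies),
#'   frequencies = named haplotype frequencies over assigned chromosomes,
#'   classes = major/minor/rare labels, unassigned = accession ids)
#' @export
assign_haplotypes <- function(g, block, posterior_min = 0.9, max_iter = 200L,
                              tol = 1e-6) {
  idx <- match(block$markers, g$map$marker_id)
  X <- g$codes[, idx, drop = FALSE]
  ref <- g$map$ref[idx]; alt <- g$map$alt[idx]
  n <- nrow(X)
  diplos <- vector("list", n)
  for (i in seq_len(n)) {
    if (anyNA(X[i, ])) next
    diplos[[i]] <- enumerate_diplotypes(X[i, ])
  }
  # collect haplotype universe
  hap_of <- function(a) hap_string(a, ref, alt)
  universe <- unique(unlist(lapply(diplos, function(dl)
    if (is.null(dl)) NULL else unlist(lapply(dl, function(d)
      c(hap_of(d$h1), hap_of(d$h2)))))))
  if (!length(universe)) stop("no assignable accession in block")
  f <- stats::setNames(rep(1 / length(universe), length(universe)), universe)
  resolved <- lapply(diplos, function(dl) {
    if (is.null(dl)) return(NULL)
    lapply(dl, function(d) c(hap_of(d$h1), hap_of(d$h2)))
  })
  for (it in seq_len(max_iter)) {
    cnt <- stats::setNames(rep(1e-12, length(universe)), universe)
    ll <- 0
    for (i in seq_len(n)) {
      dl <- resolved[[i]]
      if (is.null(dl)) next
      w <- vapply(dl, function(h) {
        pr <- f[h[1]] * f[h[2]]
        if (h[1] != h[2]) pr <- 2 * pr
        pr
      }, numeric(1))
      tw <- sum(w)
      if (tw <= 0) { w <- rep(1 / length(w), length(w)); tw <- 1 }
      ll <- ll + log(tw)
      w <- w / tw
      for (k in seq_along(dl)) {
        cnt[dl[[k]][1]] <- cnt[dl[[k]][1]] + w[k]
        cnt[dl[[k]][2]] <- cnt[dl[[k]][2]] + w[k]
      }
    }
    f_new <- cnt / sum(cnt)
    if (it > 1 && abs(ll - ll_old) < tol) { f <- f_new; break }
    ll_old <- ll
    f <- f_new
  }
  assign_rows <- list(); unassigned <- character(0)
  for (i in seq_len(n)) {
    accn <- rownames(X)[i]
    dl <- resolved[[i]]
    if (is.null(dl)) { unassigned <- c(unassigned, accn); next }
    if (length(dl) == 1L) {
      h <- dl[[1]]
    } else {
      w <- vapply(dl, function(h) {
        pr <- f[h[1]] * f[h[2]]; if (h[1] != h[2]) pr <- 2 * pr; pr
      }, numeric(1))
      w <- w / sum(w)
      if (max(w) <= posterior_min) { unassigned <- c(unassigned, accn); next }
      h <- dl[[which.max(w)]]
    }
    tab <- table(h)
    for (hs in names(tab))
      assign_rows[[length(assign_rows) + 1L]] <- data.frame(
        accession = accn, haplotype = hs, copies = as.integer(tab[[hs]]),
        stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, assign_rows)
  counts <- tapply(assignments$copies, assignments$haplotype, sum)
  freqs <- counts / sum(counts)
  classes <- ifelse(freqs > 0.10, "major", ifelse(freqs < 0.01, "rare", "minor"))
  list(assignments = assignments,
       frequencies = stats::setNames(as.vector(freqs), names(freqs)),
       classes = stats::setNames(as.vector(classes), names(freqs)),
       unassigned = unassigned)
}

#' Haplotype frequencies per collection
#' @param assignment an [assign_haplotypes()] result
#' @param collections named factor/character of collection labels per
#'   accession
#' @return matrix haplotype x collection of frequencies (copies over twice
#'   the collection size; unassigned mass makes columns sum to <= 1)
#' @export
haplotype_frequencies <- function(assignment, collections) {
  a <- assignment$assignments
  a$collection <- collections[a$accession]
  haps <- sort(unique(a$haplotype))
  cols <- sort(unique(collections))
  out <- matrix(0, length(haps), length(cols), dimnames = list(haps, cols))
  for (cl in cols) {
    n_cl <- sum(collections == cl)
    sub <- a[a$collection == cl, ]
    cnt <- tapply(sub$copies, sub$haplotype, sum)
    out[names(cnt), cl] <- cnt / (2 * n_cl)
  }
  out
}

compact_letters <- function(pmat, alpha = 0.05) {
  # insert-and-absorb compact letter display from a symmetric p-value matrix
  lv <- rownames(pmat)
  groups <- list()
  for (g_ in lv) {
    placed <- FALSE
    for (k in seq_along(groups)) {
      if (all(pmat[g_, groups[[k]]] >= alpha)) {
        groups[[k]] <- c(groups[[k]], g_); placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1L]] <- g_
  }
  letters_out <- stats::setNames(rep("", length(lv)), lv)
  for (k in seq_along(groups))
    for (g_ in groups[[k]])
      letters_out[g_] <- paste0(letters_out[g_], letters[k])
  letters_out
}

#' Haplotype-trait association for a quantitative trait
#'
#' Two-way ANOVA `Y = mu + H + C + HxC + eps` of presence (1 or 2 copies)
#' versus absence ("X") of one haplotype across collections, with Tukey HSD
#' cell comparisons and per-cell means and SDs.
#'
#' @param trait_values named per-accession trait values
#' @param assignment an [assign_haplotypes()] result
#' @param haplotype haplotype string to test
#' @param collections named collection labels per accession
#' @return list(anova = data.frame(term, df, f, p), cells (mean/sd/n per
#'   haplotype x collection cell), tukey (letters), skipped)
#' @export
haplotype_anova <- function(trait_values, assignment, haplotype, collections) {
  a <- assignment$assignments
  carriers <- unique(a$accession[a$haplotype == haplotype & a$copies > 0])
  assigned <- unique(a$accession)
  acc <- intersect(assigned, names(trait_values))
  acc <- acc[!is.na(trait_values[acc])]
  d <- data.frame(y = trait_values[acc],
                  h = factor(ifelse(acc %in% carriers, haplotype, "X"),
                             levels = c(haplotype, "X")),
                  c = factor(collections[acc]))
  keep_cells <- table(d$h, d$c)
  skipped <- sum(keep_cells < 2L)
  fit <- stats::aov(y ~ h * c, data = d)
  atab <- summary(fit)[[1]]
  rn <- trimws(rownames(atab))
  an <- data.frame(term = c("haplotype", "collection", "interaction"),
                   df = atab[match(c("h", "c", "h:c"), rn), "Df"],
                   f = atab[match(c("h", "c", "h:c"), rn), "F value"],
                   p = atab[match(c("h", "c", "h:c"), rn), "Pr(>F)"])
  cells <- stats::aggregate(y ~ h + c, data = d, FUN = function(v)
    c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  cells <- cbind(cells[c("h", "c")], as.data.frame(cells$y))
  tk <- stats::TukeyHSD(stats::aov(y ~ interaction(h, c), data = d))[[1]]
  lv <- levels(interaction(d$h, d$c))
  pmat <- matrix(1, length(lv), length(lv), dimnames = list(lv, lv))
  for (r in rownames(tk)) {
    pair <- strsplit(r, "-", fixed = TRUE)[[1]]
    if (length(pair) == 2L && all(pair %in% lv))
      pmat[pair[1], pair[2]] <- pmat[pair[2], pair[1]] <- tk[r, "p adj"]
  }
  list(anova = an, cells = cells, tukey = compact_letters(pmat),
       tukey_p = pmat, skipped = skipped)
}

#' Haplotype-trait association for a qualitative trait
#'
#' Chi-squared independence test of the presence x category table with
#' standardized Pearson residuals
#' `d_ij = (O - E) / sqrt(E (1 - p_row)(1 - p_col))` (|d| > 2 flags ~p<0.05,
#' |d| > 4 flags ~p<0.001), Bonferroni-adjusted pairwise category
#' comparisons, and a Fisher exact fallback when an expected count is zero.
#'
#' @param categories named per-accession category values
#' @param assignment an [assign_haplotypes()] result
#' @param haplotype haplotype string to test
#' @return list(chisq_p, residuals (standardized Pearson), table,
#'   pairwise (Bonferroni-adjusted), exact_fallback)
#' @export
haplotype_chisq <- function(categories, assignment, haplotype) {
  a <- assignment$assignments
  carriers <- unique(a$accession[a$haplotype == haplotype & a$copies > 0])
  assigned <- unique(a$accession)
  acc <- intersect(assigned, names(categories))
  acc <- acc[!is.na(categories[acc])]
  pres <- factor(ifelse(acc %in% carriers, haplotype, "X"),
                 levels = c(haplotype, "X"))
  cat_f <- factor(categories[acc])
  if (nlevels(cat_f) < 2L)
    return(list(chisq_p = NA_real_, residuals = NULL, table = table(pres, cat_f),
                pairwise = NULL, exact_fallback = FALSE,
                note = "single observed category: test undefined"))
  tab <- table(pres, cat_f)
  exp_cnt <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  exact <- any(exp_cnt == 0)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  p <- if (exact) stats::fisher.test(tab, simulate.p.value = TRUE,
                                     B = 2000)$p.value else ct$p.value
  pw <- NULL
  if (nlevels(cat_f) > 2L) {
    lv <- levels(cat_f)
    pairs <- utils::combn(lv, 2, simplify = FALSE)
    praw <- vapply(pairs, function(pr) {
      sub <- tab[, pr, drop = FALSE]
      suppressWarnings(stats::chisq.test(sub, correct = FALSE)$p.value)
    }, numeric(1))
    pw <- data.frame(a = vapply(pairs, `[`, character(1), 1),
                     b = vapply(pairs, `[`, character(1), 2),
                     p_adj = pmin(1, praw * length(praw)))
  }
  list(chisq_p = p, residuals = ct$stdres, table = tab, pairwise = pw,
       exact_fallback = exact)
}
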