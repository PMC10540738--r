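test_that("D-prime: complete association, counting oracle, independence", {
  # only AB and ab haplotypes present (phase-known, all homozygous)
  x <- rep(c(0L, 2L), c(30, 20)); y <- rep(c(0L, 2L), c(30, 20))
  res <- dprime(x, y)
  expect_equal(res$dprime, 1, tolerance = 1e-9)
  expect_equal(res$r2, 1, tolerance = 1e-9)
  # phase-known homozygous fixture: EM equals direct counting
  set.seed(501)
  for (i in 1:5) {
    x2 <- sample(c(0L, 2L), 120, replace = TRUE, prob = c(0.6, 0.4))
    flip <- runif(120) < 0.3
    y2 <- ifelse(flip, sample(c(0L, 2L), 120, replace = TRUE), x2)
    o <- oracle_counting_ld(x2, y2)
    r <- dprime(x2, y2)
    expect_equal(r$dprime, o$dprime, tolerance = 1e-6)
    expect_equal(r$r2, o$r2, tolerance = 1e-6)
  }
  # independent markers at large n: D' near zero
  set.seed(502)
  x3 <- sample(c(0L, 2L), 4000, replace = TRUE)
  y3 <- sample(c(0L, 2L), 4000, replace = TRUE)
  expect_lt(dprime(x3, y3)$dprime, 0.1)
  expect_error(dprime(rep(0L, 10), x3[1:10]), "monomorphic")
})

test_that("D-prime EM resolves double heterozygotes sensibly", {
  # strong coupling with some double hets: D' should stay near 1
  set.seed(503)
  hapA <- rbinom(200, 1, 0.4)
  h1 <- hapA; h2 <- rbinom(200, 1, 1) * hapA  # second chromosome copies
  h2 <- rbinom(200, 1, 0.5)  # random second gamete from the same pool
  x <- (hapA + h2); y <- (hapA + h2)  # perfectly coupled diploids incl. hets
  x <- as.integer(x); y <- as.integer(y)
  res <- dprime(x, y)
  expect_gt(res$dprime, 0.95)
})

test_that("solid-spine blocks: complete LD, spine breaks, exhaustive oracle", {
  set.seed(504)
  base <- sample(c(0L, 2L), 100, replace = TRUE)
  perturb <- function(v, k) { i <- sample(100, k); v[i] <- 2L - v[i]; v }
  # three markers in complete pairwise LD -> one block of 3
  g3 <- fixture_genotypes(cbind(base, base, base), pos = c(1e5, 2e5, 3e5))
  b3 <- solid_spine_blocks(g3, paste0("M", 1:3), hwe_p = 0)
  expect_length(b3, 1L)
  expect_equal(b3[[1]]$markers, paste0("M", 1:3))
  # a D' = 0 middle pair splits the block
  indep <- sample(c(0L, 2L), 100, replace = TRUE)
  g_split <- fixture_genotypes(cbind(base, perturb(base, 3), indep,
                                     perturb(indep, 3)),
                               pos = c(1e5, 2e5, 3e5, 4e5))
  bs <- solid_spine_blocks(g_split, paste0("M", 1:4), hwe_p = 0)
  expect_true(all(vapply(bs, function(b) length(b$markers), integer(1)) <= 2))
  # 10-marker fixture equals the exhaustive oracle over contiguous runs
  cols <- list(base)
  for (k in 2:10) cols[[k]] <- if (k %in% c(4, 8))
    sample(c(0L, 2L), 100, replace = TRUE) else perturb(cols[[k - 1]], 2)
  G10 <- do.call(cbind, cols)
  g10 <- fixture_genotypes(G10, pos = seq(1e5, by = 1e5, length.out = 10))
  blocks <- solid_spine_blocks(g10, paste0("M", 1:10), hwe_p = 0)
  dp <- matrix(NA_real_, 10, 10)
  for (i in 1:9) for (j in (i + 1):10)
    dp[i, j] <- dprime(G10[, i], G10[, j])$dprime
  oracle <- oracle_spine_blocks(dp, 0.8)
  expect_equal(lapply(blocks, function(b) match(b$markers, paste0("M", 1:10))),
               oracle)
  expect_error(solid_spine_blocks(g3, "M1"), "unknown marker|fewer than two")
})

test_that("haplotype assignment: homozygous, single-het, frequency classes", {
  codes <- rbind(
    h1 = c(0L, 0L, 0L),   # AAA x2
    h2 = c(2L, 2L, 2L),   # BBB x2
    h3 = c(0L, 1L, 0L),   # single het: AAA + ABA
    h4 = c(0L, 0L, 0L),
    h5 = c(0L, 0L, 0L),
    h6 = c(NA, 0L, 0L))   # missing call: unassigned
  g <- fixture_genotypes(codes, pos = c(1e5, 1.5e5, 2e5))
  block <- list(markers = paste0("M", 1:3))
  res <- assign_haplotypes(g, block)
  a1 <- res$assignments[res$assignments$accession == "h1", ]
  expect_equal(a1$haplotype, "AAA"); expect_equal(a1$copies, 2L)
  a3 <- res$assignments[res$assignments$accession == "h3", ]
  expect_setequal(a3$haplotype, c("AAA", "ABA"))
  expect_true(all(a3$copies == 1L))
  expect_equal(res$unassigned, "h6")
  expect_equal(sum(res$frequencies), 1)
  expect_equal(unname(res$classes["AAA"]), "major")
  freqs <- haplotype_frequencies(res, setNames(rep(c("TCC", "REF"), 3),
                                               rownames(codes)))
  expect_true(all(colSums(freqs) <= 1 + 1e-12))
})

test_that("multi-het accessions phase by EM when the posterior is decisive", {
  # population dominated by AAA / BBB: a double het is almost surely AAA+BBB
  codes <- rbind(matrix(rep(c(0L, 0L, 0L), 40), 40, 3, byrow = TRUE),
                 matrix(rep(c(2L, 2L, 2L), 40), 40, 3, byrow = TRUE),
                 c(1L, 1L, 1L))
  rownames(codes) <- sprintf("a%02d", 1:81)
  g <- fixture_genotypes(codes, pos = c(1e5, 2e5, 3e5))
  res <- assign_haplotypes(g, list(markers = paste0("M", 1:3)))
  het <- res$assignments[res$assignments$accession == "a81", ]
  expect_setequal(het$haplotype, c("AAA", "BBB"))
})

test_that("phased-truth simulation: assignment accuracy above 95%", {
  set.seed(505)
  n <- 120; m <- 4
  hap_pool <- rbind(c(0, 0, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(1, 1, 1, 1))
  acc_h1 <- hap_pool[sample(4, n, TRUE, prob = c(0.4, 0.3, 0.2, 0.1)), ]
  # inbred-like: second gamete copies the first except 5% outcrossing
  out <- runif(n) < 0.05
  acc_h2 <- acc_h1
  acc_h2[out, ] <- hap_pool[sample(4, sum(out), TRUE), ]
  codes <- acc_h1 + acc_h2
  storage.mode(codes) <- "integer"
  rownames(codes) <- sprintf("a%03d", 1:n)
  g <- fixture_genotypes(codes, pos = seq(1e5, by = 5e4, length.out = m))
  res <- assign_haplotypes(g, list(markers = paste0("M", 1:m)))
  to_str <- function(h) paste(ifelse(h == 0, "A", "B"), collapse = "")
  truth <- lapply(1:n, function(i) sort(c(to_str(acc_h1[i, ]), to_str(acc_h2[i, ]))))
  correct <- vapply(seq_len(n), function(i) {
    acc <- sprintf("a%03d", i)
    if (acc %in% res$unassigned) return(NA)
    got <- res$assignments[res$assignments$accession == acc, ]
    setequal(rep(got$haplotype, got$copies), truth[[i]]) ||
      identical(sort(rep(got$haplotype, got$copies)), truth[[i]])
  }, logical(1))
  expect_gt(mean(correct, na.rm = TRUE), 0.95)
})

test_that("haplotype ANOVA: null behaviour and planted effect", {
  set.seed(506)
  n <- 160
  codes <- rbind(matrix(0L, n / 2, 3), matrix(2L, n / 2, 3))
  rownames(codes) <- sprintf("a%03d", 1:n)
  g <- fixture_genotypes(codes, pos = c(1e5, 2e5, 3e5))
  res <- assign_haplotypes(g, list(markers = paste0("M", 1:3)))
  coll <- setNames(rep(c("TCC", "FULL"), n / 2), rownames(codes))
  # null: identical distributions -> haplotype term not significant
  y0 <- setNames(rnorm(n), rownames(codes))
  an0 <- haplotype_anova(y0, res, "BBB", coll)
  expect_gt(an0$anova$p[an0$anova$term == "haplotype"], 0.01)
  # planted +1 SD effect of the BBB haplotype
  carrier <- rownames(codes)[codes[, 1] == 2L]
  y1 <- y0; y1[carrier] <- y1[carrier] + 1
  an1 <- haplotype_anova(y1, res, "BBB", coll)
  expect_lt(an1$anova$p[an1$anova$term == "haplotype"], 1e-6)
  cells <- an1$cells
  expect_gt(mean(cells$mean[cells$h == "BBB"]), mean(cells$mean[cells$h == "X"]))
  # Tukey letters separate carrier and non-carrier cells for clear effects
  expect_true(length(unique(an1$tukey)) > 1)
})

test_that("haplotype chi-squared matches hand computation and flags residuals", {
  tab <- matrix(c(10, 50, 50, 10), 2, byrow = TRUE,
                dimnames = list(c("H", "X"), c("none", "severe")))
  # reconstruct accession-level data giving exactly this table
  n <- sum(tab)
  codes <- rbind(matrix(0L, 60, 2), matrix(2L, 60, 2))
  rownames(codes) <- sprintf("a%03d", 1:120)
  g <- fixture_genotypes(codes, pos = c(1e5, 2e5))
  res <- assign_haplotypes(g, list(markers = c("M1", "M2")))
  cats <- setNames(c(rep(c("none", "severe"), c(50, 10)),
                     rep(c("none", "severe"), c(10, 50))), rownames(codes))
  hc <- haplotype_chisq(cats, res, "BB")
  manual <- chisq.test(tab, correct = FALSE)
  expect_equal(hc$chisq_p, manual$p.value, tolerance = 1e-12)
  expect_equal(unname(hc$residuals), unname(manual$stdres), tolerance = 1e-12)
  expect_true(all(abs(hc$residuals) > 4))  # strong enrichment
  # all accessions in one category: undefined test
  hc1 <- haplotype_chisq(setNames(rep("none", 120), rownames(codes)), res, "BB")
  expect_true(is.na(hc1$chisq_p))
})

test_that("downstream chi-squared detects a planted latent haplotype effect", {
  hits <- vapply(1:10, function(s) {
    sc <- scenario_spec(n_accessions = 200, n_snps = 12, n_chromosomes = 2,
                        sigma2_g = 0.5, sigma2_e = 0.2, sigma2_eps = 0.5,
                        het_rate = 0, missing_rate = 0, seed = 600 + s,
                        maf_range = c(0.3, 0.5),
                        qtls = list(planted_qtl(3, "Q1", a = 1)))
    g <- gen_genotypes(sc)
    q <- gen_qualitative_trait(g, sc, name = "Q1",
                               categories = c("low", "high"))
    cats <- setNames(q$met$value[q$met$environment == "E1"],
                     q$met$accession[q$met$environment == "E1"])
    res <- assign_haplotypes(g, list(markers = g$map$marker_id[3]))
    hc <- haplotype_chisq(cats, res, "B")
    !is.na(hc$chisq_p) && hc$chisq_p < 0.05
  }, logical(1))
  expect_gt(mean(hits), 0.8)
})
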