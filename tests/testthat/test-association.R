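test_that("filter rules, order of application, and boundaries", {
  # 10 accessions x 6 markers, one deliberate violation of each rule
  codes <- matrix(0L, 10, 6)
  codes[, 1] <- rep(c(0L, 2L), 5)                      # fine, MAF 0.5
  codes[, 2] <- c(rep(2L, 5), rep(0L, 5))              # fine, MAF 0.5
  codes[1, ] <- NA_integer_                            # accession 1: all missing
  codes[2:4, 3] <- NA_integer_                         # marker 3: 3/9 > 25% missing
  codes[, 4] <- c(2L, rep(0L, 9))                      # marker 4: monomorphic after row-1 drop
  codes[, 5] <- c(NA, 1L, 1L, rep(0L, 4), rep(2L, 3))  # marker 5: 2/9 het
  codes[, 6] <- c(NA, rep(c(0L, 2L), 4), 0L)           # fine
  g <- fixture_genotypes(codes)
  res <- filter_snps(g, run_config())
  expect_equal(res$report$removed, c(1L, 1L, 1L, 1L))
  expect_setequal(colnames(res$genotypes$codes), c("M1", "M2", "M6"))
  # MAF exactly at the boundary is retained
  codes_b <- cbind(rep(c(0L, 2L), c(19, 1)), rep(c(0L, 2L), 10))
  gb <- fixture_genotypes(codes_b)
  resb <- filter_snps(gb, run_config())  # marker 1 MAF = 0.05: kept
  expect_equal(ncol(resb$genotypes$codes), 2L)
  expect_error(filter_snps(gb, run_config(maf_min = 0.99)), "no markers")
})

test_that("IBS kinship: exact values and brute-force oracle", {
  codes <- rbind(a = c(0L, 0L, 2L, 2L, 1L, 0L, 2L, 1L),
                 b = c(0L, 0L, 2L, 2L, 1L, 0L, 2L, 1L),
                 c = c(2L, 2L, 0L, 0L, 1L, 2L, 0L, 1L),
                 d = c(0L, 1L, 2L, NA, 0L, 2L, 1L, 0L),
                 e = c(NA, NA, 0L, 0L, 2L, 2L, 0L, 1L))
  g <- fixture_genotypes(codes)
  K <- kinship(g, "ibs_emma")
  expect_equal(K["a", "b"], 1)  # identical accessions
  opp <- fixture_genotypes(rbind(x = rep(0L, 4), y = rep(2L, 4)))
  expect_equal(kinship(opp)["x", "y"], 0)  # opposite homozygotes
  expect_equal(unname(K), oracle_ibs_kinship(codes), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(isSymmetric(K))
  expect_true(all(diag(K) == 1))
  # centered variant is symmetric and mean-centered-ish
  Kc <- kinship(g, "centered_ibs")
  expect_true(isSymmetric(Kc))
})

test_that("lmm_scan equals OLS when kinship is the identity", {
  set.seed(201)
  n <- 60
  codes <- matrix(sample(0:2, n * 12, replace = TRUE, prob = c(0.45, 0.1, 0.45)),
                  n, 12)
  g <- fixture_genotypes(codes)
  K <- diag(n)
  dimnames(K) <- list(rownames(g$codes), rownames(g$codes))
  y <- setNames(rnorm(n), rownames(g$codes))
  y[5] <- y[5] + 3
  res <- lmm_scan(y, g, K, method = "exact")
  for (m in seq_len(12)) {
    ols <- summary(lm(y ~ codes[, m]))$coefficients
    expect_equal(res$p[res$marker == paste0("M", m)], ols[2, 4],
                 tolerance = 1e-8)
    expect_equal(res$beta[res$marker == paste0("M", m)], ols[2, 1],
                 tolerance = 1e-8)
  }
})

test_that("lmm_scan p-values are invariant to affine transformation of y", {
  set.seed(202)
  sc <- scenario_spec(n_accessions = 60, n_snps = 40, n_chromosomes = 2,
                      seed = 17)
  g <- gen_genotypes(sc)
  flt <- filter_snps(g)
  K <- kinship(flt$genotypes)
  y <- setNames(rnorm(60), rownames(g$codes))
  r1 <- lmm_scan(y, flt$genotypes, K, method = "exact")
  r2 <- lmm_scan(3 * y - 7, flt$genotypes, K, method = "exact")
  expect_equal(r2$p, r1$p, tolerance = 1e-6)
  expect_equal(r2$beta, 3 * r1$beta, tolerance = 1e-6)
  # duplicated marker does not perturb other markers
  g2 <- flt$genotypes
  codes2 <- cbind(g2$codes, dup = g2$codes[, 1])
  map2 <- rbind(g2$map, data.frame(marker_id = "dup", chrom = "chr99",
                                   pos = 1L, ref = "A", alt = "B",
                                   block = "z"))
  colnames(codes2)[ncol(codes2)] <- "dup"
  g3 <- genotype_matrix(codes2, map2)
  r3 <- lmm_scan(y, g3, K, method = "exact")
  expect_equal(r3$p[r3$marker != "dup"], r1$p, tolerance = 1e-10)
})

test_that("kinship correction controls structure-driven inflation", {
  sc <- scenario_spec(n_accessions = 150, n_snps = 250, n_chromosomes = 3,
                      structure = list(prop = 0.5, shift = 0.25), seed = 23,
                      missing_rate = 0)
  g <- gen_genotypes(sc)
  flt <- filter_snps(g)
  K <- kinship(flt$genotypes)
  # response driven by the subpopulation label only
  set.seed(24)
  subpop <- attr(g, "subpop")
  y <- setNames(1.5 * subpop + rnorm(150), rownames(g$codes))
  mm <- lmm_scan(y, flt$genotypes, K, method = "approx")
  Kid <- diag(150); dimnames(Kid) <- list(names(y), names(y))
  ols <- lmm_scan(y, flt$genotypes, Kid, method = "approx")
  expect_lt(genomic_inflation(mm$p), genomic_inflation(ols$p))
  expect_gt(genomic_inflation(ols$p), 1.3)
  expect_lt(genomic_inflation(mm$p), 1.15)
})

test_that("two-stage GWEIS: identifiability, power and negative control", {
  # planted conditional-neutral QTL: effect only in E1
  sc <- scenario_spec(n_accessions = 150, n_snps = 60, n_chromosomes = 2,
                      sigma2_g = 1, sigma2_e = 1, sigma2_ge = 0.5,
                      sigma2_eps = 0.5, missing_rate = 0, seed = 31,
                      maf_range = c(0.2, 0.5),
                      qtls = list(planted_qtl(10, "T1", a = 1,
                                              env_multipliers = c(1, 0, 0, 0))))
  g <- gen_genotypes(sc)
  sim <- gen_met_phenotypes(g, sc)
  flt <- filter_snps(g)
  K <- kinship(flt$genotypes)
  gw <- gweis_two_stage(sim$met, "T1", flt$genotypes, K, method = "approx")
  # balanced data: per-accession interaction effects sum to zero
  expect_lt(max(abs(rowSums(gw$stage1$ge_matrix))), 1e-8)
  # with a study-scale panel the Meff cutoff sits near the canonical 1e-5
  # MTA threshold; the toy panel here is small, so use that threshold directly
  p_e1 <- gw$gei_scans$E1$p[gw$gei_scans$E1$marker == "S00010"]
  expect_lt(p_e1, 1e-5)
  others <- vapply(gw$gei_scans[c("E2", "E3", "E4")], function(s)
    s$p[s$marker == "S00010"], numeric(1))
  expect_true(all(others > 1e-5))
  # sum-to-zero decomposition: the focal-environment effect is ~3x the
  # (opposite-signed) spillover effects in the silent environments
  b_e1 <- gw$gei_scans$E1$beta[gw$gei_scans$E1$marker == "S00010"]
  b_oth <- vapply(gw$gei_scans[c("E2", "E3", "E4")], function(s)
    s$beta[s$marker == "S00010"], numeric(1))
  expect_equal(unname(b_oth / b_e1), rep(-1 / 3, 3), tolerance = 0.25)
})

test_that("Li-Ji Meff: limits and eigen oracle", {
  # exactly orthogonal fixture built from a Hadamard design: Meff = M
  H2 <- matrix(c(1, 1, 1, -1), 2)
  H8 <- kronecker(H2, kronecker(H2, H2))
  codes <- (H8[, 2:8] + 1)  # drop the constant column; values in {0, 2}
  storage.mode(codes) <- "integer"
  g <- fixture_genotypes(codes)
  thr <- significance_threshold(g)
  expect_equal(thr$meff, 7, tolerance = 1e-8)
  # every marker duplicated: Meff = M / 2 (perfect redundancy)
  codes2 <- codes[, rep(1:7, each = 2)]
  g2 <- fixture_genotypes(codes2)
  thr2 <- significance_threshold(g2)
  expect_equal(thr2$meff, 7, tolerance = 1e-8)
  # single marker: Meff 1, cutoff alpha
  g1 <- fixture_genotypes(codes[, 1, drop = FALSE])
  thr1 <- significance_threshold(g1, alpha = 0.05)
  expect_equal(thr1$meff, 1)
  expect_equal(thr1$cutoff, 0.05)
  # LD fixture against the oracle
  sc <- scenario_spec(n_accessions = 100, n_snps = 50, n_chromosomes = 2,
                      ld_r2 = 0.7, seed = 41)
  gl <- gen_genotypes(sc)
  thr_l <- significance_threshold(gl)
  expect_equal(thr_l$meff, oracle_meff(gl$codes, gl$map$chrom),
               tolerance = 1e-8)
  expect_equal(thr_l$cutoff, 1 - 0.95^(1 / thr_l$meff), tolerance = 1e-12)
  expect_equal(significance_threshold(gl, bonferroni = TRUE)$cutoff,
               0.05 / thr_l$meff)
})

test_that("detection power increases with planted effect size", {
  min_p <- sapply(c(0.25, 0.5, 1), function(a) {
    ps <- sapply(1:3, function(s) {
      sc <- scenario_spec(n_accessions = 120, n_snps = 40, n_chromosomes = 2,
                          sigma2_g = 0.5, sigma2_e = 0.5, sigma2_ge = 0.25,
                          sigma2_eps = 1, missing_rate = 0,
                          maf_range = c(0.3, 0.5), seed = 50 + s,
                          qtls = list(planted_qtl(7, "T1", a = a)))
      g <- gen_genotypes(sc)
      sim <- gen_met_phenotypes(g, sc)
      flt <- filter_snps(g)
      K <- kinship(flt$genotypes)
      gw <- gweis_two_stage(sim$met, "T1", flt$genotypes, K, method = "approx")
      gw$mean_scan$p[gw$mean_scan$marker == "S00007"]
    })
    mean(-log10(ps))
  })
  expect_true(all(diff(min_p) > 0))
})
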