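test_that("prefilter: ordered rules and complete major-allele imputation", {
  set.seed(601)
  codes <- matrix(sample(c(0L, 2L), 20 * 40, replace = TRUE), 20, 40)
  codes[1, 1:15] <- NA_integer_          # accession 1: 37.5% missing -> removed
  codes[3:8, 2] <- NA_integer_           # marker 2 (after acc drop): >10% missing
  g <- fixture_genotypes(codes, chrom = rep(c("chr01", "chr02"), each = 20),
                         pos = rep(seq(1e5, by = 1e5, length.out = 20), 2))
  res <- prefilter_and_sample(g, marker_fraction = 0.5, seed = 5)
  expect_false("ACC001" %in% rownames(res$codes))
  expect_false("M2" %in% colnames(res$codes))
  expect_false(anyNA(res$codes))
  expect_equal(ncol(res$codes), round(0.5 * 39))
  # deterministic subsample under the seed
  res2 <- prefilter_and_sample(g, marker_fraction = 0.5, seed = 5)
  expect_identical(res$codes, res2$codes)
})

test_that("pi and MAF: counting identities and limits", {
  # two accessions differing at one site: pi = 1 with the n/(n-1) correction
  g <- fixture_genotypes(rbind(c(0L, 0L), c(2L, 0L)), pos = c(1e5, 2e5))
  prof <- diversity_profile(g, mds_axes = 1)
  expect_equal(unname(prof$pi["M1"]), 1)
  expect_equal(unname(prof$pi["M2"]), 0)
  expect_equal(unname(prof$maf["M1"]), 0.5)
  # p = 0.5 at large n: pi -> 0.5
  set.seed(602)
  big <- fixture_genotypes(matrix(rep(c(0L, 2L), 500), 1000, 1), pos = 1e5)
  expect_equal(unname(diversity_profile(big, mds_axes = 1)$pi[1]),
               0.5 * 1000 / 999, tolerance = 1e-9)
})

test_that("MDS preserves equidistance and density bins count markers", {
  # three mutually equidistant accessions -> equilateral triangle
  codes <- rbind(a = c(2L, 0L, 0L),
                 b = c(0L, 2L, 0L),
                 c = c(0L, 0L, 2L))
  g <- fixture_genotypes(codes)
  K <- kinship(g)
  expect_equal(length(unique(round(K[upper.tri(K)], 10))), 1L)
  prof <- diversity_profile(g, mds_axes = 2)
  d <- dist(prof$mds)
  expect_equal(max(d) - min(d), 0, tolerance = 1e-8)
  expect_equal(sum(prof$density$n_snps), 3L)
})

test_that("maximin genetic sub-core: farthest first, beats random subsets", {
  sc <- scenario_spec(n_accessions = 60, n_snps = 80, n_chromosomes = 2,
                      missing_rate = 0, seed = 603)
  g <- gen_genotypes(sc)
  coords <- pcoa_coords(g, 3)
  # an accession far from everyone is always picked first
  far <- metqtl:::farthest_point_sample(coords, 5)
  centroid <- colMeans(coords)
  d_cent <- sqrt(rowSums(sweep(coords, 2, centroid)^2))
  expect_equal(far[1], rownames(coords)[which.max(d_cent)])
  # minimum pairwise distance dominates random subsets of equal size
  min_d <- function(ids) min(dist(coords[ids, ]))
  md_core <- min_d(metqtl:::farthest_point_sample(coords, 10))
  set.seed(604)
  beats <- mean(replicate(40, md_core >= min_d(sample(rownames(coords), 10))))
  expect_gte(beats, 0.95)
})

test_that("select_core: structure coverage, determinism, phenotypic tails", {
  sc <- scenario_spec(n_accessions = 90, n_snps = 60, n_chromosomes = 2,
                      structure = list(prop = 0.5, shift = 0.3),
                      missing_rate = 0, seed = 605)
  g <- gen_genotypes(sc)
  subpop <- attr(g, "subpop")
  quant <- list(FW = setNames(rnorm(90), rownames(g$codes)))
  qual <- list(SHAPE = setNames(sample(c("round", "flat", "long"), 90, TRUE),
                                rownames(g$codes)))
  geo <- setNames(sample(paste0("prov", 1:6), 90, TRUE), rownames(g$codes))
  sel <- select_core(g, quant, qual, geo, fraction = 0.3, seed = 9)
  sel2 <- select_core(g, quant, qual, geo, fraction = 0.3, seed = 9)
  expect_identical(sel$selected, sel2$selected)
  expect_false(anyDuplicated(sel$selected) > 0)
  # both planted subpopulations are represented in the genetic sub-core
  gen_ids <- sel$sources$accession[sel$sources$source == "genetic_subcore"]
  expect_setequal(unique(subpop[gen_ids]), c(0, 1))
  # extreme phenotypes are in
  expect_true(names(which.max(quant$FW)) %in% sel$selected)
  expect_true(names(which.min(quant$FW)) %in% sel$selected)
  # every geographic region is represented in the union
  expect_setequal(unique(geo[sel$selected]), unique(geo))
  # full-coverage fraction selects everybody
  sel_all <- select_core(g, quant, qual, geo, fraction = 1,
                         n_genetic = 90, seed = 9)
  expect_setequal(sel_all$selected, rownames(g$codes))
})

test_that("replacement picks the nearest unselected neighbour, never reuses", {
  sc <- scenario_spec(n_accessions = 40, n_snps = 50, n_chromosomes = 2,
                      missing_rate = 0, seed = 606)
  g <- gen_genotypes(sc)
  sel <- select_core(g, fraction = 0.3, n_genetic = 8, seed = 3)
  dropped <- sel$selected[1]
  upd <- replace_accession(sel, dropped)
  expect_false(dropped %in% upd$selected)
  repl <- setdiff(upd$selected, sel$selected)
  expect_length(repl, 1)
  cand <- setdiff(rownames(sel$pcoa), sel$selected)
  d <- sqrt(rowSums(sweep(sel$pcoa[cand, , drop = FALSE], 2,
                          sel$pcoa[dropped, ])^2))
  expect_equal(repl, cand[which.min(d)])
  # repeated replacement never selects an already-selected accession
  cur <- sel
  for (i in 1:5) {
    dr <- cur$selected[1]
    nxt <- replace_accession(cur, dr)
    expect_false(anyDuplicated(nxt$selected) > 0)
    cur <- nxt
  }
  # a duplicated accession is chosen at distance zero
  pc <- sel$pcoa
  pc <- rbind(pc, dup = pc[dropped, ])
  upd2 <- replace_accession(sel, dropped, pcoa = pc)
  expect_equal(setdiff(upd2$selected, sel$selected), "dup")
  expect_equal(upd2$replacement_distance, 0)
})

test_that("representativeness report: identity core, null rate, adversarial core", {
  sc <- scenario_spec(n_accessions = 100, n_snps = 60, n_chromosomes = 2,
                      missing_rate = 0, seed = 607)
  g <- gen_genotypes(sc)
  acc <- rownames(g$codes)
  set.seed(608)
  quant <- list(FW = setNames(rnorm(100), acc))
  qual <- list(SHAPE = setNames(sample(c("round", "flat"), 100, TRUE), acc))
  rep_full <- representativeness_report(acc, g, quant, qual)
  expect_false(any(rep_full$quantitative$flag))
  expect_equal(rep_full$pi_shift, 0)
  # random 16% cores: flags at p < 0.001 occur at no more than the nominal rate
  set.seed(609)
  flags <- replicate(40, {
    core <- sample(acc, 16)
    r <- representativeness_report(core, g, quant, qual)
    any(r$quantitative$flag)
  })
  expect_lte(mean(flags), 0.05)
  # adversarial core: top 16 by FW is flagged
  adv <- names(sort(quant$FW, decreasing = TRUE))[1:16]
  r_adv <- representativeness_report(adv, g, quant, qual)
  expect_true(r_adv$quantitative$flag[r_adv$quantitative$trait == "FW"])
})
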