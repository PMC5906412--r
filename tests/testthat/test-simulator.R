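small_map <- function(seed = 1L, n_chrom = 2L, sites = 200L, len = 5e6) {
  genome_map(n_chrom = n_chrom, chrom_length_bp = len, sites_per_chrom = sites,
             seed = seed)
}

test_that("identical seeds give bit-identical populations and reads", {
  a <- simulate_bsa_experiment(map = small_map(),
                               model = phenotype_model(qtl_chrom = "chr2"),
                               seed = 31)
  b <- simulate_bsa_experiment(map = small_map(),
                               model = phenotype_model(qtl_chrom = "chr2"),
                               seed = 31)
  expect_identical(a$rils$geno, b$rils$geno)
  expect_identical(a$rils$phenotype, b$rils$phenotype)
  expect_identical(a$pools$T, b$pools$T)
  expect_identical(a$sites, b$sites)
  c <- simulate_bsa_experiment(map = small_map(),
                               model = phenotype_model(qtl_chrom = "chr2"),
                               seed = 32)
  expect_false(identical(a$sites, c$sites))
})

test_that("tolerant-allele frequency stays near 1/2 across sites at n = 190", {
  rils <- simulate_rils(small_map(seed = 4), n = 190, seed = 12)
  freq <- colMeans(rils$geno)
  expect_true(all(abs(freq - 0.5) < 0.12))
})

test_that("residual heterozygosity at F7 is near (1/2)^6", {
  rils <- simulate_rils(small_map(seed = 2), n = 190, seed = 8,
                        collapse_het = FALSE)
  het_by_ind <- rowMeans(rils$geno == 0.5)
  m <- mean(het_by_ind)
  se <- sd(het_by_ind) / sqrt(length(het_by_ind))
  expect_lt(abs(m - (1 / 2)^6), 3 * se)
  # the default idealization leaves no heterozygotes
  ideal <- simulate_rils(small_map(seed = 2), n = 50, seed = 8)
  expect_true(all(ideal$geno %in% c(0, 1)))
})

test_that("completely linked sites inherit together", {
  map0 <- small_map(seed = 3, n_chrom = 1L, sites = 50L)
  map0$recomb_rate_cM_per_Mb <- 0
  rils <- simulate_rils(map0, n = 60, seed = 5)
  expect_true(all(apply(rils$geno, 1L, function(g) length(unique(g)) == 1L)))
})

test_that("phenotype classes land on the parent-anchored means", {
  rils <- simulate_rils(small_map(seed = 6), n = 190, seed = 21)
  model <- phenotype_model(grand_mean = 0.755, qtl_chrom = "chr1",
                           additive_effect = 0.165, noise_sd = 0.05)
  rils <- assign_phenotypes(rils, model, seed = 22)
  dose <- rils$geno[, rils$qtl_site]
  hi <- rils$phenotype[dose == 1]
  lo <- rils$phenotype[dose == 0]
  expect_lt(abs(mean(hi) - 0.92), 3 * sd(hi) / sqrt(length(hi)))
  expect_lt(abs(mean(lo) - 0.59), 3 * sd(lo) / sqrt(length(lo)))

  noiseless <- assign_phenotypes(
    rils, phenotype_model(qtl_chrom = "chr1", noise_sd = 0), seed = 1)
  expect_equal(length(unique(noiseless$phenotype)), 2L)
})

test_that("a null additive effect decouples phenotype from the QTL", {
  rils <- simulate_rils(small_map(seed = 9), n = 190, seed = 2)
  for (s in c(1, 2, 3)) {
    null <- assign_phenotypes(
      rils, phenotype_model(qtl_chrom = "chr1", additive_effect = 0),
      seed = s)
    dose <- null$geno[, null$qtl_site]
    tt <- t.test(null$phenotype[dose == 1], null$phenotype[dose == 0])
    expect_lt(abs(unname(tt$statistic)), 4)
  }
})

test_that("pool selection respects cutoffs, ties and the rank fallback", {
  rils <- simulate_rils(small_map(seed = 10), n = 190, seed = 3)
  rils <- assign_phenotypes(rils, phenotype_model(qtl_chrom = "chr1"),
                            seed = 4)
  pools <- build_pools(rils)
  expect_length(pools$T, 20L)
  expect_length(pools$S, 20L)
  expect_true(all(rils$phenotype[pools$T] >= 0.90))
  expect_true(all(rils$phenotype[pools$S] <= 0.63))
  expect_length(intersect(pools$T, pools$S), 0L)

  # cutoff nobody clears: fall back to extreme ranks with a warning
  strict_rils <- rils
  expect_warning(pools2 <- build_pools(strict_rils, hi_cutoff = 1.01),
                 "taking the top")
  expect_length(pools2$T, 20L)
  expect_equal(sort(rils$phenotype[pools2$T], decreasing = TRUE),
               sort(rils$phenotype, decreasing = TRUE)[1:20])

  # all phenotypes equal: deterministic id-order tie-break from both ends
  flat <- rils
  flat$phenotype <- setNames(rep(0.5, length(flat$phenotype)),
                             names(flat$phenotype))
  pools3 <- suppressWarnings(build_pools(flat, lo_cutoff = 0.4))
  ids <- sort(names(flat$phenotype))
  expect_equal(pools3$T, ids[1:20])
  expect_equal(pools3$S, rev(ids)[1:20])
})

test_that("pooled reads follow the binomial read-sampling model", {
  map0 <- small_map(seed = 13, n_chrom = 1L, sites = 2000L)
  rils <- simulate_rils(map0, n = 40, seed = 14)
  members <- rils$ids[1:20]
  draw <- sample_pool_reads(members, rils, mean_depth = 40, label = "T",
                            seed = 15)
  depth <- rowSums(as.matrix(draw[, paste0("T_", bases)]))
  hi_count <- as.matrix(draw[, paste0("T_", bases)])[
    cbind(seq_len(nrow(draw)), match(draw$hi_allele, bases))]
  p_true <- colMeans(rils$geno[1:20, ])
  covered <- depth > 0
  resid <- hi_count[covered] / depth[covered] - p_true[covered]
  expect_lt(abs(mean(resid)), 3 * sd(resid) / sqrt(sum(covered)))

  # pool fixed for the tolerant allele reads out index 1 everywhere covered
  fixed <- rils
  fixed$geno[] <- 1
  draw1 <- sample_pool_reads(members, fixed, mean_depth = 30, label = "T",
                             seed = 16)
  d1 <- rowSums(as.matrix(draw1[, paste0("T_", bases)]))
  h1 <- as.matrix(draw1[, paste0("T_", bases)])[
    cbind(seq_len(nrow(draw1)), match(draw1$hi_allele, bases))]
  expect_true(all(h1[d1 > 0] == d1[d1 > 0]))

  expect_error(sample_pool_reads(members, rils, mean_depth = 0), "positive")
})

test_that("zero-depth draws leave the site missing for that pool", {
  map0 <- small_map(seed = 17, n_chrom = 1L, sites = 500L)
  rils <- simulate_rils(map0, n = 20, seed = 18)
  t_draw <- sample_pool_reads(rils$ids, rils, mean_depth = 1, "T", seed = 19)
  s_draw <- sample_pool_reads(rils$ids, rils, mean_depth = 40, "S", seed = 20)
  sites <- combine_pool_reads(t_draw, s_draw)
  st <- site_stats(sites)
  zero <- st$depth_T == 0L
  expect_gt(sum(zero), 0L)  # Poisson(1) leaves some sites uncovered
  expect_true(all(is.na(st$delta[zero])))
})

test_that("pool allele-frequency contrast is large at the QTL, null elsewhere", {
  # an unlinked chromosome drifts around zero, but whole-chromosome means
  # wobble with the few independent linkage blocks a selection round leaves;
  # average over replicate experiments to beat that correlation down
  map <- small_map(seed = 23, sites = 400L, len = 25e6)
  off_means <- numeric(6)
  for (i in 1:6) {
    sim <- simulate_bsa_experiment(map = map,
                                   model = phenotype_model(qtl_chrom = "chr2"),
                                   seed = 70 + i)
    g <- sim$rils$geno
    freq_T <- colMeans(g[match(sim$pools$T, sim$rils$ids), ])
    freq_S <- colMeans(g[match(sim$pools$S, sim$rils$ids), ])
    contrast <- freq_T - freq_S
    qtl <- sim$truth$qtl_site
    expect_gt(contrast[qtl], 0.5)
    off_means[i] <- mean(contrast[map$sites$chrom == "chr1"])
    # observed pooled-read delta tracks the analytic pool contrast at the QTL
    st <- site_stats(sim$sites)
    expect_gt(st$delta[qtl], contrast[qtl] - 0.2)
  }
  expect_lt(abs(mean(off_means)),
            3 * sd(off_means) / sqrt(length(off_means)))
})

test_that("map-function and minor-QTL options behave additively", {
  map0 <- small_map(seed = 30, n_chrom = 2L, sites = 80L)
  k1 <- simulate_rils(map0, n = 30, seed = 31, map_function = "kosambi")
  k2 <- simulate_rils(map0, n = 30, seed = 31, map_function = "kosambi")
  expect_identical(k1$geno, k2$geno)
  expect_error(simulate_rils(map0, n = 30, seed = 1, map_function = "carter"),
               "unknown map function")

  rils <- simulate_rils(map0, n = 80, seed = 32)
  minor <- map0$sites[map0$sites$chrom == "chr1", ][10, ]
  model <- phenotype_model(qtl_chrom = "chr2", additive_effect = 0.1,
                           noise_sd = 0,
                           extra_qtls = data.frame(chrom = minor$chrom,
                                                   pos = minor$pos,
                                                   effect = 0.03))
  with_minor <- assign_phenotypes(rils, model, seed = 33)
  # noiseless two-locus additive model: at most four distinct values
  expect_lte(length(unique(with_minor$phenotype)), 4L)
  expect_error(assign_phenotypes(rils, phenotype_model(
    qtl_chrom = "chr2", extra_qtls = data.frame(chrom = "chr9", pos = 1,
                                                effect = 0.1)), seed = 1),
    "minor QTL")
})
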