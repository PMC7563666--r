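# Synthetic family, pool and depth-profile generators.

test_that("error-free XY family transmits the Y allele to every son", {
  d <- family_design(n_sites = 150, genotyping_error = 0, missing_rate = 0)
  fam <- simulate_family(d, seed = 3)
  i <- match(d$sd_position, fam$sites$pos)
  expect_false(is.na(i))
  sons <- which(fam$individuals$sex == "male" &
                  fam$individuals$role == "offspring")
  daughters <- which(fam$individuals$sex == "female" &
                       fam$individuals$role == "offspring")
  expect_true(all(fam$a1[i, sons] != fam$a2[i, sons]))       # all sons het
  expect_true(all(fam$a1[i, daughters] == fam$a2[i, daughters]))
  # family of 15 sons + 14 daughters: 31 individuals including both parents
  expect_equal(nrow(fam$individuals), 31)
  expect_equal(sum(fam$individuals$role == "offspring"), 29)
})

test_that("family simulation is Mendelian at zero error and deterministic", {
  d <- family_design(n_sites = 120, genotyping_error = 0, missing_rate = 0)
  fam <- simulate_family(d, seed = 11)
  sire <- which(fam$individuals$role == "sire")
  dam <- which(fam$individuals$role == "dam")
  for (j in which(fam$individuals$role == "offspring")) {
    from_sire <- fam$a1[, j] %in% NA |
      fam$a1[, j] == fam$a1[, sire] | fam$a1[, j] == fam$a2[, sire] |
      fam$a2[, j] == fam$a1[, sire] | fam$a2[, j] == fam$a2[, sire]
    expect_true(all(from_sire))
    # one allele from each parent: the pair must split across parents
    constructible <- vapply(seq_len(nrow(fam$sites)), function(i) {
      s <- c(fam$a1[i, sire], fam$a2[i, sire])
      m <- c(fam$a1[i, dam], fam$a2[i, dam])
      o <- c(fam$a1[i, j], fam$a2[i, j])
      any(o[1] == s & o[2] %in% m) || any(o[2] == s & o[1] %in% m)
    }, TRUE)
    expect_true(all(constructible))
  }
  expect_identical(fam, simulate_family(d, seed = 11))
  expect_false(identical(fam, simulate_family(d, seed = 12)))
})

test_that("null family yields no sex association beyond chance", {
  # exact test p-values are discrete and conservative, so the check is
  # stochastic dominance over uniform, not a two-sided KS match
  rej <- numeric(0); allp <- numeric(0)
  for (s in 1:20) {
    fam <- simulate_family(family_design(n_sites = 150, system = "none",
                                         genotyping_error = 0,
                                         missing_rate = 0), seed = s)
    a <- site_association(fam)
    rej <- c(rej, mean(a$fet_p < 0.01))
    allp <- c(allp, a$fet_p)
  }
  expect_lte(mean(rej), 0.015)
  grid <- seq(0.01, 1, by = 0.01)
  excess <- max(vapply(grid, function(x) mean(allp <= x) - x, 0))
  expect_lte(excess, 0.01)
})

test_that("pool counts conserve depth and respect the design", {
  d <- pool_design(n_sites = 500, seed = 5)
  pp <- simulate_pools(d)
  expect_s3_class(pp$counts, "pool_counts")
  # allele-count conservation: ref + alt equals the simulated depth per site
  expect_identical(pp$counts$f_ref + pp$counts$f_alt,
                   as.integer(pp$depth$female$depth))
  expect_identical(pp$counts$m_ref + pp$counts$m_alt,
                   as.integer(pp$depth$male$depth))
  expect_identical(simulate_pools(d), pp)   # seeded determinism
  # B-block sites are observed far above the genome mean in the carrier pool
  bb <- pp$truth$type == "bblock"
  carrier_depth <- pp$counts$m_ref[bb] + pp$counts$m_alt[bb]
  base_mean <- mean((pp$counts$m_ref + pp$counts$m_alt)[!bb])
  expect_true(all(carrier_depth > 10 * base_mean))
  expect_error(pool_design(frac_sex_patterned = 0.6, frac_bblock = 0.5),
               "<= 1")
  # Koka-style design: 14 females and 20 males are accepted as-is
  expect_silent(simulate_pools(pool_design(n_females = 14, n_males = 20,
                                           n_sites = 100, seed = 1)))
})

test_that("null pools produce almost no sex-patterned flags", {
  fp <- 0; n <- 0
  for (s in 1:10) {
    pp <- simulate_pools(pool_design(n_sites = 1000, frac_sex_patterned = 0,
                                     frac_bblock = 0, seed = s))
    fl <- sex_snp_finder(pp$counts)$sites$flagged
    fp <- fp + sum(fl); n <- n + length(fl)
  }
  expect_lt(fp / n, 0.01)
})

test_that("depth profiles carry the duplication geometry", {
  # noiseless, bin-aligned: exact expected values
  scen <- sv_scenario(region = c(0, 45000), dup = c(10000, 31500),
                      deletions = list(c(12000, 17000), c(22000, 28000)),
                      male_copy_ratio_dup = 1.5, bin_size = 50,
                      mean_depth = 40, noise = "none")
  p <- simulate_depth_profiles(scen, seed = 1)
  expect_true(all(p$female$depth == 40))
  mid <- (p$male$start + p$male$end) / 2
  in_dup <- mid > 10000 & mid < 31500
  in_del <- (mid > 12000 & mid < 17000) | (mid > 22000 & mid < 28000)
  expect_true(all(p$male$depth[in_dup & !in_del] == 60))
  expect_true(all(p$male$depth[in_del] == 40))
  expect_true(all(p$male$depth[!in_dup] == 40))
  # the duplication span of the wild-male geometry is 21512 bp
  scen2 <- sv_scenario(region = c(34480000, 34525000),
                       dup = c(34491225, 34512737))
  expect_equal(diff(scen2$dup), 21512)
  # Poisson sampling: bin means within 3 standard errors of design values
  scen3 <- sv_scenario(region = c(0, 20000), dup = c(5000, 15000),
                       bin_size = 50, mean_depth = 40, noise = "poisson")
  mu <- c(); nbin <- 0
  for (s in 1:20) {
    pm <- simulate_depth_profiles(scen3, seed = s)$male
    mid <- (pm$start + pm$end) / 2
    sel <- mid > 5000 & mid < 15000
    mu <- c(mu, mean(pm$depth[sel])); nbin <- sum(sel)
  }
  se <- sqrt(60 / (50 * nbin * 20))   # var of a Poisson-count bin mean
  expect_lt(abs(mean(mu) - 60), 3 * se)
  expect_error(sv_scenario(c(0, 100), c(10, 50), bin_size = 0), "bin_size")
  expect_error(sv_scenario(c(0, 100), c(10, 50),
                           deletions = list(c(5, 20))), "within the duplication")
  expect_error(family_design(n_sons = 0), "n_sons")
  expect_error(family_design(missing_rate = 1.5), "missing_rate")
  expect_error(family_design(sd_position = 5e7, chrom_length = 4e7),
               "within the chromosome")
})
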