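# Pooled scan: pi-based FST, pooled exact test, Sex-SNP-Finder criteria.

pc_row <- function(f_ref, f_alt, m_ref, m_alt, pos = 100) {
  pool_counts(data.frame(chrom = "LG23", pos = pos, ref = "A", alt = "G",
                         f_ref = f_ref, f_alt = f_alt,
                         m_ref = m_ref, m_alt = m_alt))
}

test_that("pooled FST hits the limits and the stated estimator formula", {
  expect_equal(pooled_fst(pc_row(30, 0, 0, 30))$fst, 1)
  expect_equal(pooled_fst(pc_row(12, 8, 12, 8))$fst, 0, tolerance = 1e-12)
  # direct-formula oracle for (27,3) vs (15,15)
  pi_of <- function(a, b) (a + b) / (a + b - 1) *
    (1 - (a / (a + b))^2 - (b / (a + b))^2)
  pi_s <- (pi_of(27, 3) + pi_of(15, 15)) / 2
  pi_t <- pi_of(42, 18)
  expect_equal(pooled_fst(pc_row(27, 3, 15, 15))$fst, (pi_t - pi_s) / pi_t,
               tolerance = 1e-12)
  # symmetric under pool order; bounded in [0, 1]
  expect_equal(pooled_fst(pc_row(27, 3, 15, 15))$fst,
               pooled_fst(pc_row(15, 15, 27, 3))$fst)
  set.seed(5)
  for (k in 1:50) {
    cnt <- rpois(4, 12)
    f <- pooled_fst(pc_row(cnt[1], cnt[2], cnt[3], cnt[4]))$fst
    if (!is.na(f)) { expect_gte(f, 0); expect_lte(f, 1) }
  }
  # zero depth in one pool: skipped with a flag
  z <- pooled_fst(pc_row(0, 0, 10, 10))
  expect_true(z$skipped)
  expect_true(is.na(z$fst))
  # monomorphic: reported 0
  expect_equal(pooled_fst(pc_row(20, 0, 20, 0))$fst, 0)
})

test_that("pooled exact test matches the enumeration oracle", {
  expect_equal(pooled_fet(pc_row(10, 0, 0, 10))$fet_p, 2 / 184756,
               tolerance = 1e-12)
  expect_equal(pooled_fet(pc_row(20, 10, 20, 10))$fet_p, 1)
  # null pools: conservative p-values, never enriched below uniform
  allp <- numeric(0)
  for (s in 1:10) {
    pp <- simulate_pools(pool_design(n_sites = 300, frac_sex_patterned = 0,
                                     frac_bblock = 0, seed = s))
    allp <- c(allp, pooled_fet(pp$counts)$fet_p)
  }
  grid <- seq(0.01, 1, by = 0.01)
  expect_lte(max(vapply(grid, function(x) mean(allp <= x) - x, 0)), 0.01)
})

test_that("finder criteria flag the XY pattern and respect thresholds", {
  params <- sex_snp_params()
  # female near-fixed 0.95, male 0.5 with minor count 20: flagged
  expect_true(sex_snp_finder(pc_row(38, 2, 20, 20), params,
                             "XY")$sites$flagged)
  # male 0.85 lies outside the 0.3-0.7 intermediate band
  expect_false(sex_snp_finder(pc_row(38, 2, 34, 6), params,
                              "XY")$sites$flagged)
  # depth 8 in the male pool is below the minimum read depth of 10
  expect_false(sex_snp_finder(pc_row(38, 2, 4, 4), params,
                              "XY")$sites$flagged)
  # minor-allele read count below 2 is rejected even at matching frequencies
  expect_false(sex_snp_finder(pc_row(19, 1, 9, 1), params,
                              "XY")$sites$flagged)
  # reference-free: the near-fixed allele may be the alt allele
  expect_true(sex_snp_finder(pc_row(2, 38, 20, 20), params,
                             "XY")$sites$flagged)
  # ZW mirrors the pools
  pc <- pc_row(20, 20, 38, 2)
  expect_true(sex_snp_finder(pc, params, "ZW")$sites$flagged)
  expect_false(sex_snp_finder(pc, params, "XY")$sites$flagged)
  expect_error(sex_snp_finder(pc, params, "WZ"))
  expect_error(sex_snp_params(fixed_threshold = 0.6),
               "fixed_threshold must exceed")
})

test_that("windows are half-open bins anchored at zero", {
  pc <- pool_counts(data.frame(
    chrom = "LG23", pos = c(9999, 10000, 10001, 25000),
    ref = "A", alt = "G", f_ref = c(38, 38, 38, 38), f_alt = c(2, 2, 2, 2),
    m_ref = c(20, 20, 20, 20), m_alt = c(20, 20, 20, 20)))
  w <- sex_snp_finder(pc)$windows
  expect_equal(w$start, c(0, 10000, 20000))
  expect_equal(w$n_flagged, c(2, 1, 1))   # 10000 is the last site of bin 1
})

test_that("planted XY sites are recovered at the published thresholds", {
  tp <- np <- fp <- nn <- 0
  for (s in 1:5) {
    pp <- simulate_pools(pool_design(mean_depth_f = 40, mean_depth_m = 40,
                                     sexpat_hom_freq = 0.95, frac_bblock = 0,
                                     n_sites = 4000, seed = s))
    fl <- sex_snp_finder(pp$counts)$sites$flagged
    sp <- pp$truth$type == "sex_patterned"
    tp <- tp + sum(fl & sp); np <- np + sum(sp)
    fp <- fp + sum(fl & !sp); nn <- nn + sum(!sp)
  }
  expect_gte(tp / np, 0.9)
  expect_lte(fp / nn, 0.01)
})
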