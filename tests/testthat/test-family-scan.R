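# Family association scan and inheritance classification.

make_half_rule_gm <- function(n_called_males, n_called_females) {
  n_m <- 15; n_f <- 14
  ids <- c("sire", "dam", sprintf("m%02d", 1:n_m), sprintf("f%02d", 1:n_f))
  sex <- c("male", "female", rep("male", n_m), rep("female", n_f))
  role <- c("sire", "dam", rep("offspring", n_m + n_f))
  call_m <- c(rep(0L, n_called_males), rep(NA, n_m - n_called_males))
  call_f <- c(rep(1L, n_called_females), rep(NA, n_f - n_called_females))
  a <- matrix(c(0L, 1L, call_m, call_f), nrow = 1)
  genotype_matrix(
    sites = data.frame(chrom = "LG23", pos = 500, ref = "A", alt = "G"),
    a1 = a, a2 = a,
    individuals = data.frame(id = ids, sex = sex, role = role))
}

test_that("half-of-each-sex completeness rule keeps boundary sites", {
  expect_equal(nrow(filter_half_sex_rule(
    make_half_rule_gm(8, 7))$sites), 1)   # 8/15 and 7/14: both at the bound
  expect_equal(nrow(filter_half_sex_rule(
    make_half_rule_gm(7, 7))$sites), 0)   # 7/15 males: below half
  expect_equal(nrow(filter_half_sex_rule(
    make_half_rule_gm(15, 14))$sites), 1) # fully called: unchanged
  no_off <- genotype_matrix(
    sites = data.frame(chrom = "LG23", pos = 1, ref = "A", alt = "G"),
    a1 = matrix(0L, 1, 1), a2 = matrix(0L, 1, 1),
    individuals = data.frame(id = "sire", sex = "male", role = "sire"))
  expect_error(filter_half_sex_rule(no_off), "no sexed offspring")
})

test_that("site association gives exact p and theta at a fixed difference", {
  off <- c(replicate(15, c(1L, 1L), simplify = FALSE),
           replicate(14, c(0L, 0L), simplify = FALSE))
  gm <- make_single_site_gm(c(0L, 1L), c(0L, 0L), off,
                            c(rep("male", 15), rep("female", 14)))
  a <- site_association(gm)
  expect_equal(a$fet_p, fet_oracle(0, 28, 30, 0), tolerance = 1e-14)
  expect_gt(a$fst, 0.98)
  # identical counts in both sexes: p = 1, theta <= 0
  off2 <- c(replicate(8, c(0L, 1L), simplify = FALSE),
            replicate(8, c(0L, 1L), simplify = FALSE))
  gm2 <- make_single_site_gm(c(0L, 1L), c(0L, 1L), off2,
                             rep(c("male", "female"), each = 8))
  a2 <- site_association(gm2)
  expect_equal(a2$fet_p, 1)
  expect_lte(a2$fst, 0)
  # monomorphic site: fst undefined, p = 1
  off3 <- replicate(10, c(0L, 0L), simplify = FALSE)
  gm3 <- make_single_site_gm(c(0L, 0L), c(0L, 0L), off3,
                             rep(c("male", "female"), each = 5))
  a3 <- site_association(gm3)
  expect_true(is.na(a3$fst))
  expect_equal(a3$fet_p, 1)
})

test_that("classifier recognises XY, ZW and null families", {
  for (s in 1:10) {
    fam <- simulate_family(family_design(n_sites = 150, genotyping_error = 0,
                                         missing_rate = 0), seed = s)
    r <- classify_inheritance(fam)
    expect_equal(r$model, "XY")
    expect_equal(max(r$detail$site_concordance), 1)
    famz <- simulate_family(family_design(n_sites = 150, system = "ZW",
                                          genotyping_error = 0,
                                          missing_rate = 0), seed = s)
    rz <- classify_inheritance(famz)
    expect_equal(rz$model, "ZW")
  }
  rn <- classify_inheritance(simulate_family(
    family_design(n_sites = 150, system = "none"), seed = 3))
  expect_equal(rn$model, "inconclusive")
})

test_that("one discordant offspring of 28 gives 3.6% discordance", {
  off <- c(replicate(13, c(0L, 1L), simplify = FALSE),  # sons like the sire
           list(c(0L, 0L)),                             # one discordant son
           replicate(14, c(0L, 0L), simplify = FALSE))  # daughters like dam
  gm <- make_single_site_gm(c(0L, 1L), c(0L, 0L), off,
                            c(rep("male", 14), rep("female", 14)))
  r <- classify_inheritance(gm, assoc_stub(gm))
  expect_equal(r$model, "XY")
  discordance <- 1 - r$detail$site_concordance
  expect_equal(discordance, 1 / 28, tolerance = 1e-12)
  expect_equal(round(100 * discordance, 1), 3.6)
})

test_that("concordance never decreases when a concordant offspring is added", {
  base_off <- c(replicate(5, c(0L, 1L), simplify = FALSE), list(c(0L, 0L)),
                replicate(5, c(0L, 0L), simplify = FALSE))
  base_sex <- c(rep("male", 6), rep("female", 5))
  gm <- make_single_site_gm(c(0L, 1L), c(0L, 0L), base_off, base_sex)
  c0 <- classify_inheritance(gm, assoc_stub(gm))$concordance[["XY"]]
  for (add_sex in c("male", "female")) {
    extra <- if (add_sex == "male") list(c(0L, 1L)) else list(c(0L, 0L))
    gm2 <- make_single_site_gm(c(0L, 1L), c(0L, 0L), c(base_off, extra),
                               c(base_sex, add_sex))
    c1 <- classify_inheritance(gm2, assoc_stub(gm2))$concordance[["XY"]]
    expect_gte(c1, c0)
  }
})

test_that("the most concordant site brackets the simulated sex determiner", {
  hits <- 0; n_runs <- 40
  for (s in 1:n_runs) {
    fam <- simulate_family(family_design(n_sites = 200, genotyping_error = 0,
                                         missing_rate = 0), seed = 1000 + s)
    r <- classify_inheritance(fam)
    peak <- range(r$detail$pos[r$detail$site_concordance ==
                                 max(r$detail$site_concordance)])
    pos <- sort(r$detail$pos)
    lo <- max(c(pos[pos < peak[1]], 0))
    hi <- min(c(pos[pos > peak[2]], fam$sites$pos[nrow(fam$sites)] + 1))
    hits <- hits + (fam$sd_position >= lo && fam$sd_position <= hi)
  }
  expect_gte(hits / n_runs, 0.95)
})

test_that("recombination breakpoints are reported between informative sites", {
  fam <- simulate_family(family_design(n_sites = 200, genotyping_error = 0,
                                       missing_rate = 0), seed = 21)
  r <- classify_inheritance(fam)
  pos <- sort(r$detail$pos)
  for (bp in r$breakpoints) {
    expect_true(all(bp$left %in% pos) && all(bp$right %in% pos))
    # right neighbour is the next informative site after left
    expect_true(all(match(bp$right, pos) == match(bp$left, pos) + 1))
  }
})
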