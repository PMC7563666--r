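# Depth-based SV inference, Y-haplotype model, marker genotype rule.

test_that("SV lengths come straight from the breakpoints", {
  sv <- read_table_fixture("sv")
  expect_equal(sv_length(sv),
               c(21512, 5273, 5986, 21516, 276, 5233, 234, 5609))
  deg <- sv_records("x", 100, 100, 0, "deletion", FALSE)
  expect_warning(l <- sv_length(deg), "degenerate")
  expect_equal(l, 0)
})

test_that("noiseless bin-aligned profiles give exact breakpoints", {
  scen <- sv_scenario(region = c(0, 45000), dup = c(10000, 31500),
                      deletions = list(c(12000, 17000), c(22000, 28000)),
                      bin_size = 50, mean_depth = 40, noise = "none")
  p <- simulate_depth_profiles(scen)
  sv <- estimate_breakpoints(p$male, p$female)
  expect_equal(sv$type, c("duplication", "deletion", "deletion"))
  expect_equal(sv$start, c(10000, 12000, 22000))
  expect_equal(sv$end, c(31500, 17000, 28000))
  expect_true(all(sv$ci == 50))
  # flat ratio: no calls
  flat <- estimate_breakpoints(p$female, p$female)
  expect_equal(nrow(flat), 0)
  # misaligned bins are rejected
  shifted <- p$male
  shifted$start <- shifted$start + 25; shifted$end <- shifted$end + 25
  expect_error(estimate_breakpoints(shifted, p$female), "misaligned")
})

test_that("binary segmentation agrees with the exhaustive single-split oracle", {
  set.seed(13)
  for (k in 1:10) {
    n <- sample(50:200, 1)
    cp <- sample(10:(n - 10), 1)
    x <- c(rnorm(cp, 1, 0.03), rnorm(n - cp, 1.5, 0.03))
    # oracle: try every single change-point, minimise total squared error
    sse <- function(v) sum((v - mean(v))^2)
    costs <- vapply(1:(n - 1), function(j) sse(x[1:j]) + sse(x[(j + 1):n]), 0)
    oracle_cp <- which.min(costs)
    male <- depth_profile(data.frame(chrom = "c", start = (0:(n - 1)) * 50,
                                     end = (1:n) * 50, depth = x * 40))
    female <- depth_profile(data.frame(chrom = "c", start = (0:(n - 1)) * 50,
                                       end = (1:n) * 50, depth = 40))
    sv <- estimate_breakpoints(male, female, max_segments = 2)
    expect_equal(nrow(sv), 1)
    expect_equal(sv$start, oracle_cp * 50)   # dup runs to the profile end
  }
})

test_that("noisy recovery stays within a bin of the planted geometry", {
  scen <- sv_scenario(region = c(34480000, 34525000),
                      dup = c(34491225, 34512737),
                      deletions = list(c(34493315, 34498588),
                                       c(34503117, 34509103)),
                      bin_size = 50, mean_depth = 40, noise = "poisson")
  truth <- sort(c(34491225, 34512737, 34493315, 34498588,
                  34503117, 34509103))
  errs <- c()
  for (s in 1:5) {
    p <- simulate_depth_profiles(scen, seed = s)
    sv <- estimate_breakpoints(p$male, p$female)
    expect_equal(sum(sv$type == "duplication"), 1)
    expect_equal(sum(sv$type == "deletion"), 2)
    errs <- c(errs, abs(sort(c(sv$start, sv$end)) - truth))
  }
  expect_lte(mean(errs), 50)
})

test_that("breakpoint contexts honor gene structure and strand", {
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff_fixture(path)
  genes <- read_gff_genes(path)
  # minus-strand gene: exon 1 is the rightmost (4501-5000 in file coords)
  rec <- sv_records("popA", start = 2100, end = 4700, ci = 50,
                    type = "duplication", shared = TRUE)
  ctx <- classify_breakpoint_context(rec, genes)
  expect_equal(ctx$feature[ctx$breakpoint == "start"], "intron 3")
  expect_equal(ctx$feature[ctx$breakpoint == "end"], "exon 1")
  expect_equal(unique(ctx$gene), "genA")
  outside <- sv_records("popA", 9000, 9500, 0, "deletion", FALSE)
  ctx2 <- classify_breakpoint_context(outside, genes)
  expect_true(all(ctx2$feature == "intergenic"))
})

test_that("Y-haplotype length is region + duplication - deletions", {
  sv <- read_table_fixture("sv")
  koka_dup <- sv[sv$population == "Koka" & sv$type == "duplication", ]
  class(koka_dup) <- class(sv)
  koka_dels <- sv[sv$population == "Koka" & sv$type == "deletion", ]
  yh <- build_y_haplotype(42000, koka_dup, koka_dels)
  expect_equal(yh$total_length, 42000 + 21512 - 5273 - 5986)
  expect_equal(round(yh$total_length / 1000), 52)
  # no deletions: pure additivity
  yh0 <- build_y_haplotype(42000, koka_dup)
  expect_equal(yh0$total_length, 42000 + 21512)
  # placement changes segment annotation, never the length
  yh2 <- build_y_haplotype(42000, koka_dup, koka_dels,
                           placement = "intact-copy")
  expect_equal(yh2$total_length, yh$total_length)
  expect_false(identical(yh2$deletions$copy, yh$deletions$copy))
  # segments tile the model: lengths sum to the total
  expect_equal(sum(yh$segments$length), yh$total_length)
  # a deletion outside the duplicated span is rejected
  bad <- sv_records("Koka", 34480000, 34485000, 0, "deletion", TRUE)
  expect_error(build_y_haplotype(42000, koka_dup, bad),
               "within the duplicated span")
})

test_that("marker patterns map to sexual genotypes with YY precedence", {
  mk <- data.frame(amhX = c("+", "+", "-", "+", "+"),
                   amhdY = c("+", "-", "+", "-", "-"),
                   amhY = c("+", "+", "+", "ND", "-"),
                   stringsAsFactors = FALSE)
  expect_equal(predict_genotype_from_markers(mk),
               c("XY", "XY", "YY", "ND", "XX"))
  bad <- data.frame(amhX = "-", amhdY = "-", amhY = "-")
  expect_error(predict_genotype_from_markers(bad), "no marker evidence")
  # the packaged grouped patterns reproduce the published genotype column
  fixture <- read_table_fixture("markers")
  expect_equal(predict_genotype_from_markers(fixture), fixture$predicted)
})

test_that("variant set operations give exact-key partitions", {
  v <- read_table_fixture("variants")
  ops <- variant_set_ops(v, v)
  expect_equal(nrow(ops$shared), 60)
  expect_equal(nrow(ops$a_specific), 0)
  expect_equal(sum(v$type == "snp"), 52)
  aa <- v[nzchar(v$aa_change), ]
  expect_equal(nrow(aa), 9)
  expect_equal(as.vector(table(aa$gene)[c("oaz1", "amh", "dot1l")]),
               c(2, 6, 1))
  half <- variant_records(as.data.frame(v[1:30, ]))
  ops2 <- variant_set_ops(v, half)
  expect_equal(nrow(ops2$shared), 30)
  expect_equal(nrow(ops2$a_specific), 30)
  expect_equal(nrow(ops2$b_specific), 0)
  expect_equal(ops2$summary$n, c(30, 30, 0))
})
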