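# Independent oracles and in-code fixtures used across the test files.

# Exhaustive hypergeometric enumeration oracle for the two-sided Fisher test
# (method of small p-values), coded from first principles with lchoose.
fet_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; total <- a + b + c + d
  if (total == 0 || r1 == 0 || r1 == total || c1 == 0 || c1 == total) return(1)
  supp <- max(0, r1 + c1 - total):min(r1, c1)
  pr <- exp(lchoose(c1, supp) + lchoose(total - c1, r1 - supp) -
              lchoose(total, r1))
  min(1, sum(pr[pr <= pr[match(a, supp)] * (1 + 1e-7)]))
}

# Weir-Cockerham two-group theta computed by summing the per-allele variance
# components over both alleles (the general multi-allelic form), an
# independently coded route to the same estimand.
wc_oracle <- function(n, p, h) {
  r <- 2
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  comp <- function(pA, hA) {
    pbar <- sum(n * pA) / (r * nbar)
    s2 <- sum(n * (pA - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * hA) / (r * nbar)
    a <- (nbar / nc) * (s2 - (1 / (nbar - 1)) *
                          (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                  ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    c(a, a + b + cc)
  }
  tot <- comp(p, h) + comp(1 - p, h)   # both alleles; het freq is shared
  if (tot[2] == 0) return(NA_real_)
  tot[1] / tot[2]
}

# Single-site family genotype matrix: sire/dam allele pairs plus offspring
# allele pairs (list) and their sexes.
make_single_site_gm <- function(sire, dam, off, off_sex, pos = 1000) {
  n_off <- length(off)
  ids <- c("sire", "dam", sprintf("off_%02d", seq_len(n_off)))
  a1 <- matrix(c(sire[1], dam[1], vapply(off, `[`, 0L, 1)), nrow = 1)
  a2 <- matrix(c(sire[2], dam[2], vapply(off, `[`, 0L, 2)), nrow = 1)
  genotype_matrix(
    sites = data.frame(chrom = "LG23", pos = pos, ref = "A", alt = "G",
                       stringsAsFactors = FALSE),
    a1 = a1, a2 = a2,
    individuals = data.frame(
      id = ids, sex = c("male", "female", off_sex),
      role = c("sire", "dam", rep("offspring", n_off)),
      stringsAsFactors = FALSE))
}

# Association table stub marking every site significant.
assoc_stub <- function(gm, p = 1e-9) {
  data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos, fet_p = p,
             stringsAsFactors = FALSE)
}

# Minimal VCF fixture: 10 biallelic sites with known DP (3 sites with mean
# depth below 5) plus one triallelic site, 4 samples.
write_vcf_fixture <- function(path) {
  samples <- c("s1", "s2", "s3", "s4")
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  gt_of <- function(g, dp) paste0(g, ":", dp)
  row <- function(pos, alt, dps, gts = c("0/0", "0/1", "1/1", "0/0")) {
    paste(c("LG23", pos, ".", "A", alt, ".", "PASS", ".", "GT:DP",
            mapply(gt_of, gts, dps)), collapse = "\t")
  }
  deep <- c(10, 10, 10, 10)     # mean 10
  shallow <- c(2, 2, 2, 2)      # mean 2 < 5
  body <- c(row(100, "G", deep), row(200, "G", shallow),
            row(300, "G", deep), row(400, "G", deep),
            row(500, "G", shallow), row(600, "G", deep),
            row(700, "G", deep), row(800, "G", shallow),
            row(900, "G", deep), row(1000, "G", deep),
            row(1100, "G,T", deep, c("0/0", "0/1", "1/2", "0/0")))
  writeLines(c(hdr, body), path)
  path
}

vcf_fixture_sexmap <- data.frame(
  id = c("s1", "s2", "s3", "s4"),
  sex = c("male", "female", "male", "female"),
  role = c("sire", "dam", "offspring", "offspring"),
  stringsAsFactors = FALSE)

# Synthetic antisense gene fixture as GFF3 text: four exons on the minus
# strand so intron numbering must be strand-aware.
write_gff_fixture <- function(path) {
  lines <- c(
    "##gff-version 3",
    "LG23\ttest\tgene\t1001\t5000\t.\t-\t.\tID=g1;Name=genA",
    "LG23\ttest\tmRNA\t1001\t5000\t.\t-\t.\tID=m1;Parent=g1",
    "LG23\ttest\texon\t4501\t5000\t.\t-\t.\tID=e1;Parent=m1",
    "LG23\ttest\texon\t3501\t4000\t.\t-\t.\tID=e2;Parent=m1",
    "LG23\ttest\texon\t2501\t3000\t.\t-\t.\tID=e3;Parent=m1",
    "LG23\ttest\texon\t1001\t1500\t.\t-\t.\tID=e4;Parent=m1")
  writeLines(lines, path)
  path
}
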