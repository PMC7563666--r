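# Synthetic data generators: F1 families genotyped at RAD-like biallelic
# sites, sex-pooled allele counts, and binned depth profiles carrying a
# Y-specific tandem duplication. These emulate the statistical structure the
# downstream scans assume, so the whole pipeline is testable at desk scale.

#' Design of a simulated F1 family
#'
#' Describes an F1 family (two parents plus sexed offspring) genotyped at
#' biallelic sites along one chromosome, optionally carrying a
#' sex-determining locus under male (XY) or female (ZW) heterogamety.
#'
#' @param n_sons,n_daughters offspring counts.
#' @param n_sites number of biallelic sites.
#' @param chrom_length chromosome length in bp.
#' @param sd_position position (bp) of the sex-determining site.
#' @param recomb_rate crossovers per Mb per meiosis (Haldane model: Poisson
#'   crossover count with mean `recomb_rate * chrom_length / 1e6`, no
#'   interference).
#' @param genotyping_error per-allele symmetric flip probability.
#' @param missing_rate per-call missing probability, independent of genotype.
#' @param system `"XY"`, `"ZW"`, or `"none"` (no sex-determining locus).
#' @param chrom chromosome name used in output.
#' @return an object of class `family_design`.
#' @export
family_design <- function(n_sons = 15L, n_daughters = 14L, n_sites = 2000L,
                          chrom_length = 40e6, sd_position = 34.5e6,
                          recomb_rate = 0.025, genotyping_error = 0.005,
                          missing_rate = 0.2, system = c("XY", "ZW", "none"),
                          chrom = "LG23") {
  system <- match.arg(system)
  d <- list(
    n_sons = check_count(n_sons, "n_sons"),
    n_daughters = check_count(n_daughters, "n_daughters"),
    n_sites = check_count(n_sites, "n_sites", min = 2L),
    chrom_length = check_pos_num(chrom_length, "chrom_length"),
    sd_position = check_pos_num(sd_position, "sd_position"),
    recomb_rate = check_pos_num(recomb_rate + 1, "recomb_rate") - 1,
    genotyping_error = check_prob(genotyping_error, "genotyping_error"),
    missing_rate = check_prob(missing_rate, "missing_rate"),
    system = system, chrom = chrom)
  stop_if(d$recomb_rate < 0, "'recomb_rate' must be >= 0")
  stop_if(d$sd_position > d$chrom_length,
          "'sd_position' must lie within the chromosome")
  structure(d, class = "family_design")
}

# One meiotic gamete over `pos` from haplotypes hapA/hapB (columns).
# Crossovers: Haldane (Poisson count, uniform positions). If `force_hap` is
# given, the starting phase is chosen so the gamete carries that haplotype
# (1 = A, 2 = B) at site index `force_at`.
meiosis_gamete <- function(hapA, hapB, pos, chrom_length, recomb_rate,
                           force_hap = NULL, force_at = NULL) {
  k <- stats::rpois(1L, recomb_rate * chrom_length / 1e6)
  breaks <- if (k > 0) sort(stats::runif(k, 0, chrom_length)) else numeric(0)
  crossings <- findInterval(pos, breaks)  # crossovers before each site
  start <- stats::rbinom(1L, 1L, 0.5)
  if (!is.null(force_hap)) {
    want <- force_hap - 1L
    start <- (want - crossings[force_at]) %% 2L
  }
  use_b <- (start + crossings) %% 2L == 1L
  ifelse(use_b, hapB, hapA)
}

#' Simulate an F1 family genotype matrix
#'
#' Parents carry random biallelic haplotypes; under an XY system the sire is
#' heterozygous at the sex-determining site with the Y-specific allele
#' transmitted to every son (ZW mirrors through the dam). Offspring
#' chromosomes are recombinant mosaics of the parental haplotypes under a
#' Haldane crossover process. Genotyping errors (symmetric allele flips) and
#' missingness are applied independently per call.
#'
#' @param design a [family_design()].
#' @param seed integer seed; identical design + seed gives identical output.
#' @return a `genotype_matrix` (see [genotype_matrix()]).
#' @export
simulate_family <- function(design, seed = 1L) {
  stop_if(!inherits(design, "family_design"), "'design' must be a family_design")
  set.seed(seed)
  n_off <- design$n_sons + design$n_daughters
  pos <- sort(sample.int(design$chrom_length, design$n_sites))
  if (design$system != "none") {
    # ensure the sex-determining site is present
    j <- which.min(abs(pos - design$sd_position))
    pos[j] <- design$sd_position
    pos <- sort(unique(pos))
    sd_idx <- match(design$sd_position, pos)
  } else sd_idx <- NA_integer_
  ns <- length(pos)

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ns, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")

  # parental haplotypes: sire (h1, h2), dam (h1, h2); h1 is Y (XY) / W (ZW)
  hap <- matrix(stats::rbinom(4L * ns, 1L, 0.5), nrow = ns, ncol = 4L)
  colnames(hap) <- c("sire1", "sire2", "dam1", "dam2")
  if (design$system == "XY") {
    hap[sd_idx, ] <- c(1L, 0L, 0L, 0L)
  } else if (design$system == "ZW") {
    hap[sd_idx, ] <- c(0L, 0L, 1L, 0L)
  }

  ids <- c("sire", "dam",
           sprintf("son_%02d", seq_len(design$n_sons)),
           sprintf("daughter_%02d", seq_len(design$n_daughters)))
  sex <- c("male", "female",
           rep("male", design$n_sons), rep("female", design$n_daughters))
  role <- c("sire", "dam", rep("offspring", n_off))

  a1 <- matrix(NA_integer_, ns, n_off + 2L)
  a2 <- matrix(NA_integer_, ns, n_off + 2L)
  a1[, 1L] <- hap[, "sire1"]; a2[, 1L] <- hap[, "sire2"]
  a1[, 2L] <- hap[, "dam1"];  a2[, 2L] <- hap[, "dam2"]

  for (i in seq_len(n_off)) {
    is_son <- i <= design$n_sons
    force_sire <- force_dam <- NULL
    if (design$system == "XY") force_sire <- if (is_son) 1L else 2L
    if (design$system == "ZW") force_dam <- if (is_son) 2L else 1L
    a1[, i + 2L] <- meiosis_gamete(hap[, "sire1"], hap[, "sire2"], pos,
                                   design$chrom_length, design$recomb_rate,
                                   force_sire, sd_idx)
    a2[, i + 2L] <- meiosis_gamete(hap[, "dam1"], hap[, "dam2"], pos,
                                   design$chrom_length, design$recomb_rate,
                                   force_dam, sd_idx)
  }

  n_ind <- n_off + 2L
  if (design$genotyping_error > 0) {
    flip1 <- matrix(stats::rbinom(ns * n_ind, 1L, design$genotyping_error),
                    ns, n_ind) == 1L
    flip2 <- matrix(stats::rbinom(ns * n_ind, 1L, design$genotyping_error),
                    ns, n_ind) == 1L
    a1[flip1] <- 1L - a1[flip1]
    a2[flip2] <- 1L - a2[flip2]
  }
  depth <- matrix(stats::rpois(ns * n_ind, 20), ns, n_ind)
  if (design$missing_rate > 0) {
    miss <- matrix(stats::rbinom(ns * n_ind, 1L, design$missing_rate),
                   ns, n_ind) == 1L
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    depth[miss] <- 0L
  }

  genotype_matrix(
    sites = data.frame(chrom = design$chrom, pos = pos, ref = ref, alt = alt,
                       stringsAsFactors = FALSE),
    a1 = a1, a2 = a2, depth = depth,
    individuals = data.frame(id = ids, sex = sex, role = role,
                             stringsAsFactors = FALSE),
    sd_position = if (design$system == "none") NA_real_ else design$sd_position,
    seed = seed)
}

#' Design of simulated sex pools
#'
#' Describes pooled whole-genome sequencing of phenotypically sexed wild
#' fish: one female and one male pool, read counts drawn binomially from
#' pool allele frequencies. A fraction of sites are sex-patterned (divergent
#' X/Y-type sites: near-fixed in the homogametic pool, ~0.5 in the
#' heterogametic pool) and a fraction lie in high-coverage B-chromosome
#' blocks present in a single pool.
#'
#' @param n_females,n_males pooled individuals (bookkeeping only; read counts
#'   are binomial at the pool frequency).
#' @param mean_depth_f,mean_depth_m mean read depth per pool.
#' @param n_sites number of biallelic sites, evenly spaced along the
#'   chromosome.
#' @param frac_sex_patterned,frac_bblock site fractions (sum must be <= 1).
#' @param bblock_fold coverage multiplier inside B blocks.
#' @param seed integer seed.
#' @param pattern heterogamety of the planted sex-patterned sites.
#' @param sexpat_hom_freq reference-allele frequency of sex-patterned sites
#'   in the homogametic pool (near-fixed divergent allele).
#' @param sexpat_het_freq same, heterogametic pool (0.5 for a fully
#'   Y/W-linked allele with all carriers heterogametic).
#' @param bblock_pool which pool carries the B chromosome.
#' @param bblock_run sites per contiguous B block.
#' @param chrom,chrom_length chromosome name and length (bp).
#' @return an object of class `pool_design`.
#' @export
pool_design <- function(n_females = 27L, n_males = 27L,
                        mean_depth_f = 18, mean_depth_m = 39,
                        n_sites = 2000L, frac_sex_patterned = 0.05,
                        frac_bblock = 0.02, bblock_fold = 15, seed = 1L,
                        pattern = c("XY", "ZW"),
                        sexpat_hom_freq = 0.98, sexpat_het_freq = 0.5,
                        bblock_pool = c("male", "female"), bblock_run = 25L,
                        chrom = "LG23", chrom_length = 10e6) {
  pattern <- match.arg(pattern)
  bblock_pool <- match.arg(bblock_pool)
  d <- list(
    n_females = check_count(n_females, "n_females"),
    n_males = check_count(n_males, "n_males"),
    mean_depth_f = check_pos_num(mean_depth_f, "mean_depth_f"),
    mean_depth_m = check_pos_num(mean_depth_m, "mean_depth_m"),
    n_sites = check_count(n_sites, "n_sites", min = 10L),
    frac_sex_patterned = check_prob(frac_sex_patterned, "frac_sex_patterned"),
    frac_bblock = check_prob(frac_bblock, "frac_bblock"),
    bblock_fold = check_pos_num(bblock_fold, "bblock_fold"),
    seed = check_count(seed, "seed", min = 0L),
    pattern = pattern,
    sexpat_hom_freq = check_prob(sexpat_hom_freq, "sexpat_hom_freq"),
    sexpat_het_freq = check_prob(sexpat_het_freq, "sexpat_het_freq"),
    bblock_pool = bblock_pool,
    bblock_run = check_count(bblock_run, "bblock_run"),
    chrom = chrom, chrom_length = check_pos_num(chrom_length, "chrom_length"))
  stop_if(d$frac_sex_patterned + d$frac_bblock > 1,
          "frac_sex_patterned + frac_bblock must be <= 1")
  structure(d, class = "pool_design")
}

#' Simulate sex-pool allele counts with truth labels
#'
#' Sites are evenly spaced; per-site pool depths are Poisson around the pool
#' means (multiplied by `bblock_fold` in the B-block carrier pool), and
#' reference read counts are binomial at the pool allele frequency. Neutral
#' sites share one frequency between the pools; sex-patterned sites follow
#' the XY (or ZW) divergent-site pattern; B-block sites are contiguous runs
#' that are highly covered and ~50:50 polymorphic in the carrier pool only.
#'
#' @param design a [pool_design()].
#' @return list with `counts` (a `pool_counts`), `truth` (data.frame with a
#'   `type` label per site: neutral / sex_patterned / bblock), and `depth`
#'   (list of female and male [depth_profile()]s binned at the site spacing).
#' @export
simulate_pools <- function(design) {
  stop_if(!inherits(design, "pool_design"), "'design' must be a pool_design")
  set.seed(design$seed)
  ns <- design$n_sites
  spacing <- design$chrom_length / (ns + 1)
  pos <- round(seq_len(ns) * spacing)

  n_sp <- round(design$frac_sex_patterned * ns)
  n_bb <- round(design$frac_bblock * ns)
  type <- rep("neutral", ns)
  if (n_sp > 0) {                      # one contiguous sex-determining region
    sp_start <- floor(ns * 0.6)
    sp_idx <- seq(sp_start, length.out = n_sp)
    type[sp_idx] <- "sex_patterned"
  }
  if (n_bb > 0) {                      # contiguous B blocks away from the SDR
    n_blocks <- max(1L, ceiling(n_bb / design$bblock_run))
    free <- which(type == "neutral")
    starts <- sort(sample(free[free < ns * 0.5], n_blocks))
    bb_idx <- unique(unlist(lapply(starts, function(s)
      seq(s, length.out = min(design$bblock_run, n_bb)))))
    bb_idx <- bb_idx[bb_idx <= ns & type[bb_idx] == "neutral"]
    bb_idx <- utils::head(bb_idx, n_bb)
    type[bb_idx] <- "bblock"
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, ns, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")

  # pool reference-allele frequencies
  q <- stats::runif(ns, 0.05, 0.95)
  freq_f <- freq_m <- q
  sp <- type == "sex_patterned"
  if (design$pattern == "XY") {
    freq_f[sp] <- design$sexpat_hom_freq
    freq_m[sp] <- design$sexpat_het_freq
  } else {
    freq_m[sp] <- design$sexpat_hom_freq
    freq_f[sp] <- design$sexpat_het_freq
  }
  bb <- type == "bblock"
  carrier_is_male <- design$bblock_pool == "male"
  if (any(bb)) {
    carrier_freq <- stats::runif(sum(bb), 0.35, 0.65)
    other_freq <- 0.99                 # conserved exonic sequence
    if (carrier_is_male) {
      freq_m[bb] <- carrier_freq; freq_f[bb] <- other_freq
    } else {
      freq_f[bb] <- carrier_freq; freq_m[bb] <- other_freq
    }
  }

  lam_f <- rep(design$mean_depth_f, ns)
  lam_m <- rep(design$mean_depth_m, ns)
  if (carrier_is_male) lam_m[bb] <- lam_m[bb] * design$bblock_fold
  else lam_f[bb] <- lam_f[bb] * design$bblock_fold
  depth_f <- stats::rpois(ns, lam_f)
  depth_m <- stats::rpois(ns, lam_m)
  f_ref <- stats::rbinom(ns, depth_f, freq_f)
  m_ref <- stats::rbinom(ns, depth_m, freq_m)

  counts <- pool_counts(data.frame(
    chrom = design$chrom, pos = pos, ref = ref, alt = alt,
    f_ref = f_ref, f_alt = depth_f - f_ref,
    m_ref = m_ref, m_alt = depth_m - m_ref, stringsAsFactors = FALSE))
  truth <- data.frame(chrom = design$chrom, pos = pos, type = type,
                      stringsAsFactors = FALSE)
  edges <- round((seq_len(ns + 1L) - 0.5) * spacing)  # bins tile exactly
  bins <- data.frame(chrom = design$chrom, start = edges[-(ns + 1L)],
                     end = edges[-1L])
  list(counts = counts, truth = truth,
       depth = list(
         female = depth_profile(cbind(bins, depth = depth_f), pool = "female"),
         male = depth_profile(cbind(bins, depth = depth_m), pool = "male")),
       seed = design$seed)
}

#' Structural-variant depth scenario
#'
#' Geometry of a Y-specific tandem duplication with internal deletions, used
#' to simulate male/female depth profiles. All intervals are 0-based
#' half-open on the reference.
#'
#' @param region length-2 vector, the profiled reference interval.
#' @param dup length-2 vector, the duplicated span (within `region`).
#' @param deletions list of length-2 vectors, deletions within `dup`.
#' @param male_copy_ratio_dup male/female copy ratio inside the duplication
#'   (3 Y-linked copies over 2 in an XY male gives 1.5).
#' @param bin_size bin width in bp.
#' @param mean_depth per-base mean depth.
#' @param noise `"poisson"` (per-bin Poisson read counts) or `"none"`.
#' @return an object of class `sv_scenario`.
#' @export
sv_scenario <- function(region, dup, deletions = list(),
                        male_copy_ratio_dup = 1.5, bin_size = 50,
                        mean_depth = 40, noise = c("poisson", "none")) {
  noise <- match.arg(noise)
  stop_if(length(region) != 2L || region[2] <= region[1], "invalid 'region'")
  stop_if(length(dup) != 2L || dup[2] <= dup[1], "invalid 'dup'")
  stop_if(dup[1] < region[1] || dup[2] > region[2],
          "'dup' must lie within 'region'")
  for (d in deletions)
    stop_if(length(d) != 2L || d[2] <= d[1] || d[1] < dup[1] || d[2] > dup[2],
            "each deletion must be a valid interval within the duplication")
  stop_if(male_copy_ratio_dup <= 1, "'male_copy_ratio_dup' must be > 1")
  bin_size <- check_pos_num(bin_size, "bin_size")
  structure(list(region = as.numeric(region), dup = as.numeric(dup),
                 deletions = lapply(deletions, as.numeric),
                 male_copy_ratio_dup = male_copy_ratio_dup,
                 bin_size = bin_size,
                 mean_depth = check_pos_num(mean_depth, "mean_depth"),
                 noise = noise),
            class = "sv_scenario")
}

# base-pair overlap of [s1,e1) with [s2,e2)
interval_overlap <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Simulate male and female depth profiles for a duplication scenario
#'
#' The female profile is flat at `mean_depth`. The male profile carries
#' `mean_depth * male_copy_ratio_dup` inside the duplication, reverting to
#' `mean_depth` over deletion spans (a deletion removes one of the two
#' Y-segment copies). Bins straddling a breakpoint take the length-weighted
#' expectation. Poisson noise, when requested, draws the per-bin read count
#' at the expected per-base depth times the bin width.
#'
#' @param scenario an [sv_scenario()].
#' @param seed integer seed.
#' @param chrom chromosome name.
#' @return list with `male` and `female` [depth_profile()]s.
#' @export
simulate_depth_profiles <- function(scenario, seed = 1L, chrom = "LG23") {
  stop_if(!inherits(scenario, "sv_scenario"), "'scenario' must be an sv_scenario")
  set.seed(seed)
  n_bins <- floor((scenario$region[2] - scenario$region[1]) / scenario$bin_size)
  stop_if(n_bins < 1, "region shorter than one bin")
  start <- scenario$region[1] + (seq_len(n_bins) - 1L) * scenario$bin_size
  end <- start + scenario$bin_size

  extra <- scenario$male_copy_ratio_dup - 1
  dup_ov <- interval_overlap(start, end, scenario$dup[1], scenario$dup[2])
  del_ov <- rep(0, n_bins)
  for (d in scenario$deletions)
    del_ov <- del_ov + interval_overlap(start, end, d[1], d[2])
  frac_extra <- (dup_ov - del_ov) / scenario$bin_size
  mu_m <- scenario$mean_depth * (1 + extra * frac_extra)
  mu_f <- rep(scenario$mean_depth, n_bins)

  draw <- function(mu) {
    if (scenario$noise == "none") mu
    else stats::rpois(n_bins, mu * scenario$bin_size) / scenario$bin_size
  }
  bins <- data.frame(chrom = chrom, start = start, end = end)
  list(male = depth_profile(cbind(bins, depth = draw(mu_m)), pool = "male"),
       female = depth_profile(cbind(bins, depth = draw(mu_f)), pool = "female"),
       seed = seed)
}
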