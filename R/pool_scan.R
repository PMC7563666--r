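# Pooled-sequencing scan: per-site allele frequencies, a pi-based pooled FST,
# Fisher's exact test on read counts, and the Sex-SNP-Finder XY/ZW
# frequency criteria with windowed counts of flagged sites.

#' Sex-SNP-Finder threshold parameters
#'
#' Frequency and depth criteria used to flag sex-patterned SNPs in pooled
#' data. Defaults are the standard published settings: a site is a candidate
#' when the homogametic pool is fixed or nearly fixed (major-allele frequency
#' at or above `fixed_threshold`) while the heterogametic pool carries the
#' alternative at intermediate frequency (within
#' `[min_polymorphic, max_polymorphic]`), with both pools inside the
#' `[min_depth, max_depth]` depth window and at least `min_read_count` reads
#' of the minor allele in the heterogametic pool. Windowed summaries count
#' flagged sites in non-overlapping `window_size` bins anchored at 0.
#'
#' @param fixed_threshold minimum major-allele frequency, homogametic pool.
#' @param min_polymorphic,max_polymorphic intermediate-frequency band for the
#'   heterogametic pool.
#' @param min_depth,max_depth per-pool depth window (reads).
#' @param min_read_count minimum minor-allele reads, heterogametic pool.
#' @param window_size window width in bp.
#' @return an object of class `sex_snp_params`.
#' @export
sex_snp_params <- function(fixed_threshold = 0.9, min_polymorphic = 0.3,
                           max_polymorphic = 0.7, min_depth = 10,
                           max_depth = 100, min_read_count = 2,
                           window_size = 10000) {
  p <- list(fixed_threshold = check_prob(fixed_threshold, "fixed_threshold"),
            min_polymorphic = check_prob(min_polymorphic, "min_polymorphic"),
            max_polymorphic = check_prob(max_polymorphic, "max_polymorphic"),
            min_depth = check_pos_num(min_depth, "min_depth"),
            max_depth = check_pos_num(max_depth, "max_depth"),
            min_read_count = check_count(min_read_count, "min_read_count",
                                         min = 0L),
            window_size = check_pos_num(window_size, "window_size"))
  stop_if(p$min_polymorphic >= p$max_polymorphic,
          "min_polymorphic must be < max_polymorphic")
  stop_if(p$fixed_threshold <= p$max_polymorphic,
          "fixed_threshold must exceed max_polymorphic")
  stop_if(p$min_depth > p$max_depth, "min_depth must be <= max_depth")
  structure(p, class = "sex_snp_params")
}

# nucleotide diversity pi for counts (a, b): (n/(n-1)) (1 - (a/n)^2 - (b/n)^2)
pi_counts <- function(a, b) {
  n <- a + b
  ifelse(n > 1, (n / (n - 1)) * (1 - (a / n)^2 - (b / n)^2), 0)
}

#' Pooled per-site FST
#'
#' pi-based estimator: `fst = (pi_T - pi_S) / pi_T`, where `pi_S` is the mean
#' of the two within-pool diversities and `pi_T` is computed from the summed
#' counts, each with the `n/(n-1)` small-sample correction (n = read depth).
#' Reported as 0 when `pi_T = 0` (monomorphic); sites with zero depth in
#' either pool are skipped (`NA` with a flag). Values lie in [0, 1] and are
#' symmetric under pool order.
#'
#' @param pc a [pool_counts()].
#' @return data.frame: `chrom`, `pos`, `fst`, `skipped`.
#' @export
pooled_fst <- function(pc) {
  stop_if(!inherits(pc, "pool_counts"), "'pc' must be pool_counts")
  nf <- pc$f_ref + pc$f_alt
  nm <- pc$m_ref + pc$m_alt
  skipped <- nf == 0 | nm == 0
  pi_s <- (pi_counts(pc$f_ref, pc$f_alt) + pi_counts(pc$m_ref, pc$m_alt)) / 2
  pi_t <- pi_counts(pc$f_ref + pc$m_ref, pc$f_alt + pc$m_alt)
  fst <- ifelse(pi_t > 0, (pi_t - pi_s) / pi_t, 0)
  fst[skipped] <- NA_real_
  data.frame(chrom = pc$chrom, pos = pc$pos, fst = pmax(0, pmin(1, fst)),
             skipped = skipped, stringsAsFactors = FALSE)
}

#' Pooled per-site Fisher's exact test
#'
#' Two-sided exact test on the ref/alt x female-pool/male-pool read-count
#' table at each site (see [fet_2x2()] for the two-sided convention).
#'
#' @param pc a [pool_counts()].
#' @return data.frame: `chrom`, `pos`, `fet_p`.
#' @export
pooled_fet <- function(pc) {
  stop_if(!inherits(pc, "pool_counts"), "'pc' must be pool_counts")
  p <- vapply(seq_len(nrow(pc)), function(i)
    fet_2x2(pc$f_ref[i], pc$f_alt[i], pc$m_ref[i], pc$m_alt[i]), 0)
  data.frame(chrom = pc$chrom, pos = pc$pos, fet_p = p,
             stringsAsFactors = FALSE)
}

#' Flag sex-patterned SNPs in pooled data
#'
#' Applies the Sex-SNP-Finder criteria (see [sex_snp_params()]) for the
#' requested heterogamety pattern. For XY the female pool is homogametic and
#' the male pool heterogametic; ZW mirrors the roles. Frequencies are
#' major-allele based (reference-free): the homogametic pool must be
#' near-fixed for its major allele and the heterogametic pool must carry the
#' homogametic pool's minor allele at intermediate frequency.
#'
#' @param pc a [pool_counts()].
#' @param params a [sex_snp_params()].
#' @param pattern `"XY"` or `"ZW"`.
#' @return list with `sites` (per-site data.frame: depths, frequencies,
#'   `flagged`) and `windows` (per-window flagged-site counts).
#' @export
sex_snp_finder <- function(pc, params = sex_snp_params(),
                           pattern = c("XY", "ZW")) {
  stop_if(!inherits(pc, "pool_counts"), "'pc' must be pool_counts")
  stop_if(!inherits(params, "sex_snp_params"), "'params' must be sex_snp_params")
  pattern <- match.arg(pattern)
  if (pattern == "XY") {
    hom_ref <- pc$f_ref; hom_alt <- pc$f_alt
    het_ref <- pc$m_ref; het_alt <- pc$m_alt
  } else {
    hom_ref <- pc$m_ref; hom_alt <- pc$m_alt
    het_ref <- pc$f_ref; het_alt <- pc$f_alt
  }
  hom_n <- hom_ref + hom_alt
  het_n <- het_ref + het_alt
  depth_ok <- hom_n >= params$min_depth & hom_n <= params$max_depth &
    het_n >= params$min_depth & het_n <= params$max_depth

  hom_major_is_ref <- hom_ref >= hom_alt
  hom_major_freq <- ifelse(hom_n > 0, pmax(hom_ref, hom_alt) / hom_n, NA)
  # frequency and read count, in the heterogametic pool, of the allele that
  # is MINOR in the homogametic pool
  het_minor_count <- ifelse(hom_major_is_ref, het_alt, het_ref)
  het_minor_freq <- ifelse(het_n > 0, het_minor_count / het_n, NA)

  flagged <- depth_ok &
    hom_major_freq >= params$fixed_threshold &
    het_minor_count >= params$min_read_count &
    het_minor_freq >= params$min_polymorphic &
    het_minor_freq <= params$max_polymorphic
  flagged[is.na(flagged)] <- FALSE

  sites <- data.frame(chrom = pc$chrom, pos = pc$pos,
                      hom_depth = hom_n, het_depth = het_n,
                      hom_major_freq = hom_major_freq,
                      het_minor_freq = het_minor_freq,
                      flagged = flagged, pattern = pattern,
                      stringsAsFactors = FALSE)
  win <- floor((pc$pos - 1) / params$window_size)   # half-open, anchored at 0
  agg <- stats::aggregate(flagged ~ chrom + win, data =
                            data.frame(chrom = pc$chrom, win = win,
                                       flagged = flagged),
                          FUN = sum)
  windows <- data.frame(chrom = agg$chrom,
                        start = agg$win * params$window_size,
                        end = (agg$win + 1) * params$window_size,
                        n_flagged = agg$flagged, stringsAsFactors = FALSE)
  windows <- windows[order(windows$chrom, windows$start), ]
  rownames(windows) <- NULL
  list(sites = sites, windows = windows, params = params)
}

#' Run the full pooled scan
#'
#' Convenience wrapper: pooled FST, pooled FET and the Sex-SNP-Finder flags
#' in one per-site table.
#'
#' @inheritParams sex_snp_finder
#' @param alpha significance level for the FET flag.
#' @return list with `sites` (fst, fet_p, finder flag, significance) and
#'   `windows`.
#' @export
scan_pools <- function(pc, params = sex_snp_params(), pattern = "XY",
                       alpha = 0.01) {
  fst <- pooled_fst(pc)
  fet <- pooled_fet(pc)
  finder <- sex_snp_finder(pc, params, pattern)
  sites <- data.frame(finder$sites,
                      fst = fst$fst, fet_p = fet$fet_p,
                      significant = fet$fet_p < alpha,
                      stringsAsFactors = FALSE)
  list(sites = sites, windows = finder$windows)
}
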