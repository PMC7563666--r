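# S3 containers shared across modules. Plain data.frame-backed structures in
# the vcfR/ape style; constructors validate the invariants once so downstream
# code can rely on them.

#' Genotype matrix for a sexed family
#'
#' Diploid genotypes at biallelic sites for parents and sexed offspring.
#' Alleles are coded 0 (ref) / 1 (alt); `a1`/`a2` hold the unordered allele
#' pair per (site, individual) with `NA` for missing calls. Positions are
#' 1-based and strictly increasing within a chromosome.
#'
#' @param sites data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param a1,a2 integer matrices (sites x individuals) of alleles.
#' @param depth integer matrix of per-call read depth (0 for missing).
#' @param individuals data.frame with `id`, `sex` (male/female), `role`
#'   (sire/dam/offspring).
#' @param sd_position optional true sex-determining position (simulations).
#' @param seed optional seed recorded for reproducibility.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, a1, a2, depth = NULL, individuals,
                            sd_position = NA_real_, seed = NA_integer_) {
  stop_if(!all(c("chrom", "pos", "ref", "alt") %in% names(sites)),
          "'sites' must have chrom, pos, ref, alt")
  stop_if(!all(c("id", "sex", "role") %in% names(individuals)),
          "'individuals' must have id, sex, role")
  stop_if(!all(individuals$sex %in% c("male", "female")),
          "individual sex must be male or female")
  stop_if(!all(individuals$role %in% c("sire", "dam", "offspring")),
          "individual role must be sire, dam or offspring")
  n_s <- nrow(sites); n_i <- nrow(individuals)
  stop_if(!identical(dim(a1), c(n_s, n_i)) || !identical(dim(a2), c(n_s, n_i)),
          "allele matrices must be sites x individuals")
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    stop_if(any(diff(p) <= 0), "positions must be strictly increasing within chrom")
  }
  if (is.null(depth)) depth <- matrix(NA_integer_, n_s, n_i)
  # store alleles unordered (a1 <= a2): genotype identity ignores phase
  swap <- !is.na(a1) & !is.na(a2) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  structure(list(sites = sites, a1 = a1, a2 = a2, depth = depth,
                 individuals = individuals, sd_position = sd_position,
                 seed = seed),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d individuals (%d offspring)\n",
              nrow(x$sites), nrow(x$individuals),
              sum(x$individuals$role == "offspring")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) c(nrow(x$sites), nrow(x$individuals))

# subset a genotype_matrix by site index
gm_subset_sites <- function(gm, idx) {
  genotype_matrix(gm$sites[idx, , drop = FALSE],
                  gm$a1[idx, , drop = FALSE], gm$a2[idx, , drop = FALSE],
                  gm$depth[idx, , drop = FALSE], gm$individuals,
                  gm$sd_position, gm$seed)
}

#' Per-site allele read counts for a female and a male pool
#'
#' @param df data.frame with `chrom`, `pos`, `ref`, `alt`, and non-negative
#'   integer read counts `f_ref`, `f_alt`, `m_ref`, `m_alt`.
#' @return an object of class `pool_counts` (a data.frame).
#' @export
pool_counts <- function(df) {
  need <- c("chrom", "pos", "ref", "alt", "f_ref", "f_alt", "m_ref", "m_alt")
  stop_if(!all(need %in% names(df)), paste("pool_counts needs columns:",
                                           paste(need, collapse = ", ")))
  cnt <- as.matrix(df[c("f_ref", "f_alt", "m_ref", "m_alt")])
  stop_if(any(cnt < 0) || any(cnt != floor(cnt)),
          "read counts must be non-negative integers")
  class(df) <- c("pool_counts", "data.frame")
  df
}

#' Binned depth profile along a genomic segment
#'
#' Bins are 0-based half-open and non-overlapping, sorted by start.
#'
#' @param df data.frame with `chrom`, `start`, `end`, `depth`.
#' @param pool optional pool label (e.g. "male"), kept as an attribute.
#' @param population optional population label.
#' @return an object of class `depth_profile` (a data.frame).
#' @export
depth_profile <- function(df, pool = NA_character_,
                          population = NA_character_) {
  need <- c("chrom", "start", "end", "depth")
  stop_if(!all(need %in% names(df)), paste("depth_profile needs columns:",
                                           paste(need, collapse = ", ")))
  stop_if(any(df$end <= df$start), "bins must have end > start")
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("depth_profile", "data.frame"),
            pool = pool, population = population)
}

#' Structural-variant records
#'
#' Duplications/deletions with 1-based start, exclusive end (so
#' `length = end - start`), symmetric breakpoint confidence interval in bp,
#' and sharing flag.
#'
#' @param population character vector of population labels.
#' @param start,end breakpoint coordinates (bp).
#' @param ci half-width of the confidence interval around each breakpoint.
#' @param type `"duplication"` or `"deletion"`.
#' @param shared logical, found in both populations.
#' @return an object of class `sv_records` (a data.frame).
#' @export
sv_records <- function(population, start, end, ci = 0,
                       type = "duplication", shared = NA) {
  stop_if(any(end < start), "SV end before start")
  stop_if(any(ci < 0), "'ci' must be >= 0")
  stop_if(!all(type %in% c("duplication", "deletion")),
          "type must be duplication or deletion")
  df <- data.frame(population = population, start = start, end = end,
                   ci = ci, type = type, shared = shared,
                   stringsAsFactors = FALSE)
  class(df) <- c("sv_records", "data.frame")
  df
}

#' Length of structural variants
#'
#' `end - start`; a degenerate record with `start == end` yields length 0 and
#' a warning (flagged invalid).
#'
#' @param rec an [sv_records()] data.frame.
#' @return numeric vector of lengths in bp.
#' @export
sv_length <- function(rec) {
  stop_if(!inherits(rec, "sv_records"), "'rec' must be sv_records")
  len <- rec$end - rec$start
  if (any(len == 0)) warning("degenerate SV record(s) with start == end")
  len
}
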