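# Detection and masking of high-coverage "B blocks": amplified
# B-chromosome-derived fragments that pile reads onto the reference and
# masquerade as sex-associated signal in pooled scans.

#' Flag high-coverage B blocks in a depth profile
#'
#' Bins with depth above `fold_threshold` times the genome mean are flagged,
#' adjacent flagged bins merged, and merged runs shorter than `min_block`
#' dropped. The genome mean is computed robustly after excluding the top 1%
#' of bins, so the very blocks being detected do not inflate it.
#'
#' @param depth a [depth_profile()].
#' @param fold_threshold coverage multiplier over the genome mean.
#' @param min_block minimum merged block length in bp.
#' @return an object of class `bblock_set`: data.frame of blocks (`chrom`,
#'   `start`, `end`, `mean_fold`, `pool`, `population`) with the trimmed
#'   genome mean as attribute `genome_mean`.
#' @export
flag_bblocks <- function(depth, fold_threshold = 10, min_block = 1000) {
  stop_if(!inherits(depth, "depth_profile"), "'depth' must be a depth_profile")
  stop_if(nrow(depth) < 1, "profile must cover at least one bin")
  fold_threshold <- check_pos_num(fold_threshold, "fold_threshold")
  # rank-based trim: drop the highest 1% of bins outright
  n_keep <- max(1L, floor(0.99 * nrow(depth)))
  gmean <- mean(sort(depth$depth)[seq_len(n_keep)])
  stop_if(!is.finite(gmean) || gmean == 0, "genome mean depth is zero")

  hot <- depth$depth > fold_threshold * gmean
  blocks <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), mean_fold = numeric(),
                       stringsAsFactors = FALSE)
  if (any(hot)) {
    for (ch in unique(depth$chrom)) {
      d <- depth[depth$chrom == ch, ]
      h <- hot[depth$chrom == ch]
      r <- rle(h)
      stops <- cumsum(r$lengths)
      starts <- stops - r$lengths + 1L
      for (k in which(r$values)) {
        i <- starts[k]:stops[k]
        # adjacency requires bins to actually touch
        gaps <- which(d$start[i][-1] != d$end[i][-length(i)])
        segs <- split(i, cumsum(c(0, seq_along(i)[-1] %in% (gaps + 1))))
        for (s in segs) {
          if (d$end[max(s)] - d$start[min(s)] >= min_block)
            blocks <- rbind(blocks, data.frame(
              chrom = ch, start = d$start[min(s)], end = d$end[max(s)],
              mean_fold = mean(d$depth[s]) / gmean, stringsAsFactors = FALSE))
        }
      }
    }
  }
  blocks$pool <- rep(attr(depth, "pool"), nrow(blocks))
  blocks$population <- rep(attr(depth, "population"), nrow(blocks))
  structure(blocks, class = c("bblock_set", "data.frame"),
            genome_mean = gmean, fold_threshold = fold_threshold)
}

#' Cross-pool consistency of B blocks
#'
#' Merges block footprints across pools (overlapping blocks share a
#' footprint) and reports, for each footprint, a presence matrix over pools
#' and a verdict: a footprint is a `"sex-linked candidate"` only when it is
#' present in the same-sex pool of every population, otherwise it is a
#' `"sex-independent artefact"` (the hallmark of B-chromosome blocks, which
#' can sit in the female pool of one population and the male pool of
#' another).
#'
#' @param sets list of [flag_bblocks()] results, each carrying `pool` and
#'   `population` labels.
#' @return data.frame: footprint coordinates, one presence column per pool
#'   (`population.pool`), and `verdict`. Empty when no blocks exist.
#' @export
bblock_consistency <- function(sets) {
  stop_if(!is.list(sets) || length(sets) < 2L, "need >= 2 pools")
  all_blocks <- do.call(rbind, lapply(sets, as.data.frame))
  pools <- unique(do.call(rbind, lapply(sets, function(s)
    data.frame(pool = attr(s, "pool") %||% unique(s$pool),
               population = attr(s, "population") %||% unique(s$population),
               stringsAsFactors = FALSE))))
  pools <- pools[!is.na(pools$pool), , drop = FALSE]
  if (is.null(all_blocks) || nrow(all_blocks) == 0)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), verdict = character()))

  populations <- unique(pools$population)
  footprints <- data.frame(chrom = character(), start = numeric(),
                           end = numeric(), stringsAsFactors = FALSE)
  for (ch in unique(all_blocks$chrom)) {
    b <- all_blocks[all_blocks$chrom == ch, ]
    b <- b[order(b$start), ]
    cur_s <- b$start[1]; cur_e <- b$end[1]
    for (i in seq_len(nrow(b))[-1]) {
      if (b$start[i] < cur_e) cur_e <- max(cur_e, b$end[i])
      else {
        footprints <- rbind(footprints, data.frame(chrom = ch, start = cur_s,
                                                   end = cur_e))
        cur_s <- b$start[i]; cur_e <- b$end[i]
      }
    }
    footprints <- rbind(footprints, data.frame(chrom = ch, start = cur_s,
                                               end = cur_e))
  }

  pool_key <- paste(all_blocks$population, all_blocks$pool, sep = ".")
  keys <- paste(pools$population, pools$pool, sep = ".")
  pres <- matrix(FALSE, nrow(footprints), length(keys),
                 dimnames = list(NULL, keys))
  for (i in seq_len(nrow(footprints))) {
    hit <- all_blocks$chrom == footprints$chrom[i] &
      all_blocks$start < footprints$end[i] &
      all_blocks$end > footprints$start[i]
    pres[i, ] <- keys %in% pool_key[hit]
  }
  verdict <- vapply(seq_len(nrow(footprints)), function(i) {
    for (sex in unique(pools$pool)) {
      same_sex <- keys[pools$pool == sex]
      in_every_pop <- length(unique(pools$population[pools$pool == sex])) ==
        length(populations) && all(pres[i, same_sex])
      other <- keys[pools$pool != sex]
      if (in_every_pop && !any(pres[i, other]))
        return("sex-linked candidate")
    }
    "sex-independent artefact"
  }, "")
  cbind(footprints, as.data.frame(pres), verdict = verdict)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mask pool-count sites inside B blocks
#'
#' Removes sites falling inside any flagged block (0-based half-open block
#' intervals vs 1-based site positions); the removal count is reported via
#' `message()`.
#'
#' @param pc a [pool_counts()].
#' @param blocks a `bblock_set` (or data.frame with chrom/start/end).
#' @return the masked [pool_counts()].
#' @export
mask_sites <- function(pc, blocks) {
  stop_if(!inherits(pc, "pool_counts"), "'pc' must be pool_counts")
  if (nrow(blocks) == 0) return(pc)
  pos0 <- pc$pos - 1   # site position in internal coordinates
  inside <- rep(FALSE, nrow(pc))
  for (i in seq_len(nrow(blocks)))
    inside <- inside | (pc$chrom == blocks$chrom[i] &
                          pos0 >= blocks$start[i] & pos0 < blocks$end[i])
  message(sprintf("mask_sites: removed %d of %d sites inside %d block(s)",
                  sum(inside), nrow(pc), nrow(blocks)))
  out <- pc[!inside, , drop = FALSE]
  rownames(out) <- NULL
  pool_counts(as.data.frame(out))
}
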