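# Depth-based structural-variant inference and Y-haplotype reconstruction:
# least-squares binary segmentation of the male/female depth ratio,
# breakpoint gene-context classification, the ordered-segment model of the
# Y-specific tandem duplication, and variant effect annotation.

# Greedy least-squares binary segmentation of a numeric series into at most
# `max_segments` piecewise-constant segments. Returns change-point indices
# (a change-point after bin i means segments split between i and i+1).
binseg <- function(x, max_segments, min_gain = NULL) {
  n <- length(x)
  if (is.null(min_gain)) {
    # gain threshold scaled to the local noise level (robust sd of diffs)
    sigma2 <- (stats::mad(diff(x)) / sqrt(2))^2
    min_gain <- max(3.84 * sigma2, 1e-12) * log(n)
  }
  seg_cost <- function(l, r, cs, cs2) {
    s <- cs[r + 1L] - cs[l]
    s2 <- cs2[r + 1L] - cs2[l]
    s2 - s^2 / (r - l + 1L)
  }
  cs <- c(0, cumsum(x)); cs2 <- c(0, cumsum(x^2))
  best_split <- function(l, r) {
    if (r - l < 1L) return(c(NA, 0))
    ks <- l:(r - 1L)
    gains <- seg_cost(l, r, cs, cs2) -
      (vapply(ks, function(k) seg_cost(l, k, cs, cs2), 0) +
         vapply(ks, function(k) seg_cost(k + 1L, r, cs, cs2), 0))
    k <- ks[which.max(gains)]
    c(k, max(gains))
  }
  bounds <- list(c(1L, n))
  splits <- integer(0)
  while (length(bounds) < max_segments) {
    cand <- vapply(bounds, function(b) best_split(b[1], b[2]), c(0, 0))
    if (all(is.na(cand[1, ])) || max(cand[2, ], na.rm = TRUE) < min_gain) break
    j <- which.max(cand[2, ])
    k <- as.integer(cand[1, j])
    b <- bounds[[j]]
    bounds[[j]] <- c(b[1], k)
    bounds[[length(bounds) + 1L]] <- c(k + 1L, b[2])
    splits <- sort(c(splits, k))
  }
  splits
}

#' Estimate duplication/deletion breakpoints from a male/female depth-ratio
#' profile
#'
#' The per-bin male/female depth ratio is segmented by least-squares binary
#' segmentation into at most `max_segments` piecewise-constant segments
#' (adjacent segments whose means differ by less than half a copy step are
#' re-merged). Segments whose mean ratio is within `ratio_tol` of
#' `dup_ratio` (1.5 = three Y-linked copies over two in an XY male) are
#' called duplicated; the duplication spans the first to the last such
#' segment, and interior segments that revert to ratio ~1 are called
#' deletions on the Y (one of the two Y-segment copies lost). Breakpoints
#' get a confidence interval of one bin.
#'
#' @param male,female [depth_profile()]s on identical bins.
#' @param max_segments maximum number of segments.
#' @param dup_ratio expected male/female ratio inside the duplication.
#' @param ratio_tol tolerance for classifying segment means.
#' @param population label for the output records.
#' @return an [sv_records()] data.frame (0 rows when the ratio is flat).
#' @export
estimate_breakpoints <- function(male, female, max_segments = 10,
                                 dup_ratio = 1.5, ratio_tol = 0.15,
                                 population = NA_character_) {
  stop_if(!inherits(male, "depth_profile") || !inherits(female, "depth_profile"),
          "'male' and 'female' must be depth_profiles")
  stop_if(!identical(male$chrom, female$chrom) ||
            !identical(male$start, female$start) ||
            !identical(male$end, female$end),
          "male and female profiles have misaligned bins")
  stop_if(any(female$depth <= 0), "female profile has zero-depth bins")
  ratio <- male$depth / female$depth
  bin_size <- stats::median(male$end - male$start)

  splits <- binseg(ratio, check_count(max_segments, "max_segments", 1L))
  edges <- c(0L, splits, length(ratio))
  means <- vapply(seq_len(length(edges) - 1L), function(i)
    mean(ratio[(edges[i] + 1L):edges[i + 1L]]), 0)
  # merge adjacent segments closer than half the copy-ratio step
  step <- (dup_ratio - 1) / 2
  repeat {
    if (length(means) < 2L) break
    d <- abs(diff(means))
    if (min(d) >= step) break
    j <- which.min(d)
    lens <- diff(edges)
    means[j] <- (means[j] * lens[j] + means[j + 1L] * lens[j + 1L]) /
      (lens[j] + lens[j + 1L])
    means <- means[-(j + 1L)]
    edges <- edges[-(j + 1L)]
  }

  is_dup <- abs(means - dup_ratio) <= ratio_tol
  if (!any(is_dup))
    return(sv_records(character(), numeric(), numeric(), numeric(),
                      character(), logical()))
  first <- min(which(is_dup)); last <- max(which(is_dup))
  seg_start <- male$start[edges[-length(edges)] + 1L]
  seg_end <- male$end[edges[-1L]]
  recs <- sv_records(population, seg_start[first], seg_end[last],
                     ci = bin_size, type = "duplication", shared = NA)
  if (last > first) {
    inner <- (first + 1L):(last - 1L)
    dels <- inner[abs(means[inner] - 1) <= ratio_tol]
    for (j in dels)
      recs <- rbind(recs, sv_records(population, seg_start[j], seg_end[j],
                                     ci = bin_size, type = "deletion",
                                     shared = NA))
  }
  recs <- recs[order(recs$start, recs$end), ]
  rownames(recs) <- NULL
  class(recs) <- c("sv_records", "data.frame")
  recs
}

# transcription-ordered exons of one gene
gene_exons <- function(genes, g) {
  ex <- genes[genes$gene == g & genes$type == "exon", , drop = FALSE]
  if (nrow(ex) == 0) return(ex)
  ex[order(ex$start0, decreasing = unique(ex$strand)[1] == "-"), ,
     drop = FALSE]
}

# label the feature containing internal position p within gene g
feature_at <- function(genes, g, p) {
  ex <- gene_exons(genes, g)
  if (nrow(ex) == 0) return("intragenic")
  for (k in seq_len(nrow(ex)))
    if (p >= ex$start0[k] && p < ex$end[k]) return(sprintf("exon %d", k))
  # introns lie between consecutive exons in transcription order
  for (k in seq_len(nrow(ex) - 1L)) {
    if (ex$strand[1] == "+") {
      if (p >= ex$end[k] && p < ex$start0[k + 1L]) return(sprintf("intron %d", k))
    } else {
      if (p >= ex$end[k + 1L] && p < ex$start0[k]) return(sprintf("intron %d", k))
    }
  }
  "intragenic"
}

gene_spans <- function(genes) {
  sp <- lapply(split(genes, genes$gene), function(g)
    data.frame(gene = g$gene[1], start0 = min(g$start0), end = max(g$end),
               strand = g$strand[1], stringsAsFactors = FALSE))
  do.call(rbind, sp)
}

#' Gene context of structural-variant breakpoints
#'
#' Labels the start and end breakpoint of each record with the gene and
#' feature (which exon or intron, numbered in transcription order, honoring
#' strand) it falls in, or `"intergenic"` outside all gene spans.
#'
#' @param rec an [sv_records()] data.frame.
#' @param genes a [gene_models()] object.
#' @return data.frame: `population`, `type`, `breakpoint` (start/end), `pos`,
#'   `gene`, `feature`.
#' @export
classify_breakpoint_context <- function(rec, genes) {
  stop_if(!inherits(rec, "sv_records"), "'rec' must be sv_records")
  stop_if(!inherits(genes, "gene_models"), "'genes' must be gene_models")
  spans <- gene_spans(genes)
  one <- function(pos_internal) {
    hit <- which(spans$start0 <= pos_internal & spans$end > pos_internal)
    if (length(hit) == 0) return(c("", "intergenic"))
    g <- spans$gene[hit[1]]
    c(g, feature_at(genes, g, pos_internal))
  }
  out <- do.call(rbind, lapply(seq_len(nrow(rec)), function(i) {
    rbind(
      data.frame(population = rec$population[i], type = rec$type[i],
                 breakpoint = "start", pos = rec$start[i],
                 gene = one(rec$start[i])[1], feature = one(rec$start[i])[2],
                 stringsAsFactors = FALSE),
      data.frame(population = rec$population[i], type = rec$type[i],
                 breakpoint = "end", pos = rec$end[i],
                 gene = one(rec$end[i] - 1)[1],
                 feature = one(rec$end[i] - 1)[2],
                 stringsAsFactors = FALSE))
  }))
  rownames(out) <- NULL
  out
}

#' Reconstruct the Y-haplotype segment model
#'
#' Builds the ordered-segment description of the Y region implied by a
#' tandem duplication with internal deletions: reference prefix, two copies
#' of the duplicated span, reference suffix. Each deletion is assigned to
#' the copy in which the overlapped boundary-gene fragment is truncated
#' under the chosen placement hypothesis (`"truncated-copy"`, the preferred
#' scenario in which deletions remove already-truncated gene fragments of
#' the internal chimera, or `"intact-copy"`). The total length
#' `region + duplication - sum(deletions)` is placement-invariant.
#'
#' @param region the reference interval from the first gene start to the
#'   last gene end: either a length-2 interval or a single total length in
#'   bp (the interval is then centred on the duplication).
#' @param dup a 1-row [sv_records()] duplication.
#' @param deletions an [sv_records()] data.frame of deletions within `dup`.
#' @param placement deletion placement hypothesis.
#' @return an object of class `y_haplotype`: ordered `segments` data.frame,
#'   `deletions` with assigned copy, and `total_length` in bp.
#' @export
build_y_haplotype <- function(region, dup, deletions = NULL,
                              placement = c("truncated-copy", "intact-copy")) {
  placement <- match.arg(placement)
  stop_if(!inherits(dup, "sv_records") || nrow(dup) != 1L ||
            dup$type != "duplication", "'dup' must be a single duplication record")
  dup_len <- dup$end - dup$start
  if (length(region) == 1L) {
    stop_if(region < dup_len, "region shorter than the duplication")
    pad <- (region - dup_len) / 2
    region <- c(dup$start - pad, dup$end + pad)
  }
  stop_if(length(region) != 2L || region[2] <= region[1], "invalid 'region'")
  stop_if(dup$start < region[1] || dup$end > region[2],
          "duplication outside region")
  region_len <- region[2] - region[1]

  del <- if (is.null(deletions) || nrow(deletions) == 0)
    data.frame(population = character(), start = numeric(), end = numeric(),
               ci = numeric(), type = character(), shared = logical())
  else as.data.frame(deletions)
  stop_if(nrow(del) > 0 && (any(del$start < dup$start) || any(del$end > dup$end)),
          "deletions must lie within the duplicated span")

  mid <- (dup$start + dup$end) / 2
  upstream <- nrow(del) > 0 & (del$start + del$end) / 2 < mid
  # chimera-in-the-middle geometry: the truncated upstream-gene fragment sits
  # on copy 2, the truncated downstream-gene fragment on copy 1
  del$copy <- if (placement == "truncated-copy")
    ifelse(upstream, 2L, 1L) else ifelse(upstream, 1L, 2L)

  seg <- function(piece, s, e, copy) {
    dels <- del[del$copy == copy & piece == "dup", c("start", "end"),
                drop = FALSE]
    data.frame(piece = piece, source_start = s, source_end = e, copy = copy,
               length = (e - s) - if (nrow(dels)) sum(dels$end - dels$start)
               else 0,
               stringsAsFactors = FALSE)
  }
  segments <- rbind(
    seg("prefix", region[1], dup$start, 0L),
    seg("dup", dup$start, dup$end, 1L),
    seg("dup", dup$start, dup$end, 2L),
    seg("suffix", dup$end, region[2], 0L))
  total <- region_len + dup_len -
    (if (nrow(del)) sum(del$end - del$start) else 0)
  stopifnot(abs(sum(segments$length) - total) < 1e-9)
  structure(list(region = region, dup = as.data.frame(dup), deletions = del,
                 placement = placement, segments = segments,
                 total_length = total),
            class = "y_haplotype")
}

#' @export
print.y_haplotype <- function(x, ...) {
  cat(sprintf(
    "y_haplotype: %d segments, total length %d bp (~%.0f Kb), placement = %s\n",
    nrow(x$segments), round(x$total_length), x$total_length / 1000,
    x$placement))
  invisible(x)
}

#' Write a Y-haplotype model as structured JSON
#'
#' @param yh a [build_y_haplotype()] result.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_y_haplotype_json <- function(yh, path) {
  stop_if(!inherits(yh, "y_haplotype"), "'yh' must be a y_haplotype")
  jsonlite::write_json(
    list(region = yh$region, placement = yh$placement,
         total_length = yh$total_length, segments = yh$segments,
         deletions = yh$deletions),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
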