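# Family-based genome scan: per-site Weir-Cockerham FST and two-sided
# Fisher's exact test between sexed offspring, plus the XY/ZW
# inheritance-pattern classifier with recombination-breakpoint reporting.

offspring_idx <- function(gm, sex = NULL) {
  i <- which(gm$individuals$role == "offspring")
  if (!is.null(sex)) i <- i[gm$individuals$sex[i] == sex]
  i
}

#' Keep sites called in at least half of each sex
#'
#' Retains sites with non-missing calls in at least `ceiling(n_males / 2)`
#' male offspring and `ceiling(n_females / 2)` female offspring. This is the
#' standard completeness filter for family RAD genotype tables.
#'
#' @param gm a [genotype_matrix()] with sexed offspring.
#' @return the filtered `genotype_matrix`.
#' @export
filter_half_sex_rule <- function(gm) {
  stop_if(!inherits(gm, "genotype_matrix"), "'gm' must be a genotype_matrix")
  males <- offspring_idx(gm, "male")
  females <- offspring_idx(gm, "female")
  stop_if(length(males) + length(females) == 0L, "no sexed offspring")
  called <- !is.na(gm$a1)
  keep <- rowSums(called[, males, drop = FALSE]) >= ceiling(length(males) / 2) &
    rowSums(called[, females, drop = FALSE]) >= ceiling(length(females) / 2)
  gm_subset_sites(gm, which(keep))
}

# allele and genotype counts for one sex at all sites
sex_counts <- function(gm, idx) {
  a1 <- gm$a1[, idx, drop = FALSE]
  a2 <- gm$a2[, idx, drop = FALSE]
  called <- !is.na(a1)
  n <- rowSums(called)
  alt <- rowSums(a1, na.rm = TRUE) + rowSums(a2, na.rm = TRUE)
  het <- rowSums(a1 != a2, na.rm = TRUE)
  list(n = n, alt = alt, ref = 2 * n - alt, het = het)
}

#' Per-site sex association in a family
#'
#' For each site, computes (a) the two-sided Fisher's exact p-value on the
#' 2x2 ref/alt x male/female allele-count table and (b) the Weir-Cockerham
#' theta between male and female offspring from genotype counts. Parents are
#' excluded from the test (their inclusion would bias the table). Sites
#' monomorphic among called offspring get `fst = NA` (reported 0 on output)
#' and `p = 1`.
#'
#' @param gm a [genotype_matrix()].
#' @param alpha significance level for the `significant` flag.
#' @return data.frame of class `association_table`: `chrom`, `pos`, `fst`,
#'   `fet_p`, `n_males_called`, `n_females_called`, `significant`.
#' @export
site_association <- function(gm, alpha = 0.01) {
  stop_if(!inherits(gm, "genotype_matrix"), "'gm' must be a genotype_matrix")
  alpha <- check_prob(alpha, "alpha")
  males <- offspring_idx(gm, "male")
  females <- offspring_idx(gm, "female")
  stop_if(length(males) == 0L || length(females) == 0L,
          "need sexed offspring of both sexes")
  cm <- sex_counts(gm, males)
  cf <- sex_counts(gm, females)
  ns <- nrow(gm$sites)
  p <- fst <- numeric(ns)
  for (i in seq_len(ns)) {
    p[i] <- fet_2x2(cf$ref[i], cf$alt[i], cm$ref[i], cm$alt[i])
    if (cm$n[i] == 0 || cf$n[i] == 0) { fst[i] <- NA_real_; next }
    fst[i] <- wc_theta(
      n = c(cm$n[i], cf$n[i]),
      p = c(cm$alt[i] / (2 * cm$n[i]), cf$alt[i] / (2 * cf$n[i])),
      h = c(cm$het[i] / cm$n[i], cf$het[i] / cf$n[i]))
  }
  out <- data.frame(chrom = gm$sites$chrom, pos = gm$sites$pos,
                    fst = fst, fet_p = p,
                    n_males_called = cm$n, n_females_called = cf$n,
                    significant = p < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), ]
  rownames(out) <- NULL
  class(out) <- c("association_table", "data.frame")
  out
}

# per-offspring labels at one informative site (het parent x hom parent)
label_offspring <- function(o1, o2, het, hom) {
  # het: het parent's allele pair (sorted); hom: hom parent's allele (scalar)
  specific <- setdiff(het, hom)          # allele the hom parent lacks
  lab <- rep("missing", length(o1))
  called <- !is.na(o1)
  same_hom <- called & o1 == hom & o2 == hom
  same_het <- called & o1 == min(het) & o2 == max(het)
  yy_like <- called & o1 == specific & o2 == specific
  lab[called] <- "neither"
  lab[same_hom] <- "hom_parent"
  lab[same_het] <- "het_parent"
  lab[yy_like] <- "specific_homozygous"
  lab
}

#' Classify the heterogamety model from parent-offspring genotypes
#'
#' Evaluates the XY and ZW inheritance hypotheses at candidate sites
#' (significant in `assoc` at `alpha`, both parents called, and passing the
#' half-of-each-sex completeness rule). For XY, informative sites have a
#' heterozygous sire and homozygous dam; each offspring is labelled by whom
#' its genotype matches (`maternal`, `paternal`, homozygous for the
#' sire-specific allele -- a YY-like signal -- `neither`, or `missing`).
#'
#' Because the linkage phase of the sire's Y-borne allele is unknown at any
#' single site, the XY-consistent configuration at an informative site is
#' either "sons heterozygous like the sire, daughters homozygous like the
#' dam" or its mirror image (when the Y happens to carry the dam's allele).
#' Each site is therefore oriented to whichever phase agrees with more
#' offspring, its concordance is the agreeing fraction among non-missing
#' calls, and the model concordance pools the agreeing calls over all
#' informative sites. ZW mirrors the rule through the dam. The decision
#' statistic is each model's best single-site concordance (the genotype
#' nearest the sex determiner predicts phenotypic sex, while the pooled
#' value is diluted by loosely linked significant sites): the model with
#' the higher best-site concordance is selected when it reaches `decision`,
#' otherwise the report is inconclusive. Per-offspring recombination
#' breakpoints are switches of the oriented carrier state between
#' consecutive informative sites.
#'
#' @param gm a [genotype_matrix()] with both parents.
#' @param assoc an association table from [site_association()] on `gm`.
#' @param alpha significance level defining candidate sites.
#' @param decision concordance threshold for declaring a model.
#' @return list of class `inheritance_report`: `model`, `concordance`
#'   (named XY/ZW), per-site detail data.frame (labels per offspring plus
#'   `site_concordance`), and per-offspring breakpoint list for the selected
#'   (or best) model.
#' @export
classify_inheritance <- function(gm, assoc = site_association(gm),
                                 alpha = 0.01, decision = 0.9) {
  stop_if(!inherits(gm, "genotype_matrix"), "'gm' must be a genotype_matrix")
  sire <- which(gm$individuals$role == "sire")
  dam <- which(gm$individuals$role == "dam")
  stop_if(length(sire) != 1L || length(dam) != 1L,
          "need exactly one sire and one dam")
  gm_f <- filter_half_sex_rule(gm)
  key <- paste(gm_f$sites$chrom, gm_f$sites$pos)
  sig <- paste(assoc$chrom, assoc$pos)[assoc$fet_p < alpha]
  cand <- which(key %in% sig &
                  !is.na(gm_f$a1[, sire]) & !is.na(gm_f$a1[, dam]))
  off <- offspring_idx(gm_f)
  off_sex <- gm_f$individuals$sex[off]
  off_id <- gm_f$individuals$id[off]

  eval_model <- function(model) {
    het_par <- if (model == "XY") sire else dam
    hom_par <- if (model == "XY") dam else sire
    hetero_sex <- if (model == "XY") "male" else "female"
    inform <- cand[gm_f$a1[cand, het_par] != gm_f$a2[cand, het_par] &
                     gm_f$a1[cand, hom_par] == gm_f$a2[cand, hom_par]]
    if (length(inform) == 0L)
      return(list(concordance = NA_real_, labels = NULL, sites = inform))
    labels <- matrix("missing", length(inform), length(off),
                     dimnames = list(NULL, off_id))
    carrier <- matrix(NA, length(inform), length(off),
                      dimnames = list(NULL, off_id))
    site_conc <- numeric(length(inform))
    is_hetero <- off_sex == hetero_sex
    for (k in seq_along(inform)) {
      i <- inform[k]
      het <- c(gm_f$a1[i, het_par], gm_f$a2[i, het_par])
      hom <- gm_f$a1[i, hom_par]
      labels[k, ] <- label_offspring(gm_f$a1[i, off], gm_f$a2[i, off],
                                     het = het, hom = hom)
      # carrier of the het parent's sex-specific allele (the one the hom
      # parent lacks), under the phase where that allele rides the Y/W
      specific <- setdiff(het, hom)
      has_specific <- !is.na(gm_f$a1[i, off]) &
        (gm_f$a1[i, off] == specific | gm_f$a2[i, off] == specific)
      called <- !is.na(gm_f$a1[i, off])
      agree_direct <- sum((has_specific == is_hetero)[called])
      agree_mirror <- sum(called) - agree_direct
      if (agree_mirror > agree_direct) {      # Y/W carries the shared allele
        carrier[k, called] <- !has_specific[called]
        site_conc[k] <- agree_mirror / max(1L, sum(called))
      } else {
        carrier[k, called] <- has_specific[called]
        site_conc[k] <- agree_direct / max(1L, sum(called))
      }
    }
    called <- !is.na(carrier)
    conc <- sum(sweep(carrier, 2L, is_hetero, "==") & called) /
      max(1L, sum(called))
    list(concordance = conc, best = max(site_conc), labels = labels,
         carrier = carrier, site_concordance = site_conc, sites = inform)
  }

  xy <- eval_model("XY")
  zw <- eval_model("ZW")
  conc <- c(XY = xy$concordance, ZW = zw$concordance)
  # the decision statistic is the best single discriminating site: genotype
  # nearest the sex determiner predicts phenotypic sex, while pooled
  # concordance is diluted by loosely linked significant sites
  conc_best <- c(XY = if (is.null(xy$labels)) NA_real_ else xy$best,
                 ZW = if (is.null(zw$labels)) NA_real_ else zw$best)
  if (all(is.na(conc_best))) {
    model <- "inconclusive"
    best <- NULL
    note <- "no informative sites for either model"
  } else {
    best_name <- names(which.max(conc_best))
    best <- if (best_name == "XY") xy else zw
    model <- if (max(conc_best, na.rm = TRUE) >= decision) best_name else
      "inconclusive"
    note <- NA_character_
  }

  breakpoints <- list()
  detail <- NULL
  if (!is.null(best) && length(best$sites) > 0) {
    pos <- gm_f$sites$pos[best$sites]
    ord <- order(pos)
    lab <- best$labels[ord, , drop = FALSE]
    carrier <- best$carrier[ord, , drop = FALSE]
    pos <- pos[ord]
    best_is_zw <- identical(best, zw)
    # translate internal labels to report vocabulary for the chosen model
    pretty <- lab
    pretty[lab == "het_parent"] <- if (best_is_zw) "maternal" else "paternal"
    pretty[lab == "hom_parent"] <- if (best_is_zw) "paternal" else "maternal"
    pretty[lab == "specific_homozygous"] <- "homozygous-specific"
    detail <- data.frame(chrom = gm_f$sites$chrom[best$sites][ord], pos = pos,
                         site_concordance = best$site_concordance[ord],
                         stringsAsFactors = FALSE)
    detail <- cbind(detail, as.data.frame(pretty, stringsAsFactors = FALSE))
    # breakpoints: switches of the oriented carrier state along the map
    for (j in seq_len(ncol(carrier))) {
      l <- carrier[, j]
      known <- which(!is.na(l))
      if (length(known) > 1) {
        sw <- known[which(l[known][-1] != l[known][-length(known)])]
        nxt <- known[match(sw, known) + 1L]
        if (length(sw))
          breakpoints[[off_id[j]]] <-
            data.frame(left = pos[sw], right = pos[nxt])
      }
    }
  }

  structure(list(model = model, concordance = conc,
                 best_site_concordance = conc_best, detail = detail,
                 breakpoints = breakpoints, note = note,
                 n_candidate_sites = length(cand)),
            class = "inheritance_report")
}

#' @export
print.inheritance_report <- function(x, ...) {
  cat(sprintf(
    "inheritance_report: model = %s (pooled concordance XY %.3f / ZW %.3f; best site XY %.3f / ZW %.3f)\n",
    x$model, x$concordance[["XY"]], x$concordance[["ZW"]],
    x$best_site_concordance[["XY"]], x$best_site_concordance[["ZW"]]))
  if (!is.null(x$detail))
    cat(sprintf("  %d informative sites, %d offspring with breakpoints\n",
                nrow(x$detail), length(x$breakpoints)))
  invisible(x)
}

#' Write an association table as TSV
#'
#' Manhattan-plot-ready output: chrom, pos, fst (NA reported as 0), p,
#' significance flag.
#'
#' @param assoc an `association_table`.
#' @param path output file.
#' @param seed,config recorded in the header.
#' @return the path, invisibly.
#' @export
write_association_tsv <- function(assoc, path, seed = NULL, config = NULL) {
  out <- assoc
  out$fst[is.na(out$fst)] <- 0
  write_tsv_with_header(out, path, "family association scan", seed, config)
}
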