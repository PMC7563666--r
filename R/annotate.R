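# Variant effect annotation against gene models and a reference segment,
# set operations on variant lists, and the amh marker-based genotype rule.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

aa3 <- function(aa1) {
  if (aa1 == "*") return("Stop")
  Biostrings::AMINO_ACID_CODE[[aa1]]
}

variant_type <- function(ref, alt) {
  if (grepl(",", alt, fixed = TRUE)) return("deletion")
  rl <- nchar(ref); al <- nchar(alt)
  if (rl == 1 && al == 1) "snp"
  else if (al > rl) "insertion"
  else if (al < rl) "deletion"
  else "complex"
}

# spliced transcript-orientation CDS of one gene as a character string, plus
# the map from genomic (1-based) position to CDS position
gene_cds <- function(genes, g, seq, seq_offset) {
  cds <- genes[genes$gene == g & genes$type == "CDS", , drop = FALSE]
  if (nrow(cds) == 0) return(NULL)
  strand <- cds$strand[1]
  cds <- cds[order(cds$start0), , drop = FALSE]
  pos1 <- unlist(lapply(seq_len(nrow(cds)), function(k)
    (cds$start0[k] + 1):cds$end[k]))            # genomic 1-based, ascending
  idx <- pos1 - (seq_offset - 1)
  stop_if(any(idx < 1) || any(idx > nchar(seq)),
          "CDS extends outside the supplied sequence")
  plus_seq <- paste(strsplit(seq, "")[[1]][idx], collapse = "")
  if (strand == "+") {
    tx <- plus_seq
    cds_pos <- seq_along(pos1)
  } else {
    tx <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(plus_seq)))
    cds_pos <- rev(seq_along(pos1))
  }
  # frame offset from the phase of the transcription-wise first CDS chunk
  first <- if (strand == "+") 1L else nrow(cds)
  phase <- cds$phase[first]
  if (is.na(phase)) phase <- 0L
  list(tx = tx, genomic = pos1, cds_pos = cds_pos, strand = strand,
       phase = phase)
}

#' Annotate a variant with gene context and amino-acid change
#'
#' Assigns the gene and feature context (exon / intron / 5'UTR / 3'UTR /
#' non-coding) of a variant and, for single-nucleotide variants in coding
#' sequence, rebuilds the affected codon honoring strand (the spliced CDS is
#' reverse-complemented for antisense genes) and reports the amino-acid
#' change in three-letter code (empty for synonymous changes).
#'
#' @param pos 1-based genomic position.
#' @param ref,alt reference and alternate alleles (genomic strand).
#' @param genes a [gene_models()] object.
#' @param seq reference segment as a character string (or `DNAString`).
#' @param seq_offset 1-based genomic position of the first base of `seq`.
#' @return a 1-row `variant_records` data.frame.
#' @export
annotate_variant <- function(pos, ref, alt, genes, seq, seq_offset = 1L) {
  stop_if(!inherits(genes, "gene_models"), "'genes' must be gene_models")
  seq <- as.character(seq)
  idx <- pos - (seq_offset - 1)
  stop_if(idx < 1 || idx + nchar(ref) - 1 > nchar(seq),
          "variant outside the supplied sequence")
  obs <- substr(seq, idx, idx + nchar(ref) - 1)
  if (!identical(toupper(obs), toupper(ref)))
    warning(sprintf("reference mismatch at %d: sequence has %s, record says %s",
                    pos, obs, ref))

  p0 <- pos - 1   # internal coordinate
  spans <- gene_spans(genes)
  hit <- which(spans$start0 <= p0 & spans$end > p0)
  gene <- ""
  context <- "non-coding"
  aa_change <- ""
  if (length(hit) > 0) {
    gene <- spans$gene[hit[1]]
    in_feat <- function(ty) {
      f <- genes[genes$gene == gene & genes$type == ty, , drop = FALSE]
      nrow(f) > 0 && any(f$start0 <= p0 & f$end > p0)
    }
    if (in_feat("five_prime_UTR")) context <- "5'UTR"
    else if (in_feat("three_prime_UTR")) context <- "3'UTR"
    else if (in_feat("CDS")) {
      context <- "exon"
      if (nchar(ref) == 1 && nchar(alt) == 1) {
        cds <- gene_cds(genes, gene, seq, seq_offset)
        j <- match(pos, cds$genomic)
        tp <- cds$cds_pos[j] - cds$phase        # position in reading frame
        if (!is.na(tp) && tp >= 1) {
          codon_i <- (tp - 1) %/% 3
          cstart <- codon_i * 3 + 1 + cds$phase
          if (cstart + 2 <= nchar(cds$tx)) {
            codon_ref <- substr(cds$tx, cstart, cstart + 2)
            tx_alt <- if (cds$strand == "-") COMPLEMENT[[toupper(alt)]] else
              toupper(alt)
            codon_alt <- codon_ref
            substr(codon_alt, tp - cstart + 1, tp - cstart + 1) <- tx_alt
            aa_ref <- Biostrings::GENETIC_CODE[[codon_ref]]
            aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
            if (aa_ref != aa_alt)
              aa_change <- sprintf("%s->%s", aa3(aa_ref), aa3(aa_alt))
          }
        }
      }
    } else if (in_feat("exon")) context <- "exon"
    else context <- "intron"
  }
  variant_records(data.frame(
    pos = pos, ref = ref, alt = alt, length = abs(nchar(ref) - nchar(alt)),
    type = variant_type(ref, alt), gene = gene, context = context,
    aa_change = aa_change, literature = "", stringsAsFactors = FALSE))
}

#' Shared and population-specific variant sets
#'
#' Exact-key intersection and differences of two variant lists keyed by
#' `(pos, ref, alt)`, with summary counts by type and by presence of an
#' amino-acid change.
#'
#' @param setA,setB `variant_records` data.frames.
#' @return list: `shared`, `a_specific`, `b_specific` (rows of `setA`/`setB`)
#'   and `summary` (counts per set by type and amino-acid change).
#' @export
variant_set_ops <- function(setA, setB) {
  stop_if(!inherits(setA, "variant_records") ||
            !inherits(setB, "variant_records"),
          "inputs must be variant_records")
  keyA <- paste(setA$pos, setA$ref, setA$alt)
  keyB <- paste(setB$pos, setB$ref, setB$alt)
  shared <- setA[keyA %in% keyB, , drop = FALSE]
  a_spec <- setA[!(keyA %in% keyB), , drop = FALSE]
  b_spec <- setB[!(keyB %in% keyA), , drop = FALSE]
  summarise <- function(df, label) {
    tab <- table(factor(df$type,
                        levels = c("snp", "complex", "insertion", "deletion")))
    data.frame(set = label, n = nrow(df), snp = tab[["snp"]],
               complex = tab[["complex"]], insertion = tab[["insertion"]],
               deletion = tab[["deletion"]],
               aa_change = sum(nzchar(df$aa_change)),
               stringsAsFactors = FALSE)
  }
  list(shared = shared, a_specific = a_spec, b_specific = b_spec,
       summary = rbind(summarise(shared, "shared"),
                       summarise(a_spec, "A-specific"),
                       summarise(b_spec, "B-specific")))
}

#' Predict sexual genotype from amh marker presence/absence
#'
#' Applies the X/Y marker rule for the three amh copies: presence of the X
#' copy marker (amhX) with either Y-copy marker (amh-delta-Y or amhY) gives
#' XY; absence of amhX with Y-copy evidence gives YY (the supermale test is
#' evaluated first); amhX alone gives XX; and an undetermined amhY with no
#' amh-delta-Y leaves the genotype undetermined (ND). A pattern with no
#' amplification of any marker carries no chromosome evidence and is an
#' error.
#'
#' @param markers data.frame with columns `amhX`, `amhdY` (`"+"`/`"-"`) and
#'   `amhY` (`"+"`/`"-"`/`"ND"`).
#' @return character vector of predicted genotypes: XX, XY, YY or ND.
#' @export
predict_genotype_from_markers <- function(markers) {
  need <- c("amhX", "amhdY", "amhY")
  stop_if(!all(need %in% names(markers)),
          "markers needs columns amhX, amhdY, amhY")
  stop_if(!all(markers$amhX %in% c("+", "-")) ||
            !all(markers$amhdY %in% c("+", "-")) ||
            !all(markers$amhY %in% c("+", "-", "ND")),
          "marker values must be +/- (amhY also ND)")
  x <- markers$amhX == "+"
  dy <- markers$amhdY == "+"
  y <- markers$amhY == "+"
  nd <- markers$amhY == "ND"
  stop_if(any(!x & !dy & !y & !nd),
          "pattern with no marker evidence of any chromosome")
  out <- rep(NA_character_, nrow(markers))
  out[!x & (dy | y)] <- "YY"          # supermale test first
  out[is.na(out) & x & (dy | y)] <- "XY"
  out[is.na(out) & x & !dy & nd] <- "ND"
  out[is.na(out) & x & !dy & !y] <- "XX"
  out
}
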