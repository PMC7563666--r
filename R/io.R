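# Readers and writers for the formats the pipeline touches. Established
# parsers are used where they exist (vcfR for VCF, rtracklayer for GFF3 and
# bedGraph, Biostrings for FASTA); the Popoolation2 sync dialect has no
# installed reader and is parsed here. Writers emit plain text with a
# seed/config header so every artefact is reproducible.

# ---- VCF -------------------------------------------------------------------

#' Read a family genotype VCF with site filters
#'
#' Parses a VCF (GT required, DP optional; other FORMAT fields are ignored)
#' and applies the two standard site filters used for family RAD data: drop
#' sites with more than `max_alleles` alleles and sites whose mean read
#' depth across called individuals is below `min_mean_depth`. Removal counts
#' are reported via `message()`. Half-missing calls (e.g. `./1`) are treated
#' as missing.
#'
#' @param path VCF file.
#' @param sex_map data.frame (or TSV path) with columns `id`, `sex`
#'   (male/female), `role` (sire/dam/offspring) covering all samples.
#' @param max_alleles maximum number of alleles per retained site.
#' @param min_mean_depth minimum mean DP per retained site (0 disables; sites
#'   without DP are kept).
#' @return a [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path, sex_map, max_alleles = 2,
                              min_mean_depth = 5) {
  stop_if(!file.exists(path), sprintf("no such file: %s", path))
  # structural pre-check so malformed lines are reported by line number
  lines <- readLines(path)
  hdr <- grep("^#CHROM\t", lines)
  stop_if(length(hdr) != 1L, "not a VCF: missing #CHROM header line")
  nfield <- length(strsplit(lines[hdr], "\t", fixed = TRUE)[[1]])
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  bad <- body[vapply(strsplit(lines[body], "\t", fixed = TRUE),
                     length, 1L) != nfield]
  stop_if(length(bad) > 0,
          sprintf("malformed VCF line %d: expected %d fields", bad[1], nfield))

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix))

  n_alleles <- 1L + ifelse(is.na(fix$ALT) | fix$ALT == ".", 0L,
                           lengths(strsplit(fix$ALT, ",", fixed = TRUE)))
  keep_allele <- n_alleles <= max_alleles
  mean_dp <- if (is.null(dp)) rep(NA_real_, nrow(fix)) else
    rowMeans(dp, na.rm = TRUE)
  keep_depth <- is.na(mean_dp) | mean_dp >= min_mean_depth
  message(sprintf(
    "read_genotype_vcf: %d sites; removed %d with > %s alleles, %d with mean depth < %s",
    nrow(fix), sum(!keep_allele), format(max_alleles),
    sum(keep_allele & !keep_depth), format(min_mean_depth)))
  keep <- keep_allele & keep_depth
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  dp <- if (is.null(dp)) NULL else dp[keep, , drop = FALSE]

  parse_allele <- function(gt_chr, which) {
    al <- sub(if (which == 1L) "^([0-9.]+)[/|].*$" else "^.*[/|]([0-9.]+)$",
              "\\1", gt_chr)
    al[!grepl("[/|]", gt_chr)] <- NA
    suppressWarnings(as.integer(al))
  }
  a1 <- matrix(parse_allele(gt, 1L), nrow = nrow(fix))
  a2 <- matrix(parse_allele(gt, 2L), nrow = nrow(fix))
  half_missing <- xor(is.na(a1), is.na(a2))
  a1[half_missing] <- NA_integer_
  a2[half_missing] <- NA_integer_

  if (is.character(sex_map)) sex_map <- read_tsv_skip_comments(sex_map)
  samples <- colnames(gt)
  idx <- match(samples, sex_map$id)
  stop_if(anyNA(idx), "sex_map does not cover all VCF samples")
  ind <- data.frame(id = samples, sex = sex_map$sex[idx],
                    role = sex_map$role[idx], stringsAsFactors = FALSE)
  dpm <- if (is.null(dp)) NULL else {
    m <- dp; m[is.na(m)] <- 0L; storage.mode(m) <- "integer"; m
  }
  ord <- order(fix$CHROM, as.numeric(fix$POS))
  genotype_matrix(
    sites = data.frame(chrom = fix$CHROM[ord], pos = as.numeric(fix$POS[ord]),
                       ref = fix$REF[ord], alt = fix$ALT[ord],
                       stringsAsFactors = FALSE),
    a1 = a1[ord, , drop = FALSE], a2 = a2[ord, , drop = FALSE],
    depth = if (is.null(dpm)) NULL else dpm[ord, , drop = FALSE],
    individuals = ind)
}

#' Write a genotype matrix as VCFv4.2
#'
#' Emits GT and DP for one chromosome; the generating seed is recorded in the
#' header.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_genotype_vcf <- function(gm, path) {
  stop_if(!inherits(gm, "genotype_matrix"), "'gm' must be a genotype_matrix")
  geno <- matrix(
    ifelse(is.na(gm$a1), "./.", paste0(gm$a1, "/", gm$a2)),
    nrow = nrow(gm$sites))
  body <- cbind(gm$sites$chrom, format(gm$sites$pos, scientific = FALSE,
                                       trim = TRUE),
                ".", gm$sites$ref, gm$sites$alt,
                ".", "PASS", ".", "GT:DP",
                matrix(paste0(geno, ":", gm$depth), nrow = nrow(gm$sites)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##source=sexscan seed=%s", gm$seed),
               sprintf("##contig=<ID=%s>", unique(gm$sites$chrom)),
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$individuals$id), collapse = "\t")),
             con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- Popoolation2 sync ------------------------------------------------------

SYNC_BASES <- c("A", "T", "C", "G")  # column order A:T:C:G:N:del

#' Read a Popoolation2 sync file into pool counts
#'
#' Expects the two-pool dialect `chrom pos ref femalePool malePool` where
#' each pool column is `A:T:C:G:N:del` read counts. The alternate allele at
#' each site is taken as the non-reference base with the highest summed
#' count across pools; sites where no counted base differs from the
#' reference (or whose reference is not A/C/G/T) are dropped with a warning.
#'
#' @param path sync file (comment lines starting with `#` are ignored).
#' @return a [pool_counts()].
#' @export
read_sync <- function(path) {
  stop_if(!file.exists(path), sprintf("no such file: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    warning("empty sync file")
    return(pool_counts(data.frame(chrom = character(), pos = numeric(),
                                  ref = character(), alt = character(),
                                  f_ref = integer(), f_alt = integer(),
                                  m_ref = integer(), m_alt = integer())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  stop_if(any(nf != 5L),
          sprintf("sync column count mismatch on line %d: expected 5 fields",
                  which(nf != 5L)[1]))
  m <- do.call(rbind, fields)
  parse_pool <- function(col) {
    cnt <- do.call(rbind, strsplit(col, ":", fixed = TRUE))
    stop_if(ncol(cnt) != 6L, "pool columns must be A:T:C:G:N:del")
    matrix(as.integer(cnt), ncol = 6L)
  }
  fp <- parse_pool(m[, 4]); mp <- parse_pool(m[, 5])
  ref <- toupper(m[, 3])
  ref_i <- match(ref, SYNC_BASES)
  tot <- fp[, 1:4] + mp[, 1:4]
  if (length(ref_i) == 1L) tot <- matrix(tot, nrow = 1L)
  alt_i <- integer(nrow(tot))
  for (i in seq_len(nrow(tot))) {
    cand <- setdiff(order(tot[i, ], decreasing = TRUE), ref_i[i])
    alt_i[i] <- if (length(cand) && tot[i, cand[1]] > 0) cand[1] else NA_integer_
  }
  drop <- is.na(ref_i) | is.na(alt_i)
  if (any(drop))
    warning(sprintf("dropped %d site(s) without a countable alternate allele",
                    sum(drop)))
  keep <- which(!drop)
  idx <- cbind(keep, ref_i[keep]); adx <- cbind(keep, alt_i[keep])
  pool_counts(data.frame(
    chrom = m[keep, 1], pos = as.numeric(m[keep, 2]),
    ref = ref[keep], alt = SYNC_BASES[alt_i[keep]],
    f_ref = fp[idx], f_alt = fp[adx],
    m_ref = mp[idx], m_alt = mp[adx], stringsAsFactors = FALSE))
}

#' Write pool counts as a Popoolation2 sync file
#'
#' Two pool columns, female then male, in `A:T:C:G:N:del` order.
#'
#' @param pc a [pool_counts()].
#' @param path output file.
#' @param seed optional seed recorded in a header comment.
#' @return the path, invisibly.
#' @export
write_sync <- function(pc, path, seed = NULL) {
  stop_if(!inherits(pc, "pool_counts"), "'pc' must be pool_counts")
  pool_col <- function(ref, alt, nref, nalt) {
    cnt <- matrix(0L, nrow = length(ref), ncol = 6L)
    cnt[cbind(seq_along(ref), match(ref, SYNC_BASES))] <- nref
    cnt[cbind(seq_along(alt), match(alt, SYNC_BASES))] <- nalt
    apply(cnt, 1L, paste, collapse = ":")
  }
  out <- paste(pc$chrom, format(pc$pos, scientific = FALSE, trim = TRUE),
               pc$ref,
               pool_col(pc$ref, pc$alt, pc$f_ref, pc$f_alt),
               pool_col(pc$ref, pc$alt, pc$m_ref, pc$m_alt), sep = "\t")
  writeLines(c(artefact_header("sync pools=female,male", seed), out), path)
  invisible(path)
}

# ---- bedGraph ---------------------------------------------------------------

#' Write a depth profile as bedGraph
#'
#' @param profile a [depth_profile()].
#' @param path output file.
#' @param name track name.
#' @return the path, invisibly.
#' @export
write_bedgraph <- function(profile, path, name = attr(profile, "pool")) {
  stop_if(!inherits(profile, "depth_profile"), "'profile' must be a depth_profile")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"",
                     ifelse(is.na(name), "depth", name)), con)
  with_plain_numbers(
    utils::write.table(profile[c("chrom", "start", "end", "depth")], con,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE))
  invisible(path)
}

#' Read a bedGraph depth track
#'
#' @param path bedGraph file.
#' @param pool,population optional labels attached to the profile.
#' @return a [depth_profile()] (bins 0-based half-open, as in the file).
#' @export
read_depth_bedgraph <- function(path, pool = NA_character_,
                                population = NA_character_) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  depth_profile(data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # back to 0-based half-open
    end = GenomicRanges::end(gr),
    depth = gr$score, stringsAsFactors = FALSE),
    pool = pool, population = population)
}

# ---- GFF3 gene models -------------------------------------------------------

#' Gene models from feature intervals
#'
#' @param df data.frame with `gene`, `type` (one of exon, CDS,
#'   five_prime_UTR, three_prime_UTR), `start`, `end` (1-based inclusive),
#'   `strand` (`+`/`-`), and `phase` (CDS only; NA otherwise).
#' @return an object of class `gene_models`: the feature table with
#'   coordinates converted to 0-based half-open `start0`/`end`.
#' @export
gene_models <- function(df) {
  need <- c("gene", "type", "start", "end", "strand")
  stop_if(!all(need %in% names(df)), paste("gene_models needs columns:",
                                           paste(need, collapse = ", ")))
  stop_if(!all(df$type %in% c("exon", "CDS", "five_prime_UTR",
                              "three_prime_UTR")),
          "feature type must be exon, CDS, five_prime_UTR or three_prime_UTR")
  stop_if(!all(df$strand %in% c("+", "-")), "strand must be + or -")
  if (is.null(df$phase)) df$phase <- NA_integer_
  conv <- coords_file_to_internal(df$start, df$end)
  out <- data.frame(gene = df$gene, type = df$type, start0 = conv$start,
                    end = conv$end, strand = df$strand, phase = df$phase,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$start0), ]
  rownames(out) <- NULL
  structure(out, class = c("gene_models", "data.frame"))
}

#' Read gene models from GFF3
#'
#' Imports exon/CDS/UTR features with rtracklayer and assigns each to its
#' gene by walking `Parent` attributes up to the enclosing `gene` record
#' (gene `Name` preferred over `ID` for labels).
#'
#' @param path GFF3 file.
#' @return a [gene_models()] object.
#' @export
read_gff_genes <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- as.data.frame(gr)
  id2gene <- new.env(parent = emptyenv())
  label_of <- function(row) {
    nm <- meta$Name[row]
    if (!is.null(nm) && !is.na(nm) && nzchar(nm)) nm else meta$ID[row]
  }
  genes <- which(meta$type == "gene")
  for (g in genes) assign(meta$ID[g], label_of(g), envir = id2gene)
  # map transcript-level IDs to their gene
  trans <- which(meta$type %in% c("mRNA", "transcript"))
  for (t in trans) {
    par <- unlist(meta$Parent[t])[1]
    if (!is.null(par) && exists(par, envir = id2gene))
      assign(meta$ID[t], get(par, envir = id2gene), envir = id2gene)
  }
  keep <- which(meta$type %in% c("exon", "CDS", "five_prime_UTR",
                                 "three_prime_UTR"))
  gene_of <- vapply(keep, function(i) {
    par <- unlist(meta$Parent[i])[1]
    if (!is.null(par) && exists(par, envir = id2gene))
      get(par, envir = id2gene) else NA_character_
  }, "")
  ph <- if ("phase" %in% names(meta)) suppressWarnings(as.integer(meta$phase[keep]))
        else NA_integer_
  gene_models(data.frame(
    gene = gene_of, type = as.character(meta$type[keep]),
    start = meta$start[keep], end = meta$end[keep],
    strand = as.character(meta$strand[keep]), phase = ph,
    stringsAsFactors = FALSE))
}

# ---- FASTA ------------------------------------------------------------------

#' Read a reference segment from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] returning the first
#' (or named) sequence as a character string for [annotate_variant()].
#'
#' @param path FASTA file.
#' @param which sequence name or index (default: first).
#' @return a character string, with the sequence name as `names()`.
#' @export
read_reference_fasta <- function(path, which = 1L) {
  seqs <- Biostrings::readDNAStringSet(path)
  stop_if(length(seqs) == 0, "no sequences in FASTA")
  out <- as.character(seqs[[which]])
  names(out) <- names(seqs)[if (is.numeric(which)) which else
    match(which, names(seqs))]
  out
}

# ---- packaged fixtures ------------------------------------------------------

#' Read a packaged reference table
#'
#' Curated plain-text tables of published results for the Kpandu (Lake
#' Volta) and Koka (Lake Koka) wild Nile tilapia populations:
#' \describe{
#'   \item{`markers`}{grouped amh X/Y marker presence/absence patterns with
#'     phenotypic sex and group sizes.}
#'   \item{`sv`}{structural variants (duplication/deletions) of the LG23
#'     oaz1--dot1l region with breakpoint confidence intervals, as
#'     [sv_records()].}
#'   \item{`variants`}{SNPs and small indels between males and females in the
#'     same region, with gene context and amino-acid changes, as
#'     `variant_records`.}
#' }
#'
#' @param name one of `"markers"`, `"sv"`, `"variants"`.
#' @return a typed data.frame (see Details).
#' @export
read_table_fixture <- function(name = c("markers", "sv", "variants")) {
  name <- match.arg(name)
  f <- switch(name,
              markers = "amh_marker_genotypes.tsv",
              sv = "lg23_sv_calls.tsv",
              variants = "lg23_y_variants.tsv")
  path <- system.file("extdata", f, package = "sexscan", mustWork = TRUE)
  df <- read_tsv_skip_comments(path)
  switch(name,
         markers = df,
         sv = sv_records(df$population, df$start, df$end, df$ci, df$type,
                         df$shared == "yes"),
         variants = variant_records(df))
}

#' Typed variant records
#'
#' @param df data.frame with `pos`, `ref`, `alt`, `type` (snp / complex /
#'   insertion / deletion), `gene`, `context`, and optional `aa_change` and
#'   `literature` columns.
#' @return an object of class `variant_records` (a data.frame).
#' @export
variant_records <- function(df) {
  need <- c("pos", "ref", "alt", "type", "gene", "context")
  stop_if(!all(need %in% names(df)), paste("variant_records needs columns:",
                                           paste(need, collapse = ", ")))
  stop_if(!all(df$type %in% c("snp", "complex", "insertion", "deletion")),
          "variant type must be snp, complex, insertion or deletion")
  simple <- !grepl(",", df$alt, fixed = TRUE)
  rl <- nchar(df$ref[simple]); al <- nchar(df$alt[simple])
  ty <- df$type[simple]
  stop_if(any(ty == "snp" & !(rl == 1 & al == 1)) ||
            any(ty == "insertion" & al <= rl) ||
            any(ty == "deletion" & al >= rl),
          "variant type inconsistent with ref/alt lengths")
  if (is.null(df$aa_change)) df$aa_change <- ""
  if (is.null(df$literature)) df$literature <- ""
  class(df) <- c("variant_records", "data.frame")
  df
}
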