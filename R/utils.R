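#' @keywords internal
"_PACKAGE"

# Internal argument checks ----------------------------------------------------

stop_if <- function(cond, ..., call. = FALSE) {
  if (isTRUE(cond)) stop(..., call. = call.)
}

check_count <- function(x, name, min = 1L) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
            x != floor(x),
          sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

check_prob <- function(x, name) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1,
          sprintf("'%s' must be a single probability in [0, 1]", name))
  as.numeric(x)
}

check_pos_num <- function(x, name) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0,
          sprintf("'%s' must be a single positive number", name))
  as.numeric(x)
}

#' Convert between file (1-based inclusive) and internal (0-based half-open)
#' coordinates
#'
#' All on-disk formats handled by the package (VCF, sync, GFF3, BED-derived
#' bedGraph intervals are already half-open) use 1-based inclusive positions;
#' internally every interval is 0-based half-open. These two helpers are the
#' single audited conversion point.
#'
#' @param start,end interval bounds.
#' @return a list with `start` and `end` in the other convention.
#' @export
coords_file_to_internal <- function(start, end) {
  stop_if(any(end < start), "interval end before start")
  list(start = start - 1, end = end)
}

#' @rdname coords_file_to_internal
#' @export
coords_internal_to_file <- function(start, end) {
  stop_if(any(end < start), "interval end before start")
  list(start = start + 1, end = end)
}

# Header written on every text artefact so a run can be reproduced.
artefact_header <- function(what, seed = NULL, config = NULL) {
  cfg <- if (is.null(config)) "" else
    paste(sprintf("%s=%s", names(config), unlist(config)), collapse = " ")
  c(sprintf("# sexscan %s", what),
    sprintf("# seed=%s %s", ifelse(is.null(seed), "NA", seed), cfg))
}

# Evaluate a writer with plain (non-scientific) number formatting, so
# genomic coordinates never serialise as "3.45e+07".
with_plain_numbers <- function(expr) {
  old <- options(scipen = 15)
  on.exit(options(old))
  force(expr)
}

#' Write a TSV artefact with a reproducibility header
#'
#' All tabular outputs of the pipeline carry two comment lines recording
#' what the artefact is and the seed/configuration that produced it, so any
#' file can be regenerated exactly.
#'
#' @param df data.frame to write.
#' @param path output file.
#' @param what one-line description of the artefact.
#' @param seed,config seed and named configuration list for the header.
#' @return the path, invisibly.
#' @export
write_tsv_with_header <- function(df, path, what, seed = NULL, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  with_plain_numbers({
    writeLines(artefact_header(what, seed, config), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  })
  invisible(path)
}

read_tsv_skip_comments <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    quote = "", fill = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
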