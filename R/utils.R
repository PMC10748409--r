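# Coordinate conventions: all interval arithmetic inside the package is
# 0-based half-open [start, end); user-facing tables carry 1-based `pos`
# columns.  These two helpers are the only conversion points.

pos1_to_off0 <- function(pos) pos - 1L

off0_to_pos1 <- function(off) off + 1L

#' Construct a genomic interval tibble
#'
#' Intervals are 0-based, half-open (`start < end`), the convention used
#' internally by every interval operation in the package and by BED output.
#'
#' @param chrom Chromosome name(s).
#' @param start 0-based start(s).
#' @param end Half-open end(s), strictly greater than `start`.
#' @param strand `"+"` or `"-"` (default `"+"`).
#' @return A tibble with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  start <- as.integer(start)
  end <- as.integer(end)
  if (any(start < 0L) || any(start >= end)) {
    abort("genomic_interval requires 0 <= start < end")
  }
  tibble(chrom = as.character(chrom), start = start, end = end,
         strand = rep_len(strand, length(chrom)))
}

# Overlap width of one interval [s1,e1) with a set of intervals, in bp,
# counting each base at most once (intervals are unioned first).
interval_overlap_bp <- function(s1, e1, starts, ends) {
  if (length(starts) == 0L) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start = starts + 1L, end = ends))
  q <- IRanges::IRanges(start = s1 + 1L, end = e1)
  sum(IRanges::width(IRanges::pintersect(
    IRanges::findOverlapPairs(q, ir)
  )))
}

# seeded evaluation without touching the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive a stream-specific 31-bit sub-seed from a master seed
sub_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + stream * 12979L) %% 2147483647
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Accepts a FASTA path, a named character vector of sequences, or a
# DNAStringSet; returns a DNAStringSet.
as_genome <- function(x) {
  if (methods::is(x, "DNAStringSet")) return(x)
  if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
      file.exists(x)) {
    return(Biostrings::readDNAStringSet(x))
  }
  if (is.character(x)) {
    if (is.null(names(x))) abort("genome sequences must be named")
    return(Biostrings::DNAStringSet(x))
  }
  abort("cannot interpret genome input")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Read a tab-separated table with a required header
#'
#' Thin wrapper over [readr::read_tsv()] that reports the offending file on
#' failure and checks required columns.
#'
#' @param path File path.
#' @param required Character vector of required column names.
#' @return A tibble.
#' @export
read_tsv_checked <- function(path, required = character()) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  x <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) {
      abort(paste0("failed to parse ", path, ": ", conditionMessage(e)))
    }
  )
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("file ", path, " lacks required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  x
}

write_tsv_quiet <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}
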