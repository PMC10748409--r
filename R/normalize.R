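# Left-alignment and parsimony normalization of variant representations
# (the standard algorithm: trim shared trailing bases, extending left with
# the preceding reference base whenever an allele would empty, then trim
# shared leading bases).

genome_base <- function(genome, chrom, pos) {
  substring(genome[[chrom]], pos, pos)
}

#' Normalize one variant to its left-aligned, parsimonious form
#'
#' @param genome Named character vector (or `DNAStringSet`) of reference
#'   sequences.
#' @param chrom,pos,ref,alt Variant (1-based `pos`); `ref` must match the
#'   reference.
#' @return One-row tibble `chrom`, `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(genome, chrom, pos, ref, alt) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!chrom %in% names(genome)) {
    abort(paste0("chromosome ", chrom, " not in reference"))
  }
  if (substring(genome[[chrom]], pos, pos + nchar(ref) - 1L) != ref) {
    abort(paste0("REF mismatch at ", chrom, ":", pos, " (", ref, ")"))
  }
  last <- function(x) substring(x, nchar(x), nchar(x))
  # trim shared trailing bases, extending left as needed
  repeat {
    if (nchar(ref) > 0L && nchar(alt) > 0L && last(ref) == last(alt)) {
      ref <- substring(ref, 1L, nchar(ref) - 1L)
      alt <- substring(alt, 1L, nchar(alt) - 1L)
      if (nchar(ref) == 0L || nchar(alt) == 0L) {
        if (pos <= 1L) {
          abort(paste0("cannot left-extend past start of ", chrom))
        }
        pos <- pos - 1L
        b <- genome_base(genome, chrom, pos)
        ref <- paste0(b, ref)
        alt <- paste0(b, alt)
      }
    } else break
  }
  # trim shared leading bases
  while (nchar(ref) >= 2L && nchar(alt) >= 2L &&
         substring(ref, 1L, 1L) == substring(alt, 1L, 1L)) {
    ref <- substring(ref, 2L)
    alt <- substring(alt, 2L)
    pos <- pos + 1L
  }
  tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt)
}

#' Normalize a call table
#'
#' Applies [normalize_variant()] row-wise, preserving all other columns.
#'
#' @param calls Tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param genome Reference sequences.
#' @return `calls` with normalized `pos`, `ref`, `alt`.
#' @export
normalize_calls <- function(calls, genome) {
  if (nrow(calls) == 0) return(calls)
  norm <- list_rbind(map(seq_len(nrow(calls)), function(i) {
    normalize_variant(genome, calls$chrom[i], calls$pos[i],
                      calls$ref[i], calls$alt[i])
  }))
  calls$pos <- norm$pos
  calls$ref <- norm$ref
  calls$alt <- norm$alt
  calls
}

# Inverse of normalization for simulation: shift a variant representation
# to the right `steps` times (append the following reference base to both
# alleles; drop a shared leading base when possible).  Every intermediate
# representation stays equivalent to the input.
denormalize_variant <- function(genome, chrom, pos, ref, alt, steps = 1L) {
  if (methods::is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  len <- nchar(genome[[chrom]])
  for (s in seq_len(steps)) {
    nxt <- pos + nchar(ref)
    if (nxt > len) break
    b <- genome_base(genome, chrom, nxt)
    ref <- paste0(ref, b)
    alt <- paste0(alt, b)
    if (substring(ref, 1L, 1L) == substring(alt, 1L, 1L) &&
        nchar(ref) >= 2L && nchar(alt) >= 2L) {
      ref <- substring(ref, 2L)
      alt <- substring(alt, 2L)
      pos <- pos + 1L
    }
  }
  tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt)
}
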