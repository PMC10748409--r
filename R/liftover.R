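# Cross-species conservation assessment of SNP-centered windows: extract a
# window around each SNP, lift it through a chain file, and judge
# conservation from a global pairwise alignment of the source window and the
# lifted target sequence.

#' Window around a SNP position
#'
#' A window of `2 * flank` bases nominally centered on the SNP: `flank` bases
#' of left flank, `flank - 1` of right flank, so the SNP base sits at 0-based
#' offset `flank` of a `2 * flank`-long window.  Windows running off a
#' chromosome end are truncated and flagged.
#'
#' @param chrom Chromosome name.
#' @param pos 1-based SNP position.
#' @param flank Left-flank width in bp (default 50, i.e. a 100-bp window).
#' @param chrom_length Optional chromosome length for right truncation.
#' @return One-row tibble: `chrom`, `start`, `end` (0-based half-open),
#'   `snp_offset` (0-based offset of the SNP base inside the window) and
#'   `truncated`.
#' @export
window_around <- function(chrom, pos, flank = 50L, chrom_length = NULL) {
  pos0 <- pos1_to_off0(pos)
  start <- pos0 - flank
  end <- pos0 + flank
  truncated <- FALSE
  if (start < 0L) { start <- 0L; truncated <- TRUE }
  if (!is.null(chrom_length) && end > chrom_length) {
    end <- as.integer(chrom_length)
    truncated <- TRUE
  }
  if (truncated) {
    warn(paste0("window around ", chrom, ":", pos,
                " truncated at chromosome bounds"))
  }
  tibble(chrom = as.character(chrom), start = as.integer(start),
         end = as.integer(end), snp_offset = as.integer(pos0 - start),
         truncated = truncated)
}

dna_subst_matrix <- function(match = 1, mismatch = -1) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m
}

check_dna <- function(x, label) {
  if (grepl("[^ACGTN]", x)) {
    abort(paste0(label, " contains non-DNA symbols (expected A/C/G/T/N)"))
  }
}

#' Global pairwise alignment of two DNA sequences
#'
#' Needleman-Wunsch global alignment with simple scoring: match `+1`,
#' mismatch `-1`, linear gap `-2` by default (configurable), end gaps
#' penalized.  Delegates the dynamic programming to
#' [Biostrings::pairwiseAlignment()].
#'
#' @param source_seq,target_seq Uppercase DNA strings (N allowed).
#' @param match,mismatch,gap Scoring parameters.
#' @return A list of class `pairwise_alignment` with elements `source`
#'   and `target` (equal-length aligned rows with `-` gaps) and `score`.
#' @export
align_pair <- function(source_seq, target_seq, match = 1, mismatch = -1,
                       gap = -2) {
  check_dna(source_seq, "source sequence")
  check_dna(target_seq, "target sequence")
  n1 <- nchar(source_seq)
  n2 <- nchar(target_seq)
  if (n1 == 0L || n2 == 0L) {
    out <- list(
      source = paste0(source_seq, strrep("-", n2)),
      target = paste0(strrep("-", n1), target_seq),
      score = gap * (n1 + n2)
    )
    class(out) <- "pairwise_alignment"
    return(out)
  }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(source_seq), Biostrings::DNAString(target_seq),
    type = "global",
    substitutionMatrix = dna_subst_matrix(match, mismatch),
    gapOpening = 0, gapExtension = -gap
  )
  out <- list(
    source = as.character(Biostrings::alignedPattern(pa)),
    target = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa)
  )
  class(out) <- "pairwise_alignment"
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise alignment, score", x$score, "\n")
  cat(" ", x$source, "\n ", x$target, "\n")
  invisible(x)
}

# Alignment column index (1-based) holding the k-th (0-based) source base.
alignment_column_of <- function(aligned_source, source_offset) {
  chars <- strsplit(aligned_source, "")[[1]]
  nongap <- cumsum(chars != "-")
  which(nongap == source_offset + 1L & chars != "-")[1]
}

#' Classify a SNP's cross-species conservation status
#'
#' Applies, in order: `too_long` when the lifted target sequence exceeds
#' `max_target_len`; `unplaced` when the target chromosome name matches
#' `unplaced_pattern`; `gap_at_snp` when, in the global alignment of the two
#' windows, the column carrying the source SNP base holds a gap in the
#' target row; otherwise `conserved`.
#'
#' @param source_seq Source window sequence.
#' @param target_seq Lifted target sequence (`NA` if lifting failed).
#' @param snp_offset 0-based offset of the SNP base in `source_seq`.
#' @param target_chrom Target chromosome name (`NA` if lifting failed).
#' @param max_target_len Maximum accepted target-sequence length
#'   (default 1000 bp).
#' @param unplaced_pattern Regular expression identifying unplaced contigs
#'   (default `"^chrUn"`).
#' @return Status string: one of `"no_ortholog"`, `"too_long"`,
#'   `"unplaced"`, `"gap_at_snp"`, `"conserved"`.
#' @export
classify_snp <- function(source_seq, target_seq, snp_offset,
                         target_chrom = NA_character_,
                         max_target_len = 1000L,
                         unplaced_pattern = "^chrUn") {
  if (is.na(target_seq)) return("no_ortholog")
  if (snp_offset < 0L || snp_offset >= nchar(source_seq)) {
    abort("snp_offset outside the source window")
  }
  if (nchar(target_seq) > max_target_len) return("too_long")
  if (!is.na(target_chrom) && str_detect(target_chrom, unplaced_pattern)) {
    return("unplaced")
  }
  aln <- align_pair(source_seq, target_seq)
  col <- alignment_column_of(aln$source, snp_offset)
  if (substr(aln$target, col, col) == "-") "gap_at_snp" else "conserved"
}

#' Run the ortholog-mapping and conservation cascade
#'
#' For each SNP: build its window, extract the source sequence, lift the
#' window through the chain index, extract the lifted target sequence
#' (reverse-complemented for minus-strand chains so both rows share the
#' source orientation), and classify conservation.
#'
#' @param snps Tibble with `rsid`, `chrom`, `pos` (1-based).
#' @param source_genome,target_genome `DNAStringSet` objects or FASTA paths.
#' @param chains Chain index from [read_chain()], or a chain file path.
#' @param flank Window flank (default 50).
#' @param min_mapped_fraction Passed to [lift_interval()].
#' @param max_target_len,unplaced_pattern Passed to [classify_snp()].
#' @return A tibble with one row per SNP: `rsid`, `chrom`, `pos`, `status`,
#'   and target locus columns `target_chrom`, `target_start`, `target_end`
#'   (1-based inclusive; NA where lifting failed), `target_strand`,
#'   `target_pos` (1-based position of the base aligned to the SNP, NA if
#'   not conserved).
#' @export
run_ortholog_cascade <- function(snps, source_genome, target_genome, chains,
                                 flank = 50L, min_mapped_fraction = 0.95,
                                 max_target_len = 1000L,
                                 unplaced_pattern = "^chrUn") {
  source_genome <- as_genome(source_genome)
  target_genome <- as_genome(target_genome)
  names(source_genome) <- sub("\\s.*$", "", names(source_genome))
  names(target_genome) <- sub("\\s.*$", "", names(target_genome))
  if (is.character(chains)) chains <- read_chain(chains)

  one <- function(rsid, chrom, pos) {
    res <- tibble(rsid = rsid, chrom = chrom, pos = pos,
                  status = NA_character_, target_chrom = NA_character_,
                  target_start = NA_integer_, target_end = NA_integer_,
                  target_strand = NA_character_, target_pos = NA_integer_)
    if (!chrom %in% names(source_genome)) {
      res$status <- "no_ortholog"
      return(res)
    }
    win <- suppressWarnings(
      window_around(chrom, pos, flank,
                    chrom_length = Biostrings::width(source_genome[chrom]))
    )
    src <- as.character(Biostrings::subseq(source_genome[[chrom]],
                                           win$start + 1L, win$end))
    lift <- lift_interval(chains, win, min_mapped_fraction)
    if (lift$status != "lifted") {
      res$status <- "no_ortholog"
      return(res)
    }
    res$target_chrom <- lift$chrom
    res$target_start <- lift$start + 1L
    res$target_end <- lift$end
    res$target_strand <- lift$strand
    tgt_len <- lift$end - lift$start
    if (tgt_len > max_target_len) {
      res$status <- "too_long"
      return(res)
    }
    tgt <- as.character(Biostrings::subseq(target_genome[[lift$chrom]],
                                           lift$start + 1L, lift$end))
    if (lift$strand == "-") tgt <- revcomp(tgt)
    res$status <- classify_snp(src, tgt, win$snp_offset,
                               target_chrom = lift$chrom,
                               max_target_len = max_target_len,
                               unplaced_pattern = unplaced_pattern)
    if (res$status == "conserved") {
      aln <- align_pair(src, tgt)
      col <- alignment_column_of(aln$source, win$snp_offset)
      tchars <- substr(aln$target, 1L, col)
      toff <- sum(strsplit(tchars, "")[[1]] != "-") - 1L
      res$target_pos <- if (lift$strand == "-") {
        lift$end - toff
      } else {
        lift$start + toff + 1L
      }
    }
    res
  }
  out <- list_rbind(pmap(list(snps$rsid, snps$chrom, snps$pos), one))
  out
}

#' Tabulate cascade statuses
#'
#' @param cascade Result of [run_ortholog_cascade()].
#' @return A tibble of `status` and `n`, with every status level present.
#' @export
cascade_counts <- function(cascade) {
  levels <- c("conserved", "no_ortholog", "too_long", "unplaced",
              "gap_at_snp")
  out <- count(cascade, status = factor(.data$status, levels = levels),
               .drop = FALSE)
  mutate(out, status = as.character(.data$status))
}
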