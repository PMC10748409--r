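# UCSC chain files describe pairwise genome alignments as runs of ungapped
# blocks.  Header fields (all 0-based half-open):
#   chain score tName tSize tStrand tStart tEnd qName qSize qStrand qStart qEnd id
# followed by block lines `size dt dq` and a final bare `size`.
# Coordinates on the q side are expressed on the q strand; for qStrand == "-"
# they count from the chromosome end.

#' Read a UCSC chain file into a chain index
#'
#' @param path Path to a chain file.
#' @return A tibble with one row per chain: `chain_id`, `score`, `t_name`,
#'   `t_size`, `t_start`, `t_end`, `q_name`, `q_size`, `q_strand`, `q_start`,
#'   `q_end`, and a `blocks` list-column of tibbles (`t_start`, `q_start`,
#'   `size`), all 0-based with `q_start` in q-strand coordinates.
#' @export
read_chain <- function(path) {
  lines <- readLines(path)
  chains <- list()
  i <- 1L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (line == "") { i <- i + 1L; next }
    if (!startsWith(line, "chain ")) {
      abort(paste0("malformed chain file ", path, " at line ", i,
                   ": expected 'chain' header"))
    }
    f <- strsplit(line, "[ \t]+")[[1]]
    if (length(f) < 12L) {
      abort(paste0("malformed chain header at line ", i, " of ", path))
    }
    hdr <- list(
      score = as.numeric(f[2]),
      t_name = f[3], t_size = as.integer(f[4]),
      t_strand = f[5], t_start = as.integer(f[6]), t_end = as.integer(f[7]),
      q_name = f[8], q_size = as.integer(f[9]),
      q_strand = f[10], q_start = as.integer(f[11]), q_end = as.integer(f[12]),
      chain_id = if (length(f) >= 13L) f[13] else as.character(length(chains) + 1L)
    )
    if (hdr$t_strand != "+") {
      abort(paste0("chain at line ", i, ": t strand must be '+'"))
    }
    # block lines
    t_off <- hdr$t_start
    q_off <- hdr$q_start
    sizes <- integer(); t_starts <- integer(); q_starts <- integer()
    repeat {
      i <- i + 1L
      if (i > length(lines)) abort(paste0("truncated chain in ", path))
      bl <- trimws(lines[i])
      if (bl == "") abort(paste0("truncated chain block list at line ", i))
      b <- suppressWarnings(as.integer(strsplit(bl, "[ \t]+")[[1]]))
      if (any(is.na(b))) {
        abort(paste0("malformed chain block at line ", i, " of ", path))
      }
      sizes <- c(sizes, b[1])
      t_starts <- c(t_starts, t_off)
      q_starts <- c(q_starts, q_off)
      if (length(b) == 1L) break
      t_off <- t_off + b[1] + b[2]
      q_off <- q_off + b[1] + b[3]
    }
    if (t_off + sizes[length(sizes)] != hdr$t_end) {
      abort(paste0("chain ending before line ", i, " of ", path,
                   ": blocks inconsistent with t span"))
    }
    hdr$blocks <- list(tibble(t_start = t_starts, q_start = q_starts,
                              size = sizes))
    chains[[length(chains) + 1L]] <- as_tibble(hdr)
    i <- i + 1L
  }
  if (length(chains) == 0) {
    return(tibble(score = numeric(), t_name = character(),
                  t_size = integer(), t_strand = character(),
                  t_start = integer(), t_end = integer(),
                  q_name = character(), q_size = integer(),
                  q_strand = character(), q_start = integer(),
                  q_end = integer(), chain_id = character(),
                  blocks = list()))
  }
  list_rbind(chains)
}

#' Write a chain index to a UCSC chain file
#'
#' Inverse of [read_chain()]; blocks must be sorted and consistent.
#'
#' @param chains A chain tibble as returned by [read_chain()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chain <- function(chains, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(nrow(chains))) {
    ch <- chains[k, ]
    b <- ch$blocks[[1]]
    writeLines(paste("chain", format(ch$score, scientific = FALSE),
                     ch$t_name, ch$t_size, "+", ch$t_start, ch$t_end,
                     ch$q_name, ch$q_size, ch$q_strand, ch$q_start, ch$q_end,
                     ch$chain_id), con)
    n <- nrow(b)
    if (n > 1L) {
      dt <- b$t_start[-1] - (b$t_start[-n] + b$size[-n])
      dq <- b$q_start[-1] - (b$q_start[-n] + b$size[-n])
      writeLines(paste(b$size[-n], dt, dq), con)
    }
    writeLines(as.character(b$size[n]), con)
    writeLines("", con)
  }
  invisible(path)
}

# Map 0-based source positions through one chain's ungapped blocks.
# Returns q-strand coordinates; NA where a position falls in a gap or
# outside the chain.
map_positions_chain <- function(chain_row, positions) {
  b <- chain_row$blocks[[1]]
  idx <- findInterval(positions, b$t_start)
  q <- rep(NA_integer_, length(positions))
  ok <- idx >= 1L
  okin <- ok
  okin[ok] <- positions[ok] < b$t_start[idx[ok]] + b$size[idx[ok]]
  q[okin] <- b$q_start[idx[okin]] + (positions[okin] - b$t_start[idx[okin]])
  q
}

#' Lift a genomic interval through a chain index
#'
#' Maps every base of `interval` through the ungapped blocks of the
#' best-scoring chain overlapping it.  The lifted interval is the span of the
#' mapped target positions (forward-strand coordinates; for minus-strand
#' chains, q-strand coordinates are reflected).  Lifting fails with status
#' `"no_ortholog"` when no chain overlaps the interval or when the fraction
#' of bases that map through the chosen chain falls below
#' `min_mapped_fraction`.
#'
#' @param chains Chain index from [read_chain()].
#' @param interval One-row tibble with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [genomic_interval()] or [window_around()].
#' @param min_mapped_fraction Minimum fraction of interval bases that must
#'   map (default 0.95, the usual liftOver region default).
#' @return A one-row tibble: `status` (`"lifted"` or `"no_ortholog"`),
#'   `chrom`, `start`, `end`, `strand` (target, forward-strand, 0-based
#'   half-open; NA on failure), `mapped_fraction`, and `chain_id`.
#' @export
lift_interval <- function(chains, interval, min_mapped_fraction = 0.95) {
  fail <- function(frac = 0) {
    tibble(status = "no_ortholog", chrom = NA_character_,
           start = NA_integer_, end = NA_integer_, strand = NA_character_,
           mapped_fraction = frac, chain_id = NA_character_)
  }
  cand <- filter(chains, .data$t_name == interval$chrom,
                 .data$t_start < interval$end,
                 .data$t_end > interval$start)
  if (nrow(cand) == 0) return(fail())
  cand <- arrange(cand, desc(.data$score))
  best <- cand[1, ]
  pos <- seq.int(interval$start, interval$end - 1L)
  q <- map_positions_chain(best, pos)
  frac <- mean(!is.na(q))
  if (frac < min_mapped_fraction) return(fail(frac))
  qm <- q[!is.na(q)]
  if (best$q_strand == "-") qm <- best$q_size - 1L - qm
  tibble(status = "lifted", chrom = best$q_name,
         start = min(qm), end = max(qm) + 1L, strand = best$q_strand,
         mapped_fraction = frac, chain_id = best$chain_id)
}
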