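# Independent brute-force oracles used to validate the optimized
# implementations on small instances.

# per-base chain walk: map each 0-based source position by scanning every
# block of the given chain row with a plain loop
oracle_map_positions <- function(chain_row, positions) {
  b <- chain_row$blocks[[1]]
  vapply(positions, function(p) {
    for (i in seq_len(nrow(b))) {
      if (p >= b$t_start[i] && p < b$t_start[i] + b$size[i]) {
        return(b$q_start[i] + (p - b$t_start[i]))
      }
    }
    NA_integer_
  }, integer(1))
}

# exhaustive global-alignment score by full recursion over alignment paths
oracle_align_score <- function(s, t, match = 1, mismatch = -1, gap = -2) {
  ns <- nchar(s); nt <- nchar(t)
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      sc <- if (substr(s, i, i) == substr(t, j, j)) match else mismatch
      best <- max(best, rec(i - 1, j - 1) + sc)
    }
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    best
  }
  rec(ns, nt)
}

# all-pairs scan for UTR overlap with the coding-overlap condition
oracle_overlaps_utr <- function(locus, features) {
  utr <- features[features$type %in% c("five_prime_utr",
                                       "three_prime_utr", "UTR"), ]
  lbase <- seq(locus$start, locus$end)
  for (g in unique(utr$gene_id)) {
    gu <- utr[utr$gene_id == g & utr$chrom == locus$chrom, ]
    hit <- FALSE
    for (i in seq_len(nrow(gu))) {
      if (length(intersect(lbase, seq(gu$start[i], gu$end[i]))) > 0) {
        hit <- TRUE
      }
    }
    if (!hit) next
    cds <- features[features$type == "CDS" & features$gene_id == g &
                      features$chrom == locus$chrom, ]
    cbase <- integer(0)
    for (i in seq_len(nrow(cds))) {
      cbase <- union(cbase, seq(cds$start[i], cds$end[i]))
    }
    ov <- length(intersect(lbase, cbase))
    if (ov == 0 || ov < (2 / 3) * length(lbase)) return(TRUE)
  }
  FALSE
}

# naive nearest-TSS scan
oracle_nearest_tss <- function(locus, tss) {
  t <- tss[tss$chrom == locus$chrom, ]
  if (nrow(t) == 0) return(NULL)
  mid <- (locus$start + locus$end) %/% 2
  dist <- pmax(0, pmax(locus$start - t$tss, t$tss - locus$end))
  pick <- function(sel) {
    if (!any(sel)) return(list(gene = NA_character_, dist = NA_integer_))
    d <- dist[sel]; g <- t$gene_id[sel]
    o <- order(d, g)
    list(gene = g[o[1]], dist = d[o[1]])
  }
  list(up = pick(t$tss <= mid), down = pick(t$tss >= mid),
       near = pick(rep(TRUE, nrow(t))))
}

# adjacency count by raw looping
oracle_hub_genes <- function(edges, min_partners = 10, min_dscore = 0.5) {
  genes <- unique(c(edges$gene_a, edges$gene_b))
  hubs <- character(0)
  for (g in genes) {
    partners <- character(0)
    for (i in seq_len(nrow(edges))) {
      if (edges$dscore[i] <= min_dscore) next
      if (edges$gene_a[i] == g && edges$gene_b[i] != g) {
        partners <- union(partners, edges$gene_b[i])
      }
      if (edges$gene_b[i] == g && edges$gene_a[i] != g) {
        partners <- union(partners, edges$gene_a[i])
      }
    }
    if (length(partners) > min_partners) hubs <- c(hubs, g)
  }
  sort(hubs)
}

# exhaustive search for the left-aligned parsimonious representation:
# among every equivalent (pos, ref, alt) with non-empty alleles, take the
# minimal total allele length, then the smallest position
oracle_normalize <- function(genome, chrom, pos, ref, alt,
                             window = 25L) {
  G <- if (is.character(genome)) genome[[chrom]] else
    as.character(genome[[chrom]])
  altered <- paste0(substring(G, 1, pos - 1), alt,
                    substring(G, pos + nchar(ref)))
  best <- NULL
  for (p2 in seq(max(1, pos - window), pos + window)) {
    for (rlen in 0:(nchar(ref) + window)) {
      if (p2 + rlen - 1 > nchar(G)) next
      ref2 <- substring(G, p2, p2 + rlen - 1)
      pre <- substring(G, 1, p2 - 1)
      suf <- substring(G, p2 + rlen)
      alen <- nchar(altered) - nchar(pre) - nchar(suf)
      if (alen < 1 || rlen < 1) next
      if (substring(altered, 1, p2 - 1) != pre) next
      if (nchar(suf) > 0 &&
          substring(altered, nchar(altered) - nchar(suf) + 1) != suf) next
      alt2 <- substring(altered, p2, p2 + alen - 1)
      cand <- list(pos = p2, ref = ref2, alt = alt2,
                   len = rlen + alen)
      if (identical(ref2, alt2)) next
      if (is.null(best) || cand$len < best$len ||
          (cand$len == best$len && cand$pos < best$pos)) {
        best <- cand
      }
    }
  }
  tibble::tibble(chrom = chrom, pos = best$pos, ref = best$ref,
                 alt = best$alt)
}

# set-algebra consensus: per-sample intersection of the callers'
# qual-filtered site sets, then union across samples
oracle_pooled <- function(calls, min_qual = 20) {
  f <- calls[calls$qual >= min_qual, ]
  key <- function(d) paste0(d$chrom, ":", d$pos, d$ref, ">", d$alt)
  pooled <- character(0)
  for (s in unique(f$sample)) {
    fs <- f[f$sample == s, ]
    sets <- lapply(split(fs, fs$caller), key)
    if (length(sets) < 3) next
    pooled <- union(pooled, Reduce(intersect, sets))
  }
  sort(pooled)
}

# random small chain over one chromosome for lift oracle tests
random_chain <- function(seed) {
  panelsnp:::with_seed(seed, {
    n_blocks <- sample(1:5, 1)
    t_cur <- sample(0:20, 1)
    q_cur <- sample(0:20, 1)
    t_starts <- integer(0); q_starts <- integer(0); sizes <- integer(0)
    for (i in seq_len(n_blocks)) {
      size <- sample(1:30, 1)
      t_starts <- c(t_starts, t_cur); q_starts <- c(q_starts, q_cur)
      sizes <- c(sizes, size)
      t_cur <- t_cur + size + sample(0:15, 1)
      q_cur <- q_cur + size + sample(0:15, 1)
    }
    k <- length(sizes)
    tibble::tibble(
      score = 100, t_name = "chr1", t_size = t_cur + 50L,
      t_strand = "+",
      t_start = t_starts[1], t_end = t_starts[k] + sizes[k],
      q_name = "chr1", q_size = q_cur + 50L, q_strand = "+",
      q_start = q_starts[1], q_end = q_starts[k] + sizes[k],
      chain_id = "1",
      blocks = list(tibble::tibble(t_start = t_starts,
                                   q_start = q_starts, size = sizes))
    )
  })
}
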