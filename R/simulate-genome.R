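# Genome-pair simulation: a source genome of per-SNP segments and a target
# genome derived from it by recorded edits, with a chain file that exactly
# describes the derivation.  Each SNP segment is assigned an intended lift
# outcome, so the ortholog/conservation cascade has full ground truth.

# Fixed local context planted around every SNP so that, for gap_at_snp
# segments, the alignment gap falls unambiguously on the SNP column:
# the deleted bases (GC) are flanked by TA on both sides.
SNP_CONTEXT <- c("T", "A", "G", "C", "T", "A")  # offsets snp-2 .. snp+3

#' Simulate a source/target genome pair with a descriptive chain file
#'
#' The source genome is one chromosome of `n_snps` segments of `seg_bp`
#' bases, one SNP at each segment center.  The target genome is derived
#' segment-by-segment according to `config$ortholog_classes`:
#' `conserved` segments are copied (with `n_subs` substitutions away from
#' the SNP window), `gap_at_snp` segments lose `del_len` bases at the SNP,
#' `too_long` segments gain an `ins_len` insertion inside the window,
#' `no_ortholog` segments are absent from the target and the chain, and
#' `unplaced` segments map to an unplaced contig (`chrUn_1`).  The chain
#' file records the derivation exactly; chain scores equal aligned bases.
#'
#' @param config A [sim_config()].
#' @param dir Optional output directory; when given, writes `source.fa`,
#'   `target.fa`, `lift.chain`, `snps.tsv` and `truth.json`.
#' @return List with `source`, `target` (named character vectors of
#'   sequences), `chains` (chain tibble), `snps` (SNP table with `rsid`,
#'   `chrom`, `pos`, `ref`, `alt`, `source`, `species`, `p`), `truth`
#'   (per-SNP intended class), and `paths` (when `dir` given).
#' @export
simulate_genome_pair <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_snps
  classes <- config$ortholog_classes %||% rep("conserved", n)
  seg <- config$seg_bp
  if (seg < 220L) abort("seg_bp must be at least 220 to hold a 100-bp window")
  snp_off <- seg %/% 2L  # 0-based offset of the SNP inside a segment

  with_seed(config$seed, {
    src_chrom <- "chr1"
    segs <- character(n)
    for (i in seq_len(n)) {
      s <- strsplit(random_dna(seg), "")[[1]]
      s[(snp_off - 1L):(snp_off + 4L)] <- SNP_CONTEXT
      segs[i] <- paste(s, collapse = "")
    }

    # chain assembly state
    chains <- list()
    cur <- NULL  # list(t_starts, q_starts, sizes)
    q_cursor <- 0L
    u_cursor <- 0L
    tgt_pieces <- character(0)
    un_pieces <- character(0)

    push_run <- function(cur, t0, q0, size) {
      if (!is.null(cur)) {
        k <- length(cur$sizes)
        if (cur$t_starts[k] + cur$sizes[k] == t0 &&
            cur$q_starts[k] + cur$sizes[k] == q0) {
          cur$sizes[k] <- cur$sizes[k] + size
          return(cur)
        }
        cur$t_starts <- c(cur$t_starts, t0)
        cur$q_starts <- c(cur$q_starts, q0)
        cur$sizes <- c(cur$sizes, size)
        return(cur)
      }
      list(t_starts = t0, q_starts = q0, sizes = size)
    }
    close_chain <- function(q_name) {
      if (is.null(cur)) return(invisible())
      k <- length(cur$sizes)
      chains[[length(chains) + 1L]] <<- list(
        q_name = q_name,
        t_start = cur$t_starts[1],
        t_end = cur$t_starts[k] + cur$sizes[k],
        q_start = cur$q_starts[1],
        q_end = cur$q_starts[k] + cur$sizes[k],
        blocks = tibble(t_start = cur$t_starts, q_start = cur$q_starts,
                        size = cur$sizes),
        score = sum(cur$sizes)
      )
      cur <<- NULL
    }

    truth <- vector("list", n)
    for (i in seq_len(n)) {
      t0 <- (i - 1L) * seg
      cls <- classes[i]
      s <- segs[i]
      if (cls == "conserved") {
        piece <- strsplit(s, "")[[1]]
        if (config$n_subs > 0L) {
          safe <- setdiff(seq_len(seg),
                          (snp_off - 60L):(snp_off + 61L))
          at <- sample(safe, min(config$n_subs, length(safe)))
          for (a in at) {
            piece[a] <- sample(setdiff(c("A", "C", "G", "T"), piece[a]), 1)
          }
        }
        tgt_pieces <- c(tgt_pieces, paste(piece, collapse = ""))
        cur <- push_run(cur, t0, q_cursor, seg)
        q_cursor <- q_cursor + seg
      } else if (cls == "gap_at_snp") {
        dl <- config$del_len
        piece <- paste0(substr(s, 1L, snp_off),
                        substr(s, snp_off + dl + 1L, seg))
        tgt_pieces <- c(tgt_pieces, piece)
        cur <- push_run(cur, t0, q_cursor, snp_off)
        cur <- push_run(cur, t0 + snp_off + dl, q_cursor + snp_off,
                        seg - snp_off - dl)
        q_cursor <- q_cursor + seg - dl
      } else if (cls == "too_long") {
        il <- config$ins_len
        ins <- random_dna(il)
        piece <- paste0(substr(s, 1L, snp_off + 1L), ins,
                        substr(s, snp_off + 2L, seg))
        tgt_pieces <- c(tgt_pieces, piece)
        cur <- push_run(cur, t0, q_cursor, snp_off + 1L)
        cur <- push_run(cur, t0 + snp_off + 1L, q_cursor + snp_off + 1L + il,
                        seg - snp_off - 1L)
        q_cursor <- q_cursor + seg + il
      } else if (cls == "no_ortholog") {
        close_chain("chr1")
      } else if (cls == "unplaced") {
        close_chain("chr1")
        un_pieces <- c(un_pieces, s)
        cur <- push_run(cur, t0, u_cursor, seg)
        close_chain("chrUn_1")
        u_cursor <- u_cursor + seg
      }
      truth[[i]] <- tibble(rsid = sprintf("rs%06d", i),
                           chrom = src_chrom,
                           pos = t0 + snp_off + 1L,
                           class = cls)
    }
    close_chain("chr1")

    source_seq <- paste(segs, collapse = "")
    target_seq <- paste(tgt_pieces, collapse = "")
    un_seq <- paste(un_pieces, collapse = "")
    t_size <- nchar(source_seq)
    q_sizes <- c(chr1 = nchar(target_seq), chrUn_1 = nchar(un_seq))

    chain_tbl <- if (length(chains) == 0) {
      read_chain(textConnection_chain_empty())
    } else {
      list_rbind(imap(chains, function(ch, k) {
        tibble(score = ch$score, t_name = src_chrom, t_size = t_size,
               t_strand = "+", t_start = ch$t_start, t_end = ch$t_end,
               q_name = ch$q_name,
               q_size = unname(q_sizes[[ch$q_name]]),
               q_strand = "+", q_start = ch$q_start, q_end = ch$q_end,
               chain_id = as.character(k), blocks = list(ch$blocks))
      }))
    }

    truth <- list_rbind(truth)
    if (is.null(truth) || ncol(truth) == 0) {
      truth <- tibble(rsid = character(), chrom = character(),
                      pos = integer(), class = character())
    }
    snps <- transmute(truth,
      rsid = .data$rsid, chrom = .data$chrom, pos = .data$pos,
      ref = ifelse(nchar(source_seq) > 0,
                   substr(rep(source_seq, dplyr::n()), .data$pos, .data$pos),
                   NA_character_),
      alt = NA_character_, source = "synthetic", species = "source",
      p = NA_real_)

    source <- c(chr1 = source_seq)
    target <- c(chr1 = target_seq)
    if (nchar(un_seq) > 0) target <- c(target, chrUn_1 = un_seq)

    out <- list(source = source, target = target, chains = chain_tbl,
                snps = snps, truth = truth)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      paths <- list(
        source = file.path(dir, "source.fa"),
        target = file.path(dir, "target.fa"),
        chain = file.path(dir, "lift.chain"),
        snps = file.path(dir, "snps.tsv"),
        truth = file.path(dir, "truth.json")
      )
      write_fasta(source, paths$source)
      write_fasta(target, paths$target)
      write_chain(chain_tbl, paths$chain)
      write_tsv_quiet(snps, paths$snps)
      jsonlite::write_json(truth, paths$truth, dataframe = "rows")
      out$paths <- paths
    }
    out
  })
}

# internal: an empty chain tibble via read_chain's empty branch
textConnection_chain_empty <- function() {
  tmp <- tempfile(fileext = ".chain")
  writeLines(character(0), tmp)
  tmp
}

#' Write sequences to FASTA (60-column lines)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- seqs[nchar(seqs) > 0]
  set <- Biostrings::DNAStringSet(unlist(seqs))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Build a filter-cascade accounting fixture
#'
#' Constructs a genome/chain/SNP bundle in which the ortholog and
#' conservation filters provably produce the requested class sizes, plus an
#' optional table of literature SNPs already on the target genome.
#'
#' @param composition Named list or vector of counts: `n_input`,
#'   `n_no_ortholog`, `n_too_long`, `n_unplaced`, `n_gap_at_snp`,
#'   `n_literature` (missing entries default to 0).
#' @param dir Optional output directory, passed to [simulate_genome_pair()];
#'   literature SNPs are additionally written to `literature_snps.tsv`.
#' @param seed Seed controlling segment sequences and class placement.
#' @return The [simulate_genome_pair()] result, plus `literature` (tibble of
#'   target-species SNPs) and `expected` (tibble of expected class counts,
#'   including `conserved`).
#' @export
make_accounting_fixture <- function(composition, dir = NULL, seed = 1L) {
  comp <- as.list(composition)
  get0n <- function(nm) as.integer(comp[[nm]] %||% 0L)
  n_input <- get0n("n_input")
  n_no <- get0n("n_no_ortholog")
  n_long <- get0n("n_too_long")
  n_unpl <- get0n("n_unplaced")
  n_gap <- get0n("n_gap_at_snp")
  n_lit <- get0n("n_literature")
  n_fail <- n_no + n_long + n_unpl + n_gap
  if (n_fail > n_input) {
    abort("composition class counts exceed the input SNP count")
  }
  classes <- rep("conserved", n_input)
  if (n_input > 0) {
    idx <- with_seed(seed + 1L, sample.int(n_input, n_fail))
    classes[idx] <- rep(c("no_ortholog", "too_long", "unplaced",
                          "gap_at_snp"),
                        times = c(n_no, n_long, n_unpl, n_gap))
  }
  config <- sim_config(seed = seed, n_snps = n_input,
                       ortholog_classes = if (n_input > 0) classes else NULL)
  sim <- simulate_genome_pair(config, dir = dir)

  literature <- tibble(rsid = character(), chrom = character(),
                       pos = integer(), ref = character(),
                       alt = character(), source = character(),
                       species = character(), p = numeric())
  if (n_lit > 0) {
    if (!"chr1" %in% names(sim$target) || nchar(sim$target[["chr1"]]) == 0) {
      abort("cannot place literature SNPs: empty target genome")
    }
    len <- nchar(sim$target[["chr1"]])
    pos <- with_seed(seed + 2L, sort(sample.int(len, n_lit)))
    literature <- tibble(
      rsid = sprintf("lit%03d", seq_len(n_lit)),
      chrom = "chr1", pos = pos,
      ref = substring(sim$target[["chr1"]], pos, pos),
      alt = NA_character_, source = "literature", species = "target",
      p = NA_real_)
  }
  if (!is.null(dir)) {
    write_tsv_quiet(literature, file.path(dir, "literature_snps.tsv"))
    sim$paths$literature <- file.path(dir, "literature_snps.tsv")
  }
  sim$literature <- literature
  sim$expected <- tibble(
    status = c("conserved", "no_ortholog", "too_long", "unplaced",
               "gap_at_snp"),
    n = c(n_input - n_fail, n_no, n_long, n_unpl, n_gap)
  )
  sim
}
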