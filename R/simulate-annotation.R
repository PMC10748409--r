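# Prioritization-input generator: gene neighborhoods laid out so that each
# candidate locus provably triggers (or avoids) each selection criterion.

neighborhood_gene <- function(gene_id, gs, tx_id, intron = FALSE) {
  if (!intron) {
    tibble(
      chrom = "chr1",
      start = c(gs, gs, gs, gs, gs + 100L, gs + 400L),
      end = c(gs + 699L, gs + 699L, gs + 699L, gs + 99L, gs + 399L,
              gs + 699L),
      strand = "+",
      type = c("gene", "transcript", "exon", "five_prime_utr", "CDS",
               "three_prime_utr"),
      gene_id = gene_id, transcript_id = c(NA, rep(tx_id, 5)),
      gene_name = gene_id
    )
  } else {
    tibble(
      chrom = "chr1",
      start = c(gs, gs, gs, gs + 1000L, gs, gs + 100L, gs + 1000L,
                gs + 1100L),
      end = c(gs + 1299L, gs + 1299L, gs + 199L, gs + 1299L, gs + 99L,
              gs + 199L, gs + 1099L, gs + 1299L),
      strand = "+",
      type = c("gene", "transcript", "exon", "exon", "five_prime_utr",
               "CDS", "CDS", "three_prime_utr"),
      gene_id = gene_id, transcript_id = c(NA, rep(tx_id, 7)),
      gene_name = gene_id
    )
  }
}

#' Simulate prioritization inputs with known selection truth
#'
#' Lays out independent 20-kb gene neighborhoods on one chromosome, one
#' candidate locus each, such that exactly `n_utr` loci overlap UTRs,
#' `n_tf` have a TF gene as nearest up/downstream TSS (with
#' `n_overlap_utr_tf` of these counted in both sets), `n_keyreg` sit in
#' key-regulator genes and `n_deghub` are nearest to DEG network hubs;
#' `n_deg_nonhub` and `n_background` loci qualify for nothing.
#'
#' @param n_utr,n_tf,n_keyreg,n_deghub Planted set sizes (the defaults
#'   yield 101 selected loci).
#' @param n_overlap_utr_tf Loci counted in both the UTR and TF sets.
#' @param n_deg_nonhub DEG-proximal loci whose DEG is not a hub.
#' @param n_background Loci qualifying for nothing.
#' @param seed Seed (layout is deterministic; seed only labels ids).
#' @param dir Optional output directory for `annotation.gtf`, `loci.tsv`,
#'   `tf_classes.tsv`, `degs.tsv`, `key_regulators.tsv`, `edges.tsv` and
#'   `truth.json`.
#' @return List: `loci` (with `truth` tags), `gene_models`, `tf_classes`,
#'   `deg_list`, `key_regulators`, `edges`, `n_expected_selected`.
#' @export
simulate_prioritization_inputs <- function(n_utr = 29L, n_tf = 48L,
                                           n_keyreg = 4L, n_deghub = 29L,
                                           n_overlap_utr_tf = 9L,
                                           n_deg_nonhub = 10L,
                                           n_background = 10L,
                                           seed = 1L, dir = NULL) {
  if (n_overlap_utr_tf > min(n_utr, n_tf)) {
    abort("n_overlap_utr_tf cannot exceed n_utr or n_tf")
  }
  # Order matters: a locus's nearest up/downstream TSS can belong to the
  # neighboring neighborhood, so TF genes are laid out last, after every
  # locus whose selection must not depend on TF proximity.
  kinds <- c(rep("utr", n_utr - n_overlap_utr_tf),
             rep("keyreg", n_keyreg),
             rep("deghub", n_deghub),
             rep("degnonhub", n_deg_nonhub),
             rep("background", n_background),
             rep("utr_tf", n_overlap_utr_tf),
             rep("tf", n_tf - n_overlap_utr_tf))
  n <- length(kinds)
  feats <- vector("list", n)
  loci <- vector("list", n)
  tf_ids <- character(0); deg_ids <- character(0)
  key_ids <- character(0); hub_ids <- character(0)
  nonhub_deg_ids <- character(0)

  for (k in seq_len(n)) {
    gid <- sprintf("G%04d", k)
    tx <- sprintf("T%04d", k)
    gs <- (k - 1L) * 20000L + 5001L
    kind <- kinds[k]
    intron <- kind == "keyreg"
    feats[[k]] <- neighborhood_gene(gid, gs, tx, intron = intron)
    l <- switch(kind,
      utr = ,
      utr_tf = c(gs + 450L, gs + 549L),
      tf = ,
      deghub = ,
      degnonhub = ,
      background = c(gs - 600L, gs - 501L),
      keyreg = c(gs + 500L, gs + 599L)
    )
    loci[[k]] <- tibble(locus_id = sprintf("L%04d", k), chrom = "chr1",
                        start = l[1], end = l[2], truth = kind)
    if (kind %in% c("tf", "utr_tf")) tf_ids <- c(tf_ids, gid)
    if (kind == "keyreg") key_ids <- c(key_ids, gid)
    if (kind == "deghub") {
      deg_ids <- c(deg_ids, gid); hub_ids <- c(hub_ids, gid)
    }
    if (kind == "degnonhub") {
      deg_ids <- c(deg_ids, gid); nonhub_deg_ids <- c(nonhub_deg_ids, gid)
    }
  }
  gene_models <- list_rbind(feats)
  loci <- list_rbind(loci)

  edges <- bind_rows(
    list_rbind(map(hub_ids, function(g) {
      tibble(gene_a = g, gene_b = sprintf("%s_P%02d", g, 1:12),
             dscore = 0.8)
    })),
    list_rbind(map(nonhub_deg_ids, function(g) {
      bind_rows(
        tibble(gene_a = g, gene_b = sprintf("%s_P%02d", g, 1:5),
               dscore = 0.8),
        tibble(gene_a = g, gene_b = sprintf("%s_Q%02d", g, 1:8),
               dscore = 0.3)
      )
    }))
  )
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble(gene_a = character(), gene_b = character(),
                    dscore = numeric())
  }
  tf_classes <- tibble(gene_id = tf_ids,
                       protein_class = "transcription factor")
  expected <- n_utr + n_tf + n_keyreg + n_deghub - n_overlap_utr_tf

  out <- list(loci = loci, gene_models = gene_models,
              tf_classes = tf_classes, deg_list = deg_ids,
              key_regulators = key_ids, edges = edges,
              n_expected_selected = expected)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_gtf(gene_models, file.path(dir, "annotation.gtf"))
    write_tsv_quiet(loci, file.path(dir, "loci.tsv"))
    write_tsv_quiet(tf_classes, file.path(dir, "tf_classes.tsv"))
    write_tsv_quiet(tibble(gene_id = deg_ids), file.path(dir, "degs.tsv"))
    write_tsv_quiet(tibble(gene_id = key_ids),
                    file.path(dir, "key_regulators.tsv"))
    write_tsv_quiet(edges, file.path(dir, "edges.tsv"))
    jsonlite::write_json(loci, file.path(dir, "truth.json"),
                         dataframe = "rows")
  }
  out
}
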