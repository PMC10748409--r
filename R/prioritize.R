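# Locus prioritization: UTR overlap, transcription-factor proximity,
# key-regulator genes, and DEG-proximal network hubs.

#' Does each locus overlap a UTR (with limited coding overlap)?
#'
#' A locus counts as UTR-overlapping when it overlaps an annotated UTR of
#' some gene and, for that gene, the locus either has no overlap with
#' coding (CDS) segments or the coding overlap covers strictly less than
#' two thirds of the locus length.
#'
#' @param loci Tibble with `chrom`, `start`, `end` (1-based inclusive).
#' @param features Gene-model tibble (already passed through
#'   [filter_annotation()]).
#' @return Logical vector, one entry per locus.
#' @export
overlaps_utr <- function(loci, features) {
  utr <- filter(features,
                .data$type %in% c("five_prime_utr", "three_prime_utr",
                                  "UTR"))
  cds <- filter(features, .data$type == "CDS")
  map_lgl(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    len <- l$end - l$start + 1L
    hit <- filter(utr, .data$chrom == l$chrom, .data$start <= l$end,
                  .data$end >= l$start)
    if (nrow(hit) == 0) return(FALSE)
    any(map_lgl(unique(hit$gene_id), function(g) {
      gc <- filter(cds, .data$gene_id == g, .data$chrom == l$chrom)
      ov <- interval_overlap_bp(l$start - 1L, l$end, gc$start - 1L, gc$end)
      ov == 0L || ov < (2 / 3) * len
    }))
  })
}

#' Nearest upstream and downstream TSS for each locus
#'
#' Upstream/downstream is defined on genomic coordinates relative to the
#' locus midpoint; distance is measured from the nearer locus edge (0 when
#' the TSS lies inside the locus).  Ties are broken by the
#' lexicographically smaller gene id.
#'
#' @param loci Tibble with `chrom`, `start`, `end`.
#' @param features Gene-model tibble.
#' @return Tibble with one row per locus: `up_gene`, `up_dist`,
#'   `down_gene`, `down_dist`, `nearest_gene`, `nearest_dist`.  Loci on
#'   chromosomes without any TSS get NA in all columns.
#' @export
nearest_tss <- function(loci, features) {
  tss <- gene_tss(features)
  pick <- function(cand) {
    if (nrow(cand) == 0) {
      return(list(gene = NA_character_, dist = NA_integer_))
    }
    cand <- arrange(cand, .data$dist, .data$gene_id)
    list(gene = cand$gene_id[1], dist = cand$dist[1])
  }
  out <- map(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    t <- filter(tss, .data$chrom == l$chrom)
    if (nrow(t) == 0) {
      warn(paste0("no TSS on chromosome ", l$chrom))
      return(tibble(up_gene = NA_character_, up_dist = NA_integer_,
                    down_gene = NA_character_, down_dist = NA_integer_,
                    nearest_gene = NA_character_,
                    nearest_dist = NA_integer_))
    }
    mid <- (l$start + l$end) %/% 2L
    t <- mutate(t, dist = pmax(0L, pmax(l$start - .data$tss,
                                        .data$tss - l$end)))
    up <- pick(filter(t, .data$tss <= mid))
    down <- pick(filter(t, .data$tss >= mid))
    near <- pick(t)
    tibble(up_gene = up$gene, up_dist = up$dist,
           down_gene = down$gene, down_dist = down$dist,
           nearest_gene = near$gene, nearest_dist = near$dist)
  })
  list_rbind(out)
}

#' Network hub genes
#'
#' A gene is a hub when it has strictly more than `min_partners` distinct
#' interaction partners connected by edges whose curated-evidence score
#' exceeds `min_dscore`.  Edges are undirected; duplicates and self-loops
#' are ignored.
#'
#' @param edges Tibble with `gene_a`, `gene_b`, `dscore`.
#' @param min_partners Partner-count threshold (strict `>`, default 10).
#' @param min_dscore Score threshold (strict `>`, default 0.5).
#' @return Character vector of hub gene ids.
#' @export
hub_genes <- function(edges, min_partners = 10L, min_dscore = 0.5) {
  e <- edges |>
    filter(.data$dscore > min_dscore, .data$gene_a != .data$gene_b)
  if (nrow(e) == 0) return(character(0))
  adj <- bind_rows(
    tibble(gene = e$gene_a, partner = e$gene_b),
    tibble(gene = e$gene_b, partner = e$gene_a)
  ) |> distinct()
  counts <- count(adj, .data$gene)
  sort(counts$gene[counts$n > min_partners])
}

tf_gene_set <- function(tf_classes) {
  if (is.null(tf_classes)) return(NULL)
  if (is.data.frame(tf_classes)) {
    if ("protein_class" %in% names(tf_classes)) {
      tf_classes <- tf_classes$gene_id[
        str_detect(str_to_lower(tf_classes$protein_class),
                   "transcription factor")]
    } else {
      tf_classes <- tf_classes$gene_id
    }
  }
  as.character(tf_classes)
}

#' Prioritize candidate loci
#'
#' Selects the union of: (a) loci overlapping UTRs, (b) loci whose nearest
#' upstream or downstream TSS belongs to a transcription-factor gene,
#' (c) loci inside designated key-regulator genes, and (d) among the
#' remaining loci whose nearest TSS is a differentially expressed gene,
#' those whose DEG is a network hub.  Each selected locus appears once,
#' tagged with all applicable reasons.
#'
#' @param loci Tibble with `locus_id`, `chrom`, `start`, `end`.
#' @param gene_models Gene-model tibble (post [filter_annotation()]).
#' @param tf_classes Tibble (`gene_id`, `protein_class`) or character
#'   vector of TF gene ids; `NULL` skips criterion (b) with a warning.
#' @param deg_list Character vector of differentially-expressed gene ids.
#' @param key_regulators Character vector of key-regulator gene ids.
#' @param edges Interaction edge tibble (`gene_a`, `gene_b`, `dscore`).
#' @param min_partners,min_dscore Passed to [hub_genes()].
#' @return Tibble of selected loci with `reasons` (comma-joined subset of
#'   `utr`, `tf_proximal`, `key_regulator`, `deg_hub`), `nearest_gene` and
#'   `nearest_tss_distance`.
#' @export
prioritize_loci <- function(loci, gene_models, tf_classes = NULL,
                            deg_list = character(0),
                            key_regulators = character(0),
                            edges = NULL, min_partners = 10L,
                            min_dscore = 0.5) {
  stopifnot(all(c("locus_id", "chrom", "start", "end") %in% names(loci)))
  n <- nrow(loci)
  is_utr <- overlaps_utr(loci, gene_models)
  nt <- nearest_tss(loci, gene_models)

  tfs <- tf_gene_set(tf_classes)
  if (is.null(tfs)) {
    warn("no TF class table supplied: TF-proximity criterion skipped")
    is_tf <- rep(FALSE, n)
  } else {
    is_tf <- (!is.na(nt$up_gene) & nt$up_gene %in% tfs) |
      (!is.na(nt$down_gene) & nt$down_gene %in% tfs)
  }

  genes <- filter(gene_models, .data$type == "gene",
                  .data$gene_id %in% key_regulators)
  is_key <- map_lgl(seq_len(n), function(i) {
    l <- loci[i, ]
    any(genes$chrom == l$chrom & genes$start <= l$end &
          genes$end >= l$start)
  })

  hubs <- if (is.null(edges)) character(0) else {
    hub_genes(edges, min_partners, min_dscore)
  }
  already <- is_utr | is_tf | is_key
  is_deghub <- !already & !is.na(nt$nearest_gene) &
    nt$nearest_gene %in% deg_list & nt$nearest_gene %in% hubs

  selected <- is_utr | is_tf | is_key | is_deghub
  reasons <- map_chr(seq_len(n), function(i) {
    paste(c("utr", "tf_proximal", "key_regulator", "deg_hub")[
      c(is_utr[i], is_tf[i], is_key[i], is_deghub[i])], collapse = ",")
  })
  bind_cols(loci, tibble(reasons = reasons,
                         nearest_gene = nt$nearest_gene,
                         nearest_tss_distance = nt$nearest_dist))[
    selected, , drop = FALSE]
}
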