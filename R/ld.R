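# Two-locus linkage disequilibrium from unphased genotypes: EM haplotype
# frequency estimation and the likelihood-grid D' confidence interval that
# drives the Gabriel block criteria.

genotype_counts_2x2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  matrix(tabulate(g1[ok] * 3L + g2[ok] + 1L, nbins = 9L), 3, 3,
         byrow = TRUE)
}

#' EM haplotype frequencies for two biallelic loci
#'
#' Estimates the four haplotype frequencies from unphased genotype codes
#' (0/1/2 alternate-allele counts, NA allowed).  Phase of
#' double heterozygotes is resolved by expectation-maximization from a
#' uniform start, iterating until the largest frequency change is below
#' `tol` or `max_iter` iterations.
#'
#' @param g1,g2 Integer genotype vectors (0, 1, 2 or NA), equal length.
#' @param tol Convergence tolerance on haplotype frequencies
#'   (default 1e-9).
#' @param max_iter Iteration cap (default 1000).
#' @return A list of class `two_locus_table`: `freq` (named numeric:
#'   `AB`, `Ab`, `aB`, `ab` where A/B denote alternate alleles),
#'   `n_chrom`, `counts` (3x3 genotype table), `informative` (FALSE when
#'   either locus is monomorphic), `iterations`, `converged`.
#' @export
em_haplotypes <- function(g1, g2, tol = 1e-9, max_iter = 1000L) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (sum(ok) < 2L) abort("need at least 2 subjects with complete genotypes")
  tab <- genotype_counts_2x2(g1, g2)
  n_chrom <- 2L * sum(tab)
  pA <- sum(g1[ok]) / n_chrom
  pB <- sum(g2[ok]) / n_chrom
  informative <- pA > 0 && pA < 1 && pB > 0 && pB < 1

  # fixed haplotype contributions from phase-known genotypes
  # rows/cols are genotype 0,1,2 at locus 1/2; haplotype letters:
  # A/B = alternate allele present
  kAB <- 2 * tab[3, 3] + tab[3, 2] + tab[2, 3]
  kAb <- 2 * tab[3, 1] + tab[3, 2] + tab[2, 1]
  kaB <- 2 * tab[1, 3] + tab[1, 2] + tab[2, 3]
  kab <- 2 * tab[1, 1] + tab[1, 2] + tab[2, 1]
  dh <- tab[2, 2]  # double heterozygotes

  ll_geno <- function(p) {
    P <- matrix(c(
      p[["ab"]]^2, 2 * p[["aB"]] * p[["ab"]], p[["aB"]]^2,
      2 * p[["Ab"]] * p[["ab"]],
      2 * p[["AB"]] * p[["ab"]] + 2 * p[["Ab"]] * p[["aB"]],
      2 * p[["AB"]] * p[["aB"]],
      p[["Ab"]]^2, 2 * p[["AB"]] * p[["Ab"]], p[["AB"]]^2
    ), nrow = 3, byrow = TRUE)
    sum(tab[tab > 0] * log(pmax(P[tab > 0], 1e-300)))
  }

  p <- c(AB = 0.25, Ab = 0.25, aB = 0.25, ab = 0.25)
  it <- 0L
  converged <- FALSE
  ll_trace <- numeric(0)
  repeat {
    it <- it + 1L
    ll_trace <- c(ll_trace, ll_geno(p))
    cis <- unname(p[["AB"]] * p[["ab"]])
    trans <- unname(p[["Ab"]] * p[["aB"]])
    x <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    cnt <- c(AB = kAB + dh * x, Ab = kAb + dh * (1 - x),
             aB = kaB + dh * (1 - x), ab = kab + dh * x)
    pn <- cnt / n_chrom
    delta <- max(abs(pn - p))
    p <- pn
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  ll_trace <- c(ll_trace, ll_geno(p))
  structure(list(freq = p, n_chrom = n_chrom, counts = tab,
                 informative = informative, iterations = it,
                 converged = converged, loglik_trace = ll_trace),
            class = "two_locus_table")
}

# |D'| from haplotype frequencies
dprime_from_freq <- function(freq) {
  pA <- freq[["AB"]] + freq[["Ab"]]
  pB <- freq[["AB"]] + freq[["aB"]]
  D <- freq[["AB"]] - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) return(NA_real_)
  abs(D) / dmax
}

#' Likelihood-based confidence interval for |D'|
#'
#' Evaluates the likelihood of the unphased genotype data on a grid of
#' |D'| values (0, 0.001, ..., 1), holding allele frequencies at their
#' estimates and the sign of D at its MLE sign, and reports the 5th and
#' 95th percentiles of the normalized cumulative likelihood — the interval
#' underlying the Gabriel strong-LD/recombination classification.
#'
#' @param table A `two_locus_table` from [em_haplotypes()].
#' @param grid_step Grid resolution (default 0.001).
#' @return One-row tibble: `dprime`, `ci_low`, `ci_high`, `informative`.
#' @export
dprime_ci <- function(table, grid_step = 0.001) {
  stopifnot(inherits(table, "two_locus_table"))
  if (!table$informative) {
    return(tibble(dprime = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, informative = FALSE))
  }
  freq <- table$freq
  pA <- freq[["AB"]] + freq[["Ab"]]
  pB <- freq[["AB"]] + freq[["aB"]]
  D <- freq[["AB"]] - pA * pB
  sign_pos <- D >= 0
  dmax <- if (sign_pos) min(pA * (1 - pB), (1 - pA) * pB) else
    min(pA * pB, (1 - pA) * (1 - pB))
  dhat <- dprime_from_freq(freq)
  grid <- seq(0, 1, by = grid_step)
  Dd <- if (sign_pos) grid * dmax else -grid * dmax
  p11 <- pmax(pA * pB + Dd, 0)
  p12 <- pmax(pA - p11, 0)
  p21 <- pmax(pB - p11, 0)
  p22 <- pmax(1 - pA - pB + p11, 0)
  tab <- table$counts
  term <- function(n, p) {  # n * log(p), with 0 * log(0) = 0
    if (n == 0) return(0)
    out <- rep(-Inf, length(p))
    out[p > 0] <- n * log(p[p > 0])
    out
  }
  ll <- term(tab[1, 1], p22^2) + term(tab[1, 2], 2 * p21 * p22) +
    term(tab[1, 3], p21^2) + term(tab[2, 1], 2 * p12 * p22) +
    term(tab[2, 2], 2 * p11 * p22 + 2 * p12 * p21) +
    term(tab[2, 3], 2 * p11 * p21) + term(tab[3, 1], p12^2) +
    term(tab[3, 2], 2 * p11 * p12) + term(tab[3, 3], p11^2)
  w <- exp(ll - max(ll))
  cum <- cumsum(w) / sum(w)
  # widen by at most one grid step so the point estimate is never
  # excluded by quantization
  ci_low <- min(grid[which(cum >= 0.05)[1]], dhat)
  ci_high <- max(grid[which(cum >= 0.95)[1]], dhat)
  tibble(dprime = dhat, ci_low = ci_low, ci_high = ci_high,
         informative = TRUE)
}
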