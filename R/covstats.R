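# Column-pair covariation statistics.
#
# MI and G-test are computed on rows carrying a residue at both columns
# ("pairwise-complete" rows).  MI is reported in bits; the G-test uses
# natural logs, so on gap-free counts G = 2 N ln(2) MI_bits.  The G-test
# therefore grows with the number of observed symbols (occupancy), while MI
# on frequencies does not -- a distinction that matters when the null model
# does not preserve gap structure.
#
# RAF is a diagnostic-only statistic mixing covariation with conservation
# and structural consistency; it is refused by the significance machinery.

#' Mutual information of a joint distribution over 16 residue pairs
#'
#' @param p 4 x 4 matrix of joint probabilities (sums to 1); rows are the
#'   residue at the first column, columns at the second.
#' @return MI in bits (`>= 0`); terms with zero probability contribute 0.
#' @export
mi <- function(p) {
  p <- as.matrix(p)
  stopifnot(all(dim(p) == c(4L, 4L)))
  tot <- sum(p)
  if (tot <= 0) stop("empty joint distribution")
  if (abs(tot - 1) > 1e-8) stop("joint distribution must sum to 1")
  pi_ <- rowSums(p); pj <- colSums(p)
  e <- outer(pi_, pj)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / e[nz]))
}

#' G-test statistic on joint residue counts
#'
#' `G = 2 sum Obs * ln(Obs / Expected)` with `Expected = Obs_i. * Obs_.j / N`,
#' natural logarithm.  Zero-count cells contribute 0.
#'
#' @param counts 4 x 4 matrix of joint counts over rows occupying both
#'   columns.
#' @return the statistic (`>= 0`).  `N = 0` returns 0 with attribute
#'   `zero_support = TRUE`.
#' @export
gtest <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(all(dim(counts) == c(4L, 4L)))
  N <- sum(counts)
  if (N == 0) return(structure(0, zero_support = TRUE))
  e <- outer(rowSums(counts), colSums(counts)) / N
  nz <- counts > 0
  2 * sum(counts[nz] * log(counts[nz] / e[nz]))
}

#' All-pairs covariation score matrix
#'
#' Vectorized computation of the G-test (or MI) for every column pair,
#' restricted per pair to rows occupying both columns, with the average
#' product correction applied across the full matrix.
#'
#' @param aln an `rna_alignment`.
#' @param stat `"gtest"` or `"mi"`.
#' @return list of class `score_matrix` with elements `stat`, `raw` and
#'   `apc` (L x L symmetric matrices, `NA` diagonal) and `support` (L x L
#'   matrix of pairwise-complete row counts N).
#' @export
score_matrix <- function(aln, stat = c("gtest", "mi")) {
  stat <- match.arg(stat)
  m <- aln$mat
  L <- ncol(m)
  occ <- (m > 0L) * 1
  N <- crossprod(occ)                    # N[i,j]: rows occupying both
  ind <- lapply(1:4, function(a) (m == a) * 1)
  # R[[a]][i,j]: count of residue a at i among rows occupying j
  R <- lapply(ind, function(Ia) crossprod(Ia, occ))
  G <- matrix(0, L, L)
  for (a in 1:4) {
    for (b in 1:4) {
      Nab <- crossprod(ind[[a]], ind[[b]])
      nz <- Nab > 0
      if (any(nz)) {
        ratio <- Nab[nz] * N[nz] / (R[[a]][nz] * t(R[[b]])[nz])
        G[nz] <- G[nz] + Nab[nz] * log(ratio)
      }
    }
  }
  G <- 2 * G
  raw <- if (stat == "gtest") G else {
    out <- G / (2 * log(2) * N)
    out[N == 0] <- 0
    out
  }
  diag(raw) <- NA_real_
  res <- list(stat = stat, raw = raw, apc = apc(raw), support = N)
  class(res) <- "score_matrix"
  res
}

#' Average product correction
#'
#' `corrected[i,j] = raw[i,j] - mean_i * mean_j / mean_all`, where the row
#' means and grand mean exclude the diagonal.  If the grand mean is 0 the
#' correction is skipped and the result carries attribute `apc_skipped`.
#'
#' @param raw symmetric score matrix (diagonal ignored).
#' @return corrected matrix, same shape.
#' @export
apc <- function(raw) {
  L <- ncol(raw)
  if (L < 2L) stop("APC needs at least 2 columns")
  m <- raw
  diag(m) <- NA_real_
  rowm <- rowMeans(m, na.rm = TRUE)
  grand <- mean(m[upper.tri(m)], na.rm = TRUE)
  if (!is.finite(grand) || grand == 0)
    return(structure(raw, apc_skipped = TRUE))
  out <- raw - outer(rowm, rowm) / grand
  diag(out) <- NA_real_
  out
}

# Watson-Crick (+ wobble) lookup over integer codes 0..4.
# wc_ok[x+1, y+1] is TRUE for AU, UA, CG, GC, GU, UG.
wc_table <- function() {
  wc <- matrix(FALSE, 5L, 5L)
  ok <- rbind(c(1, 4), c(4, 1), c(2, 3), c(3, 2), c(3, 4), c(4, 3))
  wc[ok + 1L] <- TRUE
  wc
}

#' RAF covariation-plus-conservation score (diagnostic only)
#'
#' For every sequence pair in which both sequences hold a (possibly wobble)
#' Watson-Crick pair at columns `(i, j)`, a double change scores +2 and a
#' half change +1; every sequence whose `(i, j)` residues are non-WC or
#' include a gap contributes a -1 penalty.  Change terms are normalized by
#' the number of sequence pairs and penalties by the number of sequences.
#' RAF mixes covariation with conservation and is refused by the
#' significance pipeline; it exists to reproduce the conserved-column
#' artifact.
#'
#' @param aln an `rna_alignment`.
#' @param i,j column indices.
#' @param stacking if `TRUE`, average with the scores of the neighbouring
#'   pairs `(i-1, j+1)` and `(i+1, j-1)` where in range (RAFS-style
#'   approximation).
#' @return numeric score.
#' @export
raf <- function(aln, i, j, stacking = FALSE) {
  if (stacking) {
    L <- n_col(aln)
    vals <- raf(aln, i, j, stacking = FALSE)
    if (i > 1L && j < L) vals <- c(vals, raf(aln, i - 1L, j + 1L))
    if (i + 1L < j - 1L) vals <- c(vals, raf(aln, i + 1L, j - 1L))
    return(mean(vals))
  }
  m <- aln$mat
  S <- nrow(m)
  wc <- wc_table()
  xi <- m[, i]; xj <- m[, j]
  is_wc <- wc[cbind(xi + 1L, xj + 1L)]
  penalty <- sum(!is_wc | xi == 0L | xj == 0L)
  change <- 0
  idx <- which(is_wc)
  if (length(idx) >= 2L) {
    for (u in seq_len(length(idx) - 1L)) {
      s <- idx[u]
      tt <- idx[(u + 1L):length(idx)]
      change <- change + sum((xi[s] != xi[tt]) + (xj[s] != xj[tt]))
    }
  }
  npairs <- S * (S - 1L) / 2L
  change / npairs - penalty / S
}

#' RAF artifact diagnostic against conservation-destroying nulls
#'
#' Scores the proposed pairs with RAF on the source alignment and on a
#' null ensemble.  Because the nulls do not preserve per-column
#' conservation, a conserved Watson-Crick pair -- zero covariation, zero
#' changes -- scores 0 in the source while the nulls accumulate non-WC and
#' gap penalties, so the conserved pair floats to the top of the null
#' distribution and looks "significant".  This is precisely why RAF-style
#' statistics are refused by the significance pipeline; the diagnostic
#' exists to demonstrate the mechanism.
#'
#' @param aln an `rna_alignment` whose `structure` holds the proposed
#'   pairs (or supply `pairs`).
#' @param ensemble list of null alignments (e.g. [null_ensemble()]).
#' @param pairs optional data frame `i`, `j` overriding the structure.
#' @param stacking passed to [raf()].
#' @return data frame per proposed pair: `i`, `j`, `raf` (source score),
#'   `exceedance` (fraction of null scores at the same pair `>=` source),
#'   `pseudo_evalue` (expected count per null alignment of proposed pairs
#'   scoring as high, pooled over pairs and nulls).
#' @export
raf_diagnostic <- function(aln, ensemble, pairs = NULL, stacking = FALSE) {
  if (is.null(pairs)) pairs <- aln$structure
  stopifnot(!is.null(pairs), nrow(pairs) > 0)
  src <- raf_pairs(aln, pairs, stacking = stacking)
  nullsc <- sapply(ensemble, function(nl) raf_pairs(nl, pairs, stacking = stacking))
  nullsc <- matrix(nullsc, nrow = nrow(pairs))
  pooled <- as.vector(nullsc)
  M <- length(ensemble)
  data.frame(
    i = pairs$i, j = pairs$j, raf = src,
    exceedance = vapply(seq_along(src),
                        function(k) mean(nullsc[k, ] >= src[k]), numeric(1)),
    pseudo_evalue = vapply(src, function(s) sum(pooled >= s) / M, numeric(1)))
}

#' RAF scores for a set of column pairs
#'
#' @param aln an `rna_alignment`.
#' @param pairs data frame with columns `i`, `j`.
#' @inheritParams raf
#' @return numeric vector of scores, one per row of `pairs`.
#' @export
raf_pairs <- function(aln, pairs, stacking = FALSE) {
  vapply(seq_len(nrow(pairs)),
         function(k) raf(aln, pairs$i[k], pairs$j[k], stacking = stacking),
         numeric(1))
}
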