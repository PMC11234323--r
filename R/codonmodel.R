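# Protein-codon evolution model and expected within-codon covariation.
#
# P(c1c2c3 | a, t) = sum_b P(c1c2c3 | b) P(b | a, t): an ancestral amino
# acid a evolves to b under an amino-acid substitution process (rate matrix
# derived from BLOSUM62, normalized to one expected substitution per site
# at t = 1), and b emits a codon according to stationary codon biases.
# Stop codons are outside the state space; indels are ignored; sequences
# descend independently from the ancestor (star topology).
#
# Within-codon covariation is the mutual information (bits) of the
# two-position marginals of P(c1c2c3 | a, t): at small t only the 6-codon
# amino acids (Leu, Arg, Ser) can covary through synonymous change alone,
# so their MI starts high and decays with divergence, while single-codon
# amino acids (Met, Trp) start at 0 and rise as nonsynonymous
# substitutions accumulate.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

codon_env <- new.env(parent = emptyenv())

#' The standard genetic code over sense codons
#'
#' @return data frame with columns `codon` (RNA alphabet) and `aa`
#'   (one-letter amino acid); stop codons are excluded.
#' @export
genetic_code_table <- function() {
  if (is.null(codon_env$code)) {
    gc <- Biostrings::GENETIC_CODE
    codons <- chartr("T", "U", names(gc))
    tab <- data.frame(codon = codons, aa = unname(gc))
    codon_env$code <- tab[tab$aa != "*", ]
  }
  codon_env$code
}

#' Counts of codons per amino acid
#'
#' @return named integer vector over the 20 amino acids.  Exactly three
#'   amino acids (Leu, Arg, Ser) have six codons.
#' @export
codons_per_aa <- function() {
  tab <- genetic_code_table()
  out <- table(tab$aa)[AA20]
  stats::setNames(as.integer(out), AA20)
}

#' Codon bias distributions P(codon | amino acid)
#'
#' @param counts optional data frame (or TSV path) with columns `codon`
#'   and `count`; counts are normalized within each amino acid.  Default:
#'   uniform over synonymous codons.
#' @return 61 x 20 matrix; column `a` is a probability distribution over
#'   sense codons with mass only on codons of `a`.
#' @export
codon_bias <- function(counts = NULL) {
  tab <- genetic_code_table()
  B <- matrix(0, nrow(tab), 20L, dimnames = list(tab$codon, AA20))
  if (is.null(counts)) {
    for (a in AA20) {
      idx <- tab$aa == a
      B[idx, a] <- 1 / sum(idx)
    }
    return(B)
  }
  if (is.character(counts))
    counts <- utils::read.delim(counts, header = TRUE)
  stopifnot(all(c("codon", "count") %in% names(counts)))
  cd <- chartr("Tt", "UU", toupper(counts$codon))
  idx <- match(cd, tab$codon)
  if (anyNA(idx)) stop("unknown or stop codon in bias table: ",
                       paste(counts$codon[is.na(idx)], collapse = " "))
  w <- stats::setNames(rep(0, nrow(tab)), tab$codon)
  w[idx] <- counts$count
  for (a in AA20) {
    sel <- tab$aa == a
    tot <- sum(w[sel])
    B[sel, a] <- if (tot > 0) w[sel] / tot else 1 / sum(sel)
  }
  B
}

# Standard BLOSUM62 amino-acid background frequencies (the marginals used
# with the matrix in BLAST-style composition statistics).
BLOSUM62_BG <- c(
  A = 0.07422, R = 0.05161, N = 0.04465, D = 0.05363, C = 0.02469,
  Q = 0.03426, E = 0.05431, G = 0.07415, H = 0.02621, I = 0.06792,
  L = 0.09891, K = 0.05816, M = 0.02499, F = 0.04742, P = 0.03854,
  S = 0.05723, T = 0.05089, W = 0.01303, Y = 0.03228, V = 0.07292)

# BLOSUM62 joint (target) frequencies reconstructed from the half-bit
# score matrix and the standard background frequencies:
# q_ab proportional to p_a p_b 2^(s_ab / 2), normalized.  The integer
# rounding of the scores makes this approximate; the joint is symmetric,
# so the derived chain is reversible.
blosum62_joint <- function() {
  if (is.null(codon_env$qij)) {
    B <- get_blosum62()[AA20, AA20]
    p <- BLOSUM62_BG[AA20]
    q <- outer(p, p) * 2^(B / 2)
    codon_env$qij <- q / sum(q)
  }
  codon_env$qij
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Amino-acid substitution model derived from BLOSUM62
#'
#' The BLOSUM62 joint frequencies give a reversible conditional matrix
#' `P(b|a)`; its matrix logarithm (symmetrized eigendecomposition) gives a
#' rate matrix, negative off-diagonal entries are zeroed, the diagonal is
#' reset so rows sum to 0, and the rates are rescaled so that the expected
#' number of substitutions per site at `t = 1` is 1
#' (`sum_a pi_a (-R_aa) = 1`).
#'
#' @return list of class `aa_model`: `R` (20 x 20 rate matrix), `pi`
#'   (stationary distribution), `projected` (`TRUE` if negative
#'   off-diagonal rates had to be zeroed).
#' @export
build_amino_model <- function() {
  if (!is.null(codon_env$model)) return(codon_env$model)
  q <- blosum62_joint()
  pi0 <- rowSums(q)
  P <- q / pi0                       # rows: P(b | a)
  s <- sqrt(pi0)
  Sym <- (P * s) %*% diag(1 / s)     # diag(s) P diag(1/s), symmetric
  Sym <- (Sym + t(Sym)) / 2
  eig <- eigen(Sym, symmetric = TRUE)
  clamped <- any(eig$values < 1e-6)
  vals <- pmax(eig$values, 1e-6)  # projection for non-embeddable spectra
  logP <- eig$vectors %*% diag(log(vals)) %*% t(eig$vectors)
  R <- diag(1 / s) %*% logP %*% diag(s)
  projected <- clamped || any(R[row(R) != col(R)] < 0)
  R[R < 0 & row(R) != col(R)] <- 0
  diag(R) <- 0
  diag(R) <- -rowSums(R)
  # stationary distribution of the corrected rate matrix
  ns <- eigen(t(R))
  k <- which.min(abs(ns$values))
  pi_R <- Re(ns$vectors[, k])
  pi_R <- pi_R / sum(pi_R)
  R <- R / sum(pi_R * -diag(R))
  dimnames(R) <- list(AA20, AA20)
  out <- list(R = R, pi = stats::setNames(pi_R, AA20), projected = projected)
  class(out) <- "aa_model"
  codon_env$model <- out
  out
}

#' Amino-acid transition probabilities P(b | a, t)
#'
#' @param model an `aa_model` (default: [build_amino_model()]).
#' @param t divergence time (`>= 0`); `t = 1` corresponds to one expected
#'   substitution per site.
#' @return 20 x 20 row-stochastic matrix; the identity at `t = 0`.
#' @export
aa_transition <- function(t, model = build_amino_model()) {
  if (t < 0) stop("negative divergence time")
  if (t == 0) {
    P <- diag(20L); dimnames(P) <- dimnames(model$R)
    return(P)
  }
  P <- as.matrix(Matrix::expm(model$R * t))
  dimnames(P) <- dimnames(model$R)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Codon distribution P(c1c2c3 | a, t)
#'
#' @param a ancestral amino acid (one-letter code).
#' @param t divergence time (`>= 0`).
#' @param bias codon-bias matrix from [codon_bias()].
#' @param model an `aa_model`.
#' @return list of class `codon_distribution`: `probs` (named vector over
#'   the 61 sense codons, sums to 1), `a`, `t`.
#' @export
codon_distribution <- function(a, t, bias = codon_bias(),
                               model = build_amino_model()) {
  stopifnot(a %in% AA20)
  if (t < 0) stop("negative divergence time")
  pb <- aa_transition(t, model)[a, ]
  probs <- as.vector(bias %*% pb)
  names(probs) <- rownames(bias)
  out <- list(probs = probs, a = a, t = t)
  class(out) <- "codon_distribution"
  out
}

#' Two-position marginal of a codon distribution
#'
#' @param cd a `codon_distribution`.
#' @param pair `"c1c2"`, `"c1c3"` or `"c2c3"`.
#' @return 4 x 4 joint probability matrix over A, C, G, U.
#' @export
codon_pair_marginal <- function(cd, pair = c("c1c2", "c1c3", "c2c3")) {
  pair <- match.arg(pair)
  pos <- switch(pair, c1c2 = c(1L, 2L), c1c3 = c(1L, 3L), c2c3 = c(2L, 3L))
  codons <- names(cd$probs)
  r1 <- substr(codons, pos[1], pos[1])
  r2 <- substr(codons, pos[2], pos[2])
  m <- matrix(0, 4L, 4L, dimnames = list(c("A", "C", "G", "U"),
                                         c("A", "C", "G", "U")))
  for (k in seq_along(codons))
    m[r1[k], r2[k]] <- m[r1[k], r2[k]] + cd$probs[k]
  m
}

#' Expected within-codon covariation (MI)
#'
#' MI in bits of the named two-position marginal of `P(c1c2c3 | a, t)`.
#'
#' @inheritParams codon_distribution
#' @param pair `"c1c2"`, `"c1c3"` or `"c2c3"`.
#' @return MI in bits.
#' @export
within_codon_mi <- function(a, t, pair = c("c1c2", "c1c3", "c2c3"),
                            bias = codon_bias(),
                            model = build_amino_model()) {
  pair <- match.arg(pair)
  cd <- codon_distribution(a, t, bias, model)
  mi(codon_pair_marginal(cd, pair))
}

#' MI trajectory over a divergence grid
#'
#' @inheritParams within_codon_mi
#' @param t_grid increasing vector of divergence times.
#' @return data frame with columns `t` and `mi`.
#' @export
mi_trajectory <- function(a, pair, t_grid, bias = codon_bias(),
                          model = build_amino_model()) {
  stopifnot(all(t_grid >= 0), !is.unsorted(t_grid))
  data.frame(t = t_grid,
             mi = vapply(t_grid, function(tt)
               within_codon_mi(a, tt, pair, bias, model), numeric(1)))
}

#' Observed within-codon covariation per amino acid
#'
#' For each amino acid, the codon columns of its sites are analyzed as
#' their own sub-alignment against their own phylogenetic null (the
#' conditioning mirrors how within-codon covariation is reported per
#' encoded amino acid), and the fraction of that amino acid's codons with
#' at least one significantly covarying within-codon pair (c1-c2, c1-c3
#' or c2-c3) is returned.
#'
#' @param aln exon alignment from [simulate_exon_alignment()] (or any
#'   gap-free in-frame alignment of length `3 * length(protein)`).
#' @param protein per-site amino acids (the ancestral/reference protein).
#' @param n_nulls nulls per sub-alignment.
#' @param threshold E-value cutoff.
#' @param seed master seed.
#' @return named numeric vector over the amino acids present in
#'   `protein`: fraction of codons significantly covarying within-codon.
#' @export
observed_within_codon <- function(aln, protein, n_nulls = 30L,
                                  threshold = 0.05, seed = NULL) {
  if (length(protein) == 1L && nchar(protein[1]) > 1L)
    protein <- strsplit(protein, "")[[1]]
  stopifnot(n_col(aln) == 3L * length(protein))
  if (!is.null(seed)) set.seed(seed)
  aas <- unique(protein)
  seeds <- sample.int(.Machine$integer.max - 1L, length(aas))
  out <- vapply(seq_along(aas), function(ai) {
    a <- aas[ai]
    sites <- which(protein == a)
    cols <- as.vector(vapply(sites, function(k) 3L * (k - 1L) + 1:3,
                             integer(3)))
    sub <- rna_alignment(apply(aln$mat[, cols, drop = FALSE], 1L,
                               decode_row), aln$names)
    tr <- build_tree(sub)
    nd <- null_distribution(sub, tr, n_nulls = n_nulls, seed = seeds[ai])
    sm <- score_matrix(sub, "gtest")
    L <- n_col(sub)
    ev <- matrix(NA_real_, L, L)
    ut <- which(upper.tri(ev), arr.ind = TRUE)
    ev[ut] <- evalue(sm$apc[ut], nd)
    mean(vapply(seq_along(sites), function(kk) {
      c1 <- 3L * (kk - 1L) + 1L
      any(c(ev[c1, c1 + 1L], ev[c1, c1 + 2L], ev[c1 + 1L, c1 + 2L]) <
            threshold)
    }, logical(1)))
  }, numeric(1))
  stats::setNames(out, aas)
}

#' Simulate a star-topology protein-coding exon alignment
#'
#' Each sequence descends independently from the ancestral protein: per
#' site, an amino acid is drawn from `P(b | a, t)` and a codon from the
#' bias of `b`.  No indels.
#'
#' @param protein ancestral protein (character vector of one-letter codes,
#'   or a single string).
#' @param t divergence time.
#' @param n_sequences number of descendant sequences.
#' @inheritParams codon_distribution
#' @param seed integer seed.
#' @return an `rna_alignment` of length `3 * length(protein)`, with
#'   attribute `ancestral_protein`.
#' @export
simulate_exon_alignment <- function(protein, t, n_sequences,
                                    bias = codon_bias(),
                                    model = build_amino_model(),
                                    seed = NULL) {
  if (length(protein) == 1L && nchar(protein[1]) > 1L)
    protein <- strsplit(protein, "")[[1]]
  stopifnot(all(protein %in% AA20))
  if (!is.null(seed)) set.seed(seed)
  Pt <- aa_transition(t, model)
  codons <- rownames(bias)
  seqs <- vapply(seq_len(n_sequences), function(s) {
    cod <- vapply(protein, function(a) {
      b <- sample(AA20, 1L, prob = Pt[a, ])
      sample(codons, 1L, prob = bias[, b])
    }, character(1))
    paste(cod, collapse = "")
  }, character(1))
  out <- rna_alignment(seqs, names = sprintf("seq%03d", seq_len(n_sequences)))
  attr(out, "ancestral_protein") <- protein
  out
}
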