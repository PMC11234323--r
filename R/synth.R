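# Synthetic alignment generators: structure-constrained evolution along a
# tree, and scenario generators reproducing known covariation artifacts.
#
# Paired columns evolve jointly under a compensatory kernel (default 80%
# double-compensatory, 15% half-compensatory, 5% pair-breaking proposals);
# unpaired columns evolve independently.  Branch lengths are expected
# substitution events per site (per pair for paired columns).

STRICT_WC <- rbind(c(1L, 4L), c(4L, 1L), c(2L, 3L), c(3L, 2L))  # AU UA CG GC
WOBBLE <- rbind(c(3L, 4L), c(4L, 3L))                            # GU UG

# all (side, residue) changes turning pair (x, y) into a WC/wobble pair
half_moves <- function(x, y) {
  ok <- rbind(STRICT_WC, WOBBLE)
  moves <- NULL
  for (r in 1:4) {
    if (r != x && any(ok[, 1] == r & ok[, 2] == y))
      moves <- rbind(moves, c(1L, r))
    if (r != y && any(ok[, 1] == x & ok[, 2] == r))
      moves <- rbind(moves, c(2L, r))
  }
  moves
}

# one proposal on a paired site
pair_event <- function(x, y, kernel) {
  type <- sample(c("double", "half", "brk"), 1L, prob = kernel)
  if (type == "double") {
    cand <- STRICT_WC[!(STRICT_WC[, 1] == x & STRICT_WC[, 2] == y), , drop = FALSE]
    cand[sample.int(nrow(cand), 1L), ]
  } else if (type == "half") {
    mv <- half_moves(x, y)
    if (is.null(mv)) return(c(x, y))
    m <- mv[sample.int(nrow(mv), 1L), ]
    if (m[1] == 1L) c(m[2], y) else c(x, m[2])
  } else {
    side <- sample(1:2, 1L)
    res <- sample(setdiff(1:4, if (side == 1L) x else y), 1L)
    if (side == 1L) c(res, y) else c(x, res)
  }
}

# random coalescent tree rescaled to a given root-to-tip height, or a star
sim_tree <- function(n_seq, divergence, topology = c("coalescent", "star")) {
  topology <- match.arg(topology)
  nms <- sprintf("t%03d", seq_len(n_seq))
  if (topology == "star") {
    txt <- paste0("(", paste(sprintf("%s:%f", nms, divergence),
                             collapse = ","), ");")
    return(ape::read.tree(text = txt))
  }
  tree <- ape::rcoal(n_seq, tip.label = nms)
  h <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * divergence / h
  tree
}

#' Balanced tree with a fixed root-to-tip height
#'
#' Every branch has the same length; useful as a low-variance divergence
#' scaffold for power studies (coalescent trees put most of their length
#' in a few deep branches, making per-pair substitution counts erratic).
#'
#' @param n_seq number of leaves (a power of 2).
#' @param height root-to-tip expected substitutions per site.
#' @return a `phylo` object.
#' @export
balanced_tree <- function(n_seq, height) {
  stopifnot(n_seq >= 2L, bitwAnd(n_seq, n_seq - 1L) == 0L)
  tree <- ape::stree(n_seq, "balanced")
  depth <- log2(n_seq)
  tree$edge.length <- rep(height / depth, nrow(tree$edge))
  tree$tip.label <- sprintf("t%03d", seq_len(n_seq))
  tree
}

#' Simulate an alignment with (optionally) a conserved structure
#'
#' Evolves a root sequence down a tree.  Base-paired columns propose
#' compensatory changes under `kernel`; unpaired columns substitute
#' independently (Jukes-Cantor-like jumps).  Event counts per branch are
#' Poisson with mean `branch length` per unpaired column and per pair.
#'
#' @param n_seq number of sequences.
#' @param L alignment length.
#' @param pairs proposed structure: data frame with `i`, `j`, or an
#'   integer (number of nested pairs placed as `(k, L - k + 1)`), or
#'   `NULL`/0 for a structure-free alignment.
#' @param divergence root-to-tip height (expected substitutions per site).
#' @param tree optional `phylo`; overrides `topology`/`divergence`.
#' @param topology `"coalescent"` (default) or `"star"`.
#' @param gap_prob per-column gap probability at the leaves (scalar or
#'   length-`L` vector).
#' @param pseudogene_fraction fraction of leaves whose terminal branch
#'   evolves without the paired-site kernel (dead copies).
#' @param pseudogene_rate rate multiplier on those terminal branches.
#' @param kernel proposal weights `c(double = , half = , brk = )`.
#' @param seed integer seed.
#' @return list: `alignment` (with the structure attached when pairs were
#'   constrained), `pairs` (truth labels), `tree`, `pseudogenes` (leaf
#'   names evolved unconstrained).
#' @export
simulate_structural_alignment <- function(n_seq, L, pairs = NULL,
                                          divergence = 0.5, tree = NULL,
                                          topology = "coalescent",
                                          gap_prob = 0,
                                          pseudogene_fraction = 0,
                                          pseudogene_rate = 2,
                                          kernel = c(double = 0.8,
                                                     half = 0.15,
                                                     brk = 0.05),
                                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(pseudogene_fraction >= 0, pseudogene_fraction <= 1)
  if (is.numeric(pairs) && length(pairs) == 1L) {
    n_pairs <- as.integer(pairs)
    pairs <- if (n_pairs > 0L)
      data.frame(i = seq_len(n_pairs), j = L - seq_len(n_pairs) + 1L)
    else NULL
  }
  if (!is.null(pairs) && nrow(pairs)) {
    stopifnot(all(pairs$j <= L), all(pairs$j - pairs$i > 3L))
  }
  if (is.null(tree)) tree <- sim_tree(n_seq, divergence, topology)
  ord <- tree_orders(tree)
  edge <- ord$edge
  n_tip <- ord$n_tip
  paired_cols <- if (is.null(pairs)) integer(0) else c(pairs$i, pairs$j)
  unpaired <- setdiff(seq_len(L), paired_cols)
  pseudo <- character(0)
  if (pseudogene_fraction > 0) {
    n_pg <- round(pseudogene_fraction * n_tip)
    pseudo <- sample(tree$tip.label, n_pg)
  }
  states <- matrix(NA_integer_, ord$n_node, L)
  root <- integer(L)
  root[unpaired] <- sample.int(4L, length(unpaired), replace = TRUE)
  if (!is.null(pairs)) for (k in seq_len(nrow(pairs))) {
    wc <- STRICT_WC[sample.int(4L, 1L), ]
    root[pairs$i[k]] <- wc[1]; root[pairs$j[k]] <- wc[2]
  }
  states[ord$root, ] <- root
  elen <- tree$edge.length
  for (e in rev(seq_len(nrow(edge)))) {   # preorder
    parent <- edge[e, 1]; child <- edge[e, 2]
    b <- elen[e]
    seqv <- states[parent, ]
    is_pg <- child <= n_tip && tree$tip.label[child] %in% pseudo
    if (is_pg) b <- b * pseudogene_rate
    cols_free <- if (is_pg) seq_len(L) else unpaired
    n_ev <- stats::rpois(length(cols_free), b)
    for (ci in which(n_ev > 0L)) {
      col <- cols_free[ci]
      for (rep_ in seq_len(n_ev[ci]))
        seqv[col] <- sample(setdiff(1:4, seqv[col]), 1L)
    }
    if (!is.null(pairs) && !is_pg) {
      n_pev <- stats::rpois(nrow(pairs), b)
      for (k in which(n_pev > 0L)) {
        for (rep_ in seq_len(n_pev[k])) {
          xy <- pair_event(seqv[pairs$i[k]], seqv[pairs$j[k]], kernel)
          seqv[pairs$i[k]] <- xy[1]; seqv[pairs$j[k]] <- xy[2]
        }
      }
    }
    states[child, ] <- seqv
  }
  gp <- rep(gap_prob, length.out = L)
  mat <- states[seq_len(n_tip), , drop = FALSE]
  if (any(gp > 0)) {
    mask <- matrix(stats::runif(n_tip * L), n_tip, L) <
      matrix(gp, n_tip, L, byrow = TRUE)
    mat[mask] <- 0L
  }
  seqs <- apply(mat, 1L, decode_row)
  structure <- if (!is.null(pairs) && nrow(pairs))
    data.frame(i = pairs$i, j = pairs$j, pseudoknot = FALSE,
               short_range = (pairs$j - pairs$i) <= 3L)
  else NULL
  aln <- rna_alignment(seqs, names = tree$tip.label, structure = structure)
  list(alignment = aln, pairs = pairs, tree = tree, pseudogenes = pseudo)
}

#' Occupancy-bias scenario
#'
#' Structure-free alignment whose left half has low occupancy (many gaps)
#' and right half high occupancy.  With non-gap-preserving ("legacy")
#' nulls, an occupancy-sensitive statistic such as the G-test scores the
#' high-occupancy pairs against nulls of intermediate occupancy, creating
#' spurious significance; gap-preserving nulls do not.  MI on frequencies
#' is agnostic to occupancy.
#'
#' @param n_seq,L,divergence,seed as in [simulate_structural_alignment()].
#' @param gap_low gap probability for the left half (default 0.45).
#' @param gap_high gap probability for the right half (default 0.05).
#' @return list as in [simulate_structural_alignment()].
#' @export
make_gap_bias_scenario <- function(n_seq, L, divergence = 0.5,
                                   gap_low = 0.45, gap_high = 0.05,
                                   seed = NULL) {
  gp <- c(rep(gap_low, floor(L / 2)), rep(gap_high, ceiling(L / 2)))
  simulate_structural_alignment(n_seq, L, pairs = NULL,
                                divergence = divergence, gap_prob = gp,
                                seed = seed)
}

#' Conserved-column trap
#'
#' A structure-free alignment in which the proposed pairs connect two
#' completely invariant, Watson-Crick-complementary columns.  With an
#' invariant column there is, by definition, no covariation: MI is exactly
#' 0 and the G-test reduces to its marginal-only value (0), so the default
#' pipeline finds nothing.  A statistic that rewards conservation (RAF)
#' scored against conservation-destroying nulls calls these pairs
#' significant -- the artifact this generator reproduces.
#'
#' @param n_seq,L,divergence,seed as in [simulate_structural_alignment()].
#' @param n_pairs number of trap pairs.
#' @return list: `alignment` (with the trap structure attached), `pairs`.
#' @export
make_conserved_column_trap <- function(n_seq, L, n_pairs = 3L,
                                       divergence = 0.5, seed = NULL) {
  sim <- simulate_structural_alignment(n_seq, L, pairs = NULL,
                                       divergence = divergence, seed = seed)
  aln <- sim$alignment
  stopifnot(L >= 2L * n_pairs + 4L)
  pairs <- data.frame(i = seq_len(n_pairs), j = L - seq_len(n_pairs) + 1L)
  right <- rep_len(c(2L, 3L, 1L, 4L), n_pairs)          # C G A U ...
  complement <- c(4L, 3L, 2L, 1L)                       # A<->U, C<->G
  for (k in seq_len(n_pairs)) {
    aln$mat[, pairs$j[k]] <- right[k]
    aln$mat[, pairs$i[k]] <- complement[right[k]]
  }
  aln$structure <- data.frame(i = pairs$i, j = pairs$j, pseudoknot = FALSE,
                              short_range = (pairs$j - pairs$i) <= 3L)
  list(alignment = aln, pairs = pairs)
}

#' Pseudogene mixture
#'
#' Structure-constrained alignment in which a fraction of the sequences
#' are dead copies: their terminal branches evolve without the paired-site
#' kernel (and faster).  Substitutions in the dead copies raise apparent
#' power at the proposed pairs while diluting the covariation signal.
#'
#' @inheritParams simulate_structural_alignment
#' @param f pseudogene fraction in `[0, 1]`.
#' @return list as in [simulate_structural_alignment()]; `pseudogenes`
#'   names the dead copies.
#' @export
make_pseudogene_mixture <- function(n_seq, L, pairs, f, divergence = 0.5,
                                    seed = NULL, ...) {
  simulate_structural_alignment(n_seq, L, pairs = pairs,
                                divergence = divergence,
                                pseudogene_fraction = f, seed = seed, ...)
}

#' Misaligned-helix scenario
#'
#' Simulates a helix under the compensatory kernel, then shifts the helix
#' block by one pair in a subset of rows: the 5' strand moves right and
#' the 3' strand left, so every interior base pair is preserved in the
#' shifted rows but sits at the wrong columns.  The misaligned version
#' loses sequence conservation in the helix columns and gains spurious
#' covariation; the corrected version is the unshifted alignment.
#'
#' @param n_seq,L,divergence,seed as in [simulate_structural_alignment()].
#' @param helix_len number of base pairs in the helix.
#' @param shift_fraction fraction of rows shifted.
#' @return list: `misaligned`, `corrected` (both `rna_alignment`s with the
#'   same structure), `pairs`, `shifted_rows`.
#' @export
make_misaligned_helix <- function(n_seq, L, helix_len = 6L,
                                  divergence = 0.8, shift_fraction = 0.4,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  a <- 3L
  b <- L - 2L - helix_len + 1L
  stopifnot(b - (a + helix_len - 1L) > 3L)
  pairs <- data.frame(i = a + seq_len(helix_len) - 1L,
                      j = rev(b + seq_len(helix_len) - 1L))
  sim <- simulate_structural_alignment(n_seq, L, pairs = pairs,
                                       divergence = divergence)
  corrected <- sim$alignment
  mis <- corrected
  n_shift <- round(shift_fraction * n_seq)
  rows <- sample.int(n_seq, n_shift)
  five <- a:(a + helix_len - 1L)
  three <- b:(b + helix_len - 1L)
  for (r in rows) {
    m <- mis$mat[r, ]
    m[five[-1]] <- m[five[-helix_len]]
    m[five[1]] <- sample.int(4L, 1L)
    m[three[-helix_len]] <- m[three[-1]]
    m[three[helix_len]] <- sample.int(4L, 1L)
    mis$mat[r, ] <- m
  }
  list(misaligned = mis, corrected = corrected, pairs = pairs,
       shifted_rows = sort(rows))
}
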