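# Phylogenetic null alignments.
#
# A null alignment carries the same per-branch substitution events as a
# fresh ancestral sample of the input, but each residue substitution is
# re-placed at a position chosen uniformly among eligible positions of the
# evolving sequence currently holding the event's from-residue.  Because
# descendants inherit placed substitutions, clade-inherited (phylogenetic)
# covariation survives while site-specific pairwise covariation is
# destroyed.  Per-sequence base composition is preserved; per-column
# conservation is deliberately NOT preserved.
#
# Gap handling, gap-preserving mode (default): columns with any gap
# anywhere in the sampled tree history keep their sampled content verbatim
# (so gap masks are bit-identical to the source), and residue events at
# tree-wide resident columns are re-placed among those resident columns.
# Legacy mode re-places every event, indels included, which scrambles
# occupancy -- kept to reproduce the occupancy-bias artifact.
#
# Within a branch, events are applied in random order at positions not yet
# touched on that branch, so the null's parent/child differences recount
# exactly to the sampled per-branch event totals.

#' Synthesize one phylogenetic null alignment
#'
#' A fresh ancestral sample is drawn (each null uses its own sample), its
#' per-branch events are counted, and the root sequence is evolved down the
#' tree with events re-placed at random as described above.
#'
#' @param aln source `rna_alignment`.
#' @param tree rooted binary tree matching the alignment (default:
#'   [build_tree()]).
#' @param seed integer seed for the ancestral sample and the placements.
#' @param gap_preserving keep the source gap structure (default `TRUE`).
#' @return an `rna_alignment` with identical names, dimensions, per-branch
#'   event counts and per-sequence composition as the source; attributes
#'   `provenance`, `gap_preserving`, `fallback_events` (events whose
#'   placement rule had to be relaxed, composition then not guaranteed),
#'   `submap` (the sampled substitution map) and `null_states` (the full
#'   node-by-column state matrix of the null, for invariant checks).
#' @export
synthesize_null <- function(aln, tree = NULL, seed = NULL,
                            gap_preserving = TRUE) {
  if (is.null(tree)) tree <- build_tree(aln)
  if (!is.null(seed)) set.seed(seed)
  smp <- fitch_sample(aln, tree)         # fresh sample per null
  map <- count_substitutions(smp)
  ord <- tree_orders(tree)
  edge <- ord$edge
  L <- ncol(smp$states)
  free <- colSums(smp$states == 0L) == 0L  # resident in every node
  null_states <- smp$states              # pinned columns keep sampled content
  null_states[, free] <- NA_integer_
  null_states[ord$root, free] <- smp$states[ord$root, free]
  ev <- map$events
  movable <- if (gap_preserving) free[ev$col] else rep(TRUE, nrow(ev))
  ev_by_branch <- split(which(movable), ev$branch[movable])
  fallback <- 0L
  for (k in rev(seq_len(nrow(edge)))) {  # preorder
    parent <- edge[k, 1]; child <- edge[k, 2]
    seqv <- null_states[parent, ]
    if (gap_preserving) {
      # child inherits its own sampled content at pinned columns
      seqv[!free] <- smp$states[child, !free]
    }
    touched <- rep(FALSE, L)
    rows <- ev_by_branch[[as.character(child)]]
    if (length(rows) > 1L) rows <- sample(rows)
    ok_cols <- if (gap_preserving) free else rep(TRUE, L)
    for (r in rows) {
      x <- ev$from[r]; y <- ev$to[r]
      elig <- which(seqv == x & !touched & ok_cols)
      if (length(elig)) {
        pos <- elig[sample.int(length(elig), 1L)]
      } else {
        fallback <- fallback + 1L
        elig <- which(!touched & ok_cols & seqv != 0L)
        if (!length(elig)) next
        pos <- elig[sample.int(length(elig), 1L)]
      }
      seqv[pos] <- y
      touched[pos] <- TRUE
    }
    null_states[child, ] <- seqv
  }
  tips <- seq_len(ord$n_tip)
  seqs <- apply(null_states[tips, , drop = FALSE], 1L, decode_row)
  out <- rna_alignment(seqs, names = tree$tip.label,
                       structure = aln$structure)
  # restore source row order
  ord_idx <- match(aln$names, out$names)
  out$mat <- out$mat[ord_idx, , drop = FALSE]
  out$names <- aln$names
  attr(out, "provenance") <- sprintf(
    "null alignment; gap_preserving=%s; seed=%s", gap_preserving,
    ifelse(is.null(seed), "NA", seed))
  attr(out, "gap_preserving") <- gap_preserving
  attr(out, "fallback_events") <- fallback
  attr(out, "sample_seed") <- seed
  attr(out, "submap") <- map
  attr(out, "null_states") <- null_states
  out
}

#' Ensemble of null alignments
#'
#' Independent per-null seeds are derived from the master seed, so the
#' whole ensemble is reproducible.
#'
#' @inheritParams synthesize_null
#' @param n_nulls number of null alignments (`>= 1`).
#' @return list of null `rna_alignment`s.
#' @export
null_ensemble <- function(aln, tree = NULL, n_nulls = 20L, seed = NULL,
                          gap_preserving = TRUE) {
  stopifnot(n_nulls >= 1L)
  if (is.null(tree)) tree <- build_tree(aln)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_nulls)
  lapply(seeds, function(s)
    synthesize_null(aln, tree, seed = s, gap_preserving = gap_preserving))
}

#' Per-sequence residue composition
#'
#' @param aln an `rna_alignment`.
#' @return S x 5 matrix: counts of gap, A, C, G, U per row.
#' @export
composition <- function(aln) {
  out <- t(apply(aln$mat + 1L, 1L, tabulate, nbins = 5L))
  colnames(out) <- RNA_STATES
  rownames(out) <- aln$names
  out
}
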