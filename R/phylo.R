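# Tree inference and Fitch-parsimony ancestral sampling.
#
# The tree is only a scaffold for the null model: neighbor-joining on
# Jukes-Cantor-corrected distances, midpoint-rooted.  Fitch parsimony runs
# on five states (gap is a fifth character), so indel events are tracked as
# branch events; substitution totals used for covariation power count
# residue-to-residue events only.

# ---- distances and tree ----------------------------------------------------

#' Jukes-Cantor pairwise distance matrix
#'
#' p-distances over jointly occupied columns, JC69-corrected
#' (`d = -3/4 log(1 - 4p/3)`), with `p` capped just below saturation.
#'
#' @param aln an `rna_alignment`.
#' @return S x S distance matrix.
#' @export
jc_distances <- function(aln) {
  m <- aln$mat
  S <- nrow(m)
  d <- matrix(0, S, S, dimnames = list(aln$names, aln$names))
  for (s in seq_len(S - 1L)) {
    for (t in (s + 1L):S) {
      both <- m[s, ] > 0L & m[t, ] > 0L
      p <- if (any(both)) mean(m[s, both] != m[t, both]) else 0
      p <- min(p, 0.70)  # keep the JC log finite
      d[s, t] <- d[t, s] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  d
}

#' Build a phylogenetic tree from an alignment
#'
#' Neighbor-joining on Jukes-Cantor distances, midpoint-rooted.
#' Deterministic given the alignment.  Negative NJ branch lengths are
#' clamped to zero.
#'
#' @param aln an `rna_alignment` with `S >= 2`.
#' @return a rooted binary `phylo` object (class from \pkg{ape}) whose tip
#'   labels equal the alignment names.
#' @export
build_tree <- function(aln) {
  S <- n_seq(aln)
  if (S < 2L) stop("need at least 2 sequences")
  d <- jc_distances(aln)
  if (S == 2L) {
    txt <- sprintf("(%s:%f,%s:%f);", aln$names[1], d[1, 2] / 2,
                   aln$names[2], d[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  tree <- ape::nj(as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 0
  rooted <- tryCatch(phangorn::midpoint(tree),
                     error = function(e) NULL)
  if (is.null(rooted) || !ape::is.rooted(rooted))
    rooted <- ape::root(tree, outgroup = sort(tree$tip.label)[1],
                        resolve.root = TRUE)
  rooted <- ape::multi2di(rooted)
  rooted$edge.length[is.na(rooted$edge.length)] <- 0
  rooted
}

#' Read a user-supplied Newick tree for an alignment
#'
#' @param path Newick file.
#' @param aln the alignment the tree must match.
#' @return rooted binary `phylo`; an error if the leaf set differs from the
#'   alignment names.
#' @export
read_tree <- function(path, aln) {
  tree <- ape::read.tree(path)
  if (!setequal(tree$tip.label, aln$names))
    stop("tree leaves do not match alignment names")
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  ape::multi2di(tree)
}

# ---- Fitch machinery -------------------------------------------------------

# Bitmask lookups for 5 states (bit value 2^state; state 0 = gap).
.fitch_env <- new.env(parent = emptyenv())

fitch_tables <- function() {
  if (is.null(.fitch_env$popcount)) {
    pop <- integer(32L)
    kth <- matrix(NA_integer_, 32L, 5L)
    for (mask in 1:31) {
      bits <- which(bitwAnd(mask, 2L^(0:4)) > 0L) - 1L  # states present
      pop[mask + 1L] <- length(bits)
      kth[mask + 1L, seq_along(bits)] <- bits
    }
    .fitch_env$popcount <- pop
    .fitch_env$kth <- kth
  }
  list(pop = .fitch_env$popcount, kth = .fitch_env$kth)
}

# Uniformly sample one set bit (state) per mask; vectorized.
sample_state <- function(masks) {
  tb <- fitch_tables()
  n <- tb$pop[masks + 1L]
  k <- floor(stats::runif(length(masks)) * n) + 1L
  tb$kth[cbind(masks + 1L, k)]
}

# Tree traversal orders for a rooted binary phylo.
tree_orders <- function(tree) {
  post <- ape::reorder.phylo(tree, "postorder")
  list(edge = post$edge, n_tip = length(tree$tip.label),
       n_node = max(post$edge), root = post$edge[nrow(post$edge), 1])
}

#' Sample ancestral sequences by Fitch parsimony
#'
#' Five-state Fitch (gap as fifth state), column-vectorized.  The down-pass
#' computes the parsimony state sets and minimal cost per column; the
#' up-pass samples one assignment, breaking ties uniformly at random among
#' the down-pass state sets.  Reproducible under a fixed seed.
#'
#' @param aln an `rna_alignment`.
#' @param tree rooted binary tree with tips matching the alignment names.
#' @param seed optional integer seed.
#' @return list of class `ancestral_sample`: `states` (n_node x L integer
#'   matrix over 0..4, rows 1..S are the tips in `tree$tip.label` order),
#'   `cost` (per-column parsimony minimum), `tree`, `seed`.
#' @export
fitch_sample <- function(aln, tree, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ord <- tree_orders(tree)
  L <- n_col(aln)
  idx <- match(tree$tip.label, aln$names)
  if (anyNA(idx)) stop("tree leaves do not match alignment names")
  masks <- matrix(0L, ord$n_node, L)
  masks[seq_len(ord$n_tip), ] <- bitwShiftL(1L, aln$mat[idx, , drop = FALSE])
  cost <- integer(L)
  edge <- ord$edge
  # postorder down-pass: children come before parents
  kids <- split(edge[, 2], edge[, 1])
  for (parent in unique(edge[, 1])) {
    ch <- kids[[as.character(parent)]]
    acc <- masks[ch[1], ]
    for (c2 in ch[-1]) {
      inter <- bitwAnd(acc, masks[c2, ])
      un <- bitwOr(acc, masks[c2, ])
      hit <- inter > 0L
      cost <- cost + !hit
      acc <- ifelse(hit, inter, un)
    }
    masks[parent, ] <- acc
  }
  # preorder up-pass with randomized tie-breaking
  states <- matrix(NA_integer_, ord$n_node, L)
  states[ord$root, ] <- sample_state(masks[ord$root, ])
  for (k in rev(seq_len(nrow(edge)))) {
    parent <- edge[k, 1]; child <- edge[k, 2]
    pbit <- bitwShiftL(1L, states[parent, ])
    keep <- bitwAnd(pbit, masks[child, ]) > 0L
    st <- states[parent, ]
    if (any(!keep)) st[!keep] <- sample_state(masks[child, !keep, drop = TRUE])
    states[child, ] <- st
  }
  out <- list(states = states, cost = cost, tree = tree, seed = seed)
  class(out) <- "ancestral_sample"
  out
}

#' Per-branch, per-column substitution events of an ancestral sample
#'
#' A branch is identified by its child node.  Events are every
#' parent-child state difference; residue-to-residue events (neither side
#' a gap) are the ones that feed covariation power.
#'
#' @param sample an `ancestral_sample`.
#' @return list of class `substitution_map`: `events` (data frame `branch`
#'   = child node id, `col`, `from`, `to` as integer states 0..4),
#'   `n_branch` (events per branch, named by child node), `s_col` (events
#'   per column), `s_col_res` (residue-only events per column),
#'   `incidence` (edges x L logical, residue events), `tree`.
#' @export
count_substitutions <- function(sample) {
  tree <- sample$tree
  edge <- tree$edge
  L <- ncol(sample$states)
  evs <- vector("list", nrow(edge))
  inc <- matrix(FALSE, nrow(edge), L)
  for (k in seq_len(nrow(edge))) {
    p <- sample$states[edge[k, 1], ]
    c_ <- sample$states[edge[k, 2], ]
    dif <- which(p != c_)
    evs[[k]] <- data.frame(branch = rep(edge[k, 2], length(dif)),
                           col = dif, from = p[dif], to = c_[dif])
    inc[k, dif[p[dif] > 0L & c_[dif] > 0L]] <- TRUE
  }
  events <- do.call(rbind, evs)
  res <- events$from > 0L & events$to > 0L
  out <- list(
    events = events,
    n_branch = tabulate(match(events$branch, edge[, 2]), nrow(edge)),
    s_col = tabulate(events$col, L),
    s_col_res = tabulate(events$col[res], L),
    incidence = inc,
    tree = tree)
  class(out) <- "substitution_map"
  out
}

#' Single- and double-substitution counts for a column pair
#'
#' `single` is the sum of residue substitutions in the two columns;
#' `double` is the number of branches carrying at least one residue event
#' at both columns simultaneously.
#'
#' @param map a `substitution_map`.
#' @param i,j column indices.
#' @return named numeric vector `c(single = , double = )`.
#' @export
pair_substitution_counts <- function(map, i, j) {
  stopifnot(i != j)
  c(single = map$s_col_res[i] + map$s_col_res[j],
    double = sum(map$incidence[, i] & map$incidence[, j]))
}
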