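# Shared fixtures, built in code.

# iid random alignment with optional gaps
random_alignment <- function(S, L, gap = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chars <- matrix(sample(c("A", "C", "G", "U"), S * L, replace = TRUE), S, L)
  if (gap > 0) chars[matrix(runif(S * L) < gap, S, L)] <- "-"
  rna_alignment(apply(chars, 1L, paste, collapse = ""),
                names = sprintf("s%02d", seq_len(S)))
}

write_tmp_stockholm <- function(lines) {
  path <- tempfile(fileext = ".sto")
  writeLines(lines, path)
  path
}

# brute-force 16-term MI (independent oracle for mi())
mi_bruteforce <- function(p) {
  total <- 0
  pi_ <- rowSums(p); pj <- colSums(p)
  for (a in 1:4) for (b in 1:4) {
    if (p[a, b] > 0)
      total <- total + p[a, b] * log2(p[a, b] / (pi_[a] * pj[b]))
  }
  unname(total)
}

# brute-force APC (independent oracle for apc())
apc_bruteforce <- function(m) {
  L <- ncol(m)
  out <- m
  rowm <- sapply(1:L, function(i) mean(m[i, -i]))
  grand <- mean(m[upper.tri(m)])
  for (i in 1:L) for (j in 1:L)
    out[i, j] <- m[i, j] - rowm[i] * rowm[j] / grand
  diag(out) <- NA_real_
  out
}

# exhaustive minimum parsimony cost of one column (5 states incl. gap)
fitch_bruteforce_cost <- function(tree, leaf_states) {
  edge <- tree$edge
  n_tip <- length(tree$tip.label)
  internal <- sort(unique(edge[, 1]))
  n_int <- length(internal)
  best <- Inf
  grid <- as.matrix(expand.grid(rep(list(0:4), n_int)))
  for (g in seq_len(nrow(grid))) {
    assign_ <- c(leaf_states, rep(NA_integer_, n_int))
    assign_[internal] <- grid[g, ]
    cost <- sum(assign_[edge[, 1]] != assign_[edge[, 2]])
    best <- min(best, cost)
  }
  best
}
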