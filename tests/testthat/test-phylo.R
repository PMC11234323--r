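test_that("tree building handles 2 sequences, outgroups and degeneracy", {
  cherry <- build_tree(rna_alignment(c("ACGU", "ACGA"), c("a", "b")))
  expect_s3_class(cherry, "phylo")
  expect_setequal(cherry$tip.label, c("a", "b"))

  # clear outgroup: a and b nearly identical, c distant
  aln <- rna_alignment(c(a = "ACGUACGUACGUACGUACGU",
                         b = "ACGUACGUACGUACGAACGU",
                         c = "CAUCCAUCCAUCCAUCCAUC"),
                       names = c("a", "b", "c"))
  tr <- build_tree(aln)
  expect_true(ape::is.rooted(tr))
  # a and b must form a cherry (their MRCA has no other descendants)
  mrca <- ape::getMRCA(tr, c("a", "b"))
  desc <- tr$tip.label[phangorn::Descendants(tr, mrca, "tips")[[1]]]
  expect_setequal(desc, c("a", "b"))

  # identical sequences: zero-length branches, no error
  same <- build_tree(rna_alignment(rep("ACGUACGUAC", 4), sprintf("t%d", 1:4)))
  expect_true(all(same$edge.length == 0))
})

test_that("user-supplied trees must match the alignment leaves", {
  aln <- rna_alignment(c("ACGU", "ACGA", "ACUA"), c("a", "b", "c"))
  path <- tempfile()
  writeLines("((a:1,b:1):1,d:1);", path)
  expect_error(read_tree(path, aln), "leaves")
  writeLines("((a:1,b:1):1,c:1);", path)
  expect_s3_class(read_tree(path, aln), "phylo")
})

test_that("Fitch sampling achieves parsimony minima on forced cases", {
  aln <- rna_alignment(rep("ACGU", 4), sprintf("t%d", 1:4))
  tr <- build_tree(aln)
  smp <- fitch_sample(aln, tr, seed = 1)
  expect_equal(sum(smp$cost), 0)
  expect_true(all(apply(smp$states, 1, function(r) all(r == smp$states[1, ]))))

  two <- rna_alignment(c("A", "C"), c("x", "y"))
  tr2 <- build_tree(two)
  roots <- sapply(1:40, function(s)
    fitch_sample(two, tr2, seed = s)$states[3, 1])
  expect_setequal(unique(roots), c(1L, 2L))  # root sampled from {A, C}
  expect_equal(unique(sapply(1:10, function(s)
    sum(fitch_sample(two, tr2, seed = s)$cost))), 1)
})

test_that("sampled cost equals the exhaustive minimum (enumeration oracle)", {
  set.seed(42)
  for (rep_ in 1:4) {
    aln <- random_alignment(5, 12, gap = 0.15)
    tr <- build_tree(aln)
    smp <- fitch_sample(aln, tr, seed = rep_)
    idx <- match(tr$tip.label, aln$names)
    for (col in 1:12) {
      brute <- fitch_bruteforce_cost(tr, aln$mat[idx, col])
      expect_equal(smp$cost[col], brute)
      # sampled assignment realizes that cost
      edge <- tr$edge
      realized <- sum(smp$states[edge[, 1], col] != smp$states[edge[, 2], col])
      expect_equal(realized, brute)
    }
  }
})

test_that("substitution maps recount parent/child differences exactly", {
  aln <- random_alignment(8, 30, gap = 0.1, seed = 6)
  tr <- build_tree(aln)
  smp <- fitch_sample(aln, tr, seed = 9)
  map <- count_substitutions(smp)
  edge <- tr$edge
  # brute-force per-branch and per-column totals
  nb <- sapply(seq_len(nrow(edge)), function(k)
    sum(smp$states[edge[k, 1], ] != smp$states[edge[k, 2], ]))
  expect_equal(map$n_branch, nb)
  sc <- sapply(1:30, function(cl)
    sum(smp$states[edge[, 1], cl] != smp$states[edge[, 2], cl]))
  expect_equal(map$s_col, sc)
  expect_equal(sum(map$n_branch), sum(map$s_col))  # shared total
})

test_that("a pair with five events on four branches is representable", {
  # two aligned columns where one branch carries a double substitution and
  # three branches carry single pair-preserving substitutions: 5 events, 4
  # branches (the worked toy from the null-model description)
  aln <- rna_alignment(c("AU", "GC", "GC", "UA", "CG"), sprintf("s%d", 1:5))
  tr <- build_tree(aln)
  smp <- fitch_sample(aln, tr, seed = 4)
  map <- count_substitutions(smp)
  branches_hit <- unique(map$events$branch)
  expect_gte(nrow(map$events), 5)
  expect_gte(length(branches_hit), 3)
  pc <- pair_substitution_counts(map, 1, 2)
  expect_equal(unname(pc["single"]), nrow(map$events))
})

test_that("pair substitution counts follow their definitions", {
  aln <- rna_alignment(rep("ACGU", 3), sprintf("t%d", 1:3))
  tr <- build_tree(aln)
  map <- count_substitutions(fitch_sample(aln, tr, seed = 1))
  expect_equal(unname(pair_substitution_counts(map, 1, 2)), c(0, 0))

  aln2 <- random_alignment(10, 20, seed = 31)
  tr2 <- build_tree(aln2)
  map2 <- count_substitutions(fitch_sample(aln2, tr2, seed = 8))
  for (k in 1:10) {
    i <- sample(19, 1); j <- sample((i + 1):20, 1)
    pc <- pair_substitution_counts(map2, i, j)
    ev <- map2$events[map2$events$from > 0 & map2$events$to > 0, ]
    expect_equal(unname(pc["single"]),
                 sum(ev$col == i) + sum(ev$col == j))
    both <- intersect(ev$branch[ev$col == i], ev$branch[ev$col == j])
    expect_equal(unname(pc["double"]), length(both))
    # invariants
    expect_lte(pc["double"], min(length(unique(ev$branch[ev$col == i])),
                                 length(unique(ev$branch[ev$col == j]))))
    if (pc["double"] > 0) expect_gte(pc["single"], 2)
  }
})
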