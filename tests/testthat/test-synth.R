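test_that("zero divergence yields a constant alignment", {
  sim <- simulate_structural_alignment(8, 40, pairs = 5, divergence = 0,
                                       seed = 1)
  expect_equal(length(unique(as.character(sim$alignment))), 1L)
})

test_that("generators are reproducible and structure-free truth is empty", {
  s1 <- simulate_structural_alignment(10, 30, pairs = NULL,
                                      divergence = 0.5, seed = 12)
  s2 <- simulate_structural_alignment(10, 30, pairs = NULL,
                                      divergence = 0.5, seed = 12)
  expect_equal(s1$alignment$mat, s2$alignment$mat)
  expect_null(s1$pairs)
  expect_null(s1$alignment$structure)
})

test_that("true pairs are enriched in double substitutions", {
  sim <- simulate_structural_alignment(16, 60, pairs = 10, divergence = 1,
                                       tree = balanced_tree(16, 1), seed = 21)
  aln <- sim$alignment
  tr <- build_tree(aln)
  map <- count_substitutions(fitch_sample(aln, tr, seed = 22))
  true_dbl <- sapply(seq_len(10), function(k)
    pair_substitution_counts(map, sim$pairs$i[k], sim$pairs$j[k])["double"])
  unpaired <- setdiff(seq_len(60), c(sim$pairs$i, sim$pairs$j))
  set.seed(23)
  rand_dbl <- replicate(40, {
    ij <- sample(unpaired, 2)
    pair_substitution_counts(map, ij[1], ij[2])["double"]
  })
  expect_gt(mean(true_dbl), mean(rand_dbl))
})

test_that("gap-bias scenario produces the stated occupancy gradient", {
  sc <- make_gap_bias_scenario(20, 40, divergence = 0.4, seed = 31)
  occ <- column_profiles(sc$alignment)$occupancy
  expect_gt(mean(occ[21:40]), mean(occ[1:20]))
  flat <- simulate_structural_alignment(20, 40, pairs = NULL,
                                        divergence = 0.4, gap_prob = 0.1,
                                        seed = 32)
  occ2 <- column_profiles(flat$alignment)$occupancy
  expect_lt(abs(mean(occ2[21:40]) - mean(occ2[1:20])), 0.1)
})

test_that("conserved-column trap pairs have exactly zero MI", {
  trap <- make_conserved_column_trap(15, 40, n_pairs = 3, divergence = 0.6,
                                     seed = 41)
  smi <- score_matrix(trap$alignment, "mi")
  smg <- score_matrix(trap$alignment, "gtest")
  idx <- cbind(trap$pairs$i, trap$pairs$j)
  expect_equal(unname(smi$raw[idx]), rep(0, 3))
  expect_equal(unname(smg$raw[idx]), rep(0, 3))
  # one side is completely invariant by construction
  for (k in 1:3)
    expect_equal(length(unique(trap$alignment$mat[, trap$pairs$j[k]])), 1L)
})

test_that("pseudogene mixture labels dead copies and f = 0 is pure", {
  pure <- make_pseudogene_mixture(12, 40, pairs = 6, f = 0,
                                  divergence = 0.5, seed = 51)
  expect_length(pure$pseudogenes, 0L)
  mix <- make_pseudogene_mixture(12, 40, pairs = 6, f = 0.5,
                                 divergence = 0.5, seed = 52)
  expect_length(mix$pseudogenes, 6L)
  expect_true(all(mix$pseudogenes %in% mix$alignment$names))
})

test_that("misaligned helices lose conservation but keep interior pairing", {
  mh <- make_misaligned_helix(20, 60, helix_len = 6, divergence = 0.8,
                              shift_fraction = 0.4, seed = 61)
  helix_cols <- c(mh$pairs$i, mh$pairs$j)
  sub_id <- function(aln) {
    sub <- rna_alignment(apply(aln$mat[, helix_cols, drop = FALSE], 1,
                               function(r) paste(c("-", "A", "C", "G", "U")[r + 1],
                                                 collapse = "")),
                         aln$names)
    average_pairwise_identity(sub)
  }
  expect_lt(sub_id(mh$misaligned), sub_id(mh$corrected))
  # interior pairs remain overwhelmingly Watson-Crick/wobble in shifted
  # rows (the kernel's 5% pair-breaking proposals leave a few broken)
  wc <- rbind(c(1, 4), c(4, 1), c(2, 3), c(3, 2), c(3, 4), c(4, 3))
  ok <- apply(wc, 1, paste, collapse = ":")
  interior <- 2:5
  frac_wc <- mean(sapply(mh$shifted_rows, function(r)
    mean(sapply(interior, function(k)
      paste(mh$misaligned$mat[r, mh$pairs$i[k]],
            mh$misaligned$mat[r, mh$pairs$j[k]], sep = ":") %in% ok))))
  expect_gt(frac_wc, 0.8)
  # a zero-row shift changes nothing
  none <- make_misaligned_helix(10, 60, helix_len = 6, divergence = 0.8,
                                shift_fraction = 0, seed = 62)
  expect_equal(none$misaligned$mat, none$corrected$mat)
})

test_that("generated Stockholm files round-trip through the reader", {
  sim <- simulate_structural_alignment(8, 30, pairs = 4, divergence = 0.6,
                                       gap_prob = 0.1, seed = 71)
  path <- tempfile(fileext = ".sto")
  write_alignment(sim$alignment, path)
  back <- read_alignment(path)
  expect_equal(as.character(back), as.character(sim$alignment))
  expect_equal(back$structure$i, sim$alignment$structure$i)
  expect_equal(back$structure$j, sim$alignment$structure$j)
})
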