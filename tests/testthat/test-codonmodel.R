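test_that("genetic code facts", {
  cpa <- codons_per_aa()
  expect_equal(sum(cpa == 6L), 3L)
  expect_setequal(names(cpa)[cpa == 6L], c("L", "R", "S"))
  expect_equal(unname(cpa[c("M", "W")]), c(1L, 1L))
  expect_equal(nrow(genetic_code_table()), 61L)  # sense codons only
})

test_that("codon biases normalize per amino acid with zero off-target mass", {
  B <- codon_bias()
  expect_equal(unname(colSums(B)), rep(1, 20))
  tab <- genetic_code_table()
  for (a in c("S", "W", "C")) {
    off <- B[tab$aa != a, a]
    expect_true(all(off == 0))
  }
  # user-supplied counts
  counts <- data.frame(codon = c("UUA", "UUG"), count = c(3, 1))
  B2 <- codon_bias(counts)
  expect_equal(unname(B2[c("UUA", "UUG"), "L"]), c(0.75, 0.25))
  expect_equal(sum(B2[, "L"]), 1)
  expect_equal(unname(colSums(B2)), rep(1, 20))  # other aa fall back uniform
  expect_error(codon_bias(data.frame(codon = "UAA", count = 1)), "stop")
})

test_that("the amino-acid model is a normalized reversible chain", {
  m <- build_amino_model()
  expect_equal(unname(rowSums(m$R)), rep(0, 20), tolerance = 1e-10)
  expect_equal(sum(m$pi * -diag(m$R)), 1, tolerance = 1e-6)
  expect_equal(aa_transition(0, m), diag(20),
               ignore_attr = TRUE)
  P <- aa_transition(0.2, m)
  expect_equal(unname(rowSums(P)), rep(1, 20), tolerance = 1e-10)
  expect_true(all(P >= 0))
  expect_error(aa_transition(-1, m), "negative")
})

test_that("codon distributions reduce to biases at t = 0 and stay normalized", {
  cd0 <- codon_distribution("C", 0)
  expect_equal(unname(cd0$probs[c("UGU", "UGC")]), c(0.5, 0.5))
  expect_equal(sum(cd0$probs), 1)
  B <- codon_bias()
  for (a in c("S", "L", "W")) {
    expect_equal(codon_distribution(a, 0)$probs, B[, a],
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(sum(codon_distribution(a, 0.7)$probs), 1, tolerance = 1e-10)
  }
  expect_error(codon_distribution("S", -0.1), "negative")
})

test_that("pair marginals are consistent with the joint", {
  cd <- codon_distribution("R", 0.3)
  for (pair in c("c1c2", "c1c3", "c2c3")) {
    m <- codon_pair_marginal(cd, pair)
    expect_equal(sum(m), 1, tolerance = 1e-12)
  }
  # marginal over c1 from c1c2 equals marginal over c1 from c1c3
  expect_equal(rowSums(codon_pair_marginal(cd, "c1c2")),
               rowSums(codon_pair_marginal(cd, "c1c3")), tolerance = 1e-12)
  expect_error(codon_pair_marginal(cd, "c2c1"))
})

test_that("within-codon MI matches forced and brute-force values", {
  # single-codon amino acids: constant columns at t = 0
  expect_equal(within_codon_mi("W", 0, "c1c2"), 0)
  expect_equal(within_codon_mi("M", 0, "c1c3"), 0)
  # arginine c2 is fixed (always G): no c1-c2 covariation at t = 0
  expect_equal(within_codon_mi("R", 0, "c1c2"), 0)
  # serine at t = 0, uniform bias: 16-cell brute-force oracle
  cd <- codon_distribution("S", 0)
  for (pair in c("c1c2", "c1c3", "c2c3")) {
    expect_equal(within_codon_mi("S", 0, pair),
                 mi_bruteforce(codon_pair_marginal(cd, pair)),
                 tolerance = 1e-12)
  }
  # degenerate marginal gives exactly zero (proline c1 is always C)
  expect_equal(within_codon_mi("P", 0, "c1c3"), 0)
})

test_that("trajectories have the right shape and endpoints", {
  tj <- mi_trajectory("S", "c1c2", 0.4)
  expect_equal(nrow(tj), 1L)          # singleton grid
  tg <- c(0, 0.05, 0.25, 1)
  up <- mi_trajectory("W", "c2c3", tg)
  expect_equal(up$mi[1], 0)                    # starts at exactly 0
  expect_gt(up$mi[length(tg)], up$mi[2])       # rises with divergence
})

test_that("star exon simulation converges to the model distribution", {
  # t = 0 with a deterministic bias: all sequences identical
  counts <- data.frame(codon = c("UCU", "CGU", "CUU"), count = 1)
  bias <- codon_bias(counts)
  aln <- simulate_exon_alignment("SRL", 0, 8, bias = bias, seed = 5)
  expect_equal(length(unique(as.character(aln))), 1L)
  expect_equal(n_col(aln), 9L)

  # law of large numbers: empirical codon frequencies near the model
  cd <- codon_distribution("C", 0.2)
  aln2 <- simulate_exon_alignment("C", 0.2, 4000, seed = 6)
  cods <- apply(aln2$mat, 1, function(r)
    paste(c("-", "A", "C", "G", "U")[r + 1], collapse = ""))
  emp <- table(factor(cods, levels = names(cd$probs))) / length(cods)
  expect_lt(max(abs(as.numeric(emp) - cd$probs)), 0.03)
})
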