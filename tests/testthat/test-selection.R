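test_that("NG86 reproduces hand-enumerated and independently computed pairs", {
  # identical sequences: no divergence, undefined ratio
  r0 <- ng86("ATGGCC", "ATGGCC")
  expect_equal(r0$Ka, 0)
  expect_equal(r0$Ks, 0)
  expect_true(is.na(r0$omega))
  # TTT vs TTA: one nonsynonymous difference; averaged sites S = 0.5,
  # N = 2.5, so pN = 0.4 and Ka = -3/4 ln(1 - 1.6/3)
  r <- ng86("TTT", "TTA")
  expect_equal(r$S, 0.5, tolerance = 1e-12)
  expect_equal(r$N, 2.5, tolerance = 1e-12)
  expect_equal(r$pN, 0.4, tolerance = 1e-12)
  expect_equal(r$Ka, -0.75 * log(1 - 4 * 0.4 / 3), tolerance = 1e-12)
  expect_equal(r$Ks, 0)
  expect_true(is.na(r$omega))
  # frozen values computed with Biopython's NG86 implementation
  r2 <- ng86("ATGGCCTTTGGCAAA", "ATGGCGTTAGGTAAA")
  expect_equal(r2$Ka, 0.0870541284395655, tolerance = 1e-9)
  expect_equal(r2$Ks, 2.124910008042162, tolerance = 1e-9)
  # TAT/TAC: stop-adjacent third position still counts as 1/3 synonymous
  r3 <- ng86("TATGGGGGGGGG", "TACGGGGGGGGG")
  expect_equal(r3$Ks, 0.38311921782449304, tolerance = 1e-9)
  expect_equal(r3$Ka, 0)
})

test_that("NG86 is symmetric and flags saturation", {
  set.seed(21)
  tr <- ape::read.tree(text = "(A:0.3,B:0.3);")
  seqs <- evolve_sequences(tr, 120, model = "codon", omega = 0.3, kappa = 2)
  a <- ng86(seqs[["A"]], seqs[["B"]])
  b <- ng86(seqs[["B"]], seqs[["A"]])
  expect_equal(a$Ka, b$Ka, tolerance = 1e-12)
  expect_equal(a$Ks, b$Ks, tolerance = 1e-12)
  # saturated synonymous divergence is reported, not silently corrected
  rs <- ng86("TTTTTTTTT", "TTCTTCTTC")  # all-synonymous, pS = 3/3 sites
  expect_true(rs$saturated)
  expect_true(is.na(rs$Ks))
})

test_that("NG86 calls purifying selection on data generated under omega 0.1", {
  set.seed(77)
  tr <- ape::read.tree(text = "(A:0.4,B:0.4);")
  below1 <- 0L
  n_rep <- 20L
  for (i in seq_len(n_rep)) {
    seqs <- evolve_sequences(tr, 300, model = "codon", omega = 0.1,
                             kappa = 2)
    r <- ng86(seqs[["A"]], seqs[["B"]])
    if (!is.na(r$omega) && r$omega < 1) below1 <- below1 + 1L
  }
  expect_gte(below1 / n_rep, 0.95)
})

test_that("M0 log-likelihood matches an independent matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  set.seed(12)
  tr <- ape::read.tree(text = "(A:0.11,B:0.07);")
  seqs <- evolve_sequences(tr, 40, model = "codon", omega = 0.25, kappa = 3)
  aln <- codon_alignment(seqs)
  pi <- f3x4_frequencies(aln)
  for (par in list(c(2, 0.1), c(3.5, 0.6), c(1, 1))) {
    for (t_tot in c(0.05, 0.3)) {
      mine <- xenoscreen:::.m0_loglik(
        tr, xenoscreen:::.site_patterns(
          structure(aln$states, dimnames = list(aln$taxa, NULL))),
        pi, kappa = par[1], omega = par[2], bl = c(t_tot / 2, t_tot / 2))
      oracle <- m0_oracle_loglik_pair(seqs[["A"]], seqs[["B"]],
                                      kappa = par[1], omega = par[2],
                                      pi = pi, t_total = t_tot)
      expect_equal(mine, oracle, tolerance = 1e-6,
                   info = paste(par, collapse = "/"))
    }
  }
})

test_that("M0 fit degenerates correctly on identical sequences", {
  aln <- codon_alignment(c(A = "ATGGCCAAATTTGGCCTG", B = "ATGGCCAAATTTGGCCTG"))
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  fit <- m0_fit(aln, tr, n_starts = 1, control = list(maxit = 100))
  expect_lt(sum(fit$branch_lengths), 1e-3)
  # with no divergence the likelihood is the frequency-only likelihood
  pi <- f3x4_frequencies(aln)
  states <- aln$states[1, ]
  expect_equal(fit$lnL, sum(log(pi[states])), tolerance = 1e-4)
})

test_that("M0 likelihood is invariant to taxon order", {
  set.seed(14)
  tr <- ape::read.tree(text = "((A:0.2,B:0.2):0.1,(C:0.2,D:0.2):0.1);")
  seqs <- evolve_sequences(ape::unroot(tr), 60, model = "codon",
                           omega = 0.3, kappa = 2)
  f1 <- m0_fit(codon_alignment(seqs), ape::unroot(tr), n_starts = 1)
  f2 <- m0_fit(codon_alignment(seqs[c(3, 1, 4, 2)]), ape::unroot(tr),
               n_starts = 1)
  expect_equal(f1$lnL, f2$lnL, tolerance = 1e-4)
  expect_equal(f1$omega, f2$omega, tolerance = 1e-3)
})

test_that("the likelihood ratio test matches chi-square quantiles", {
  expect_equal(lrt(-100, -100, 1)$p_value, 1)
  expect_equal(lrt(-100, -100 + 3.841459 / 2, 1)$p_value, 0.05,
               tolerance = 1e-4)
  expect_equal(lrt(-100, -100 + 5.991465 / 2, 2)$p_value, 0.05,
               tolerance = 1e-4)
  expect_error(lrt(-90, -100, 1), "not nested|lower likelihood")
})
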