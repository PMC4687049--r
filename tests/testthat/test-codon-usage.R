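test_that("composition matches closed forms and flags undefined GC3s", {
  expect_equal(composition("GGCGGC")$GC, 1)
  expect_equal(composition("GGCGGC")$GC3s, 1)
  # Met and Trp only: GC3s has no eligible codon
  expect_true(is.na(composition("ATGTGG")$GC3s))
  expect_equal(composition("ATGTGG")$GC, 0.5)
  # agreement with an independent implementation on random genes
  skip_if_not_installed("seqinr")
  set.seed(4)
  for (i in 1:10) {
    cds <- random_cds(150, gc_bias = runif(1, 0.2, 0.8))
    expect_equal(composition(cds)$GC,
                 seqinr::GC(strsplit(tolower(cds), "")[[1]]),
                 tolerance = 1e-12)
  }
})

test_that("GC3s estimates the generating third-position GC level", {
  set.seed(11)
  cds <- random_cds(333, gc_bias = 0.7)
  got <- composition(cds)$GC3s
  # binomial sampling noise around 0.7 at ~333 draws
  expect_lt(abs(got - 0.7), 4 * sqrt(0.7 * 0.3 / 333))
})

test_that("CAI attains 1 on all-optimal genes and matches a two-codon hand case", {
  set.seed(2)
  degfam <- names(SYN_FAMILIES)[lengths(SYN_FAMILIES) > 1]
  aas <- sample(degfam, 1500, replace = TRUE)
  ref_cds <- paste(vapply(aas, function(a) sample(SYN_FAMILIES[[a]], 1), ""),
                   collapse = "")
  ref <- codon_usage_table(ref_cds)
  opt <- optimal_codons(ref)
  names(opt) <- GENETIC_CODE_1[opt]
  allopt <- paste(opt[aas[1:300]], collapse = "")
  expect_equal(cai(allopt, ref), 1)
  # two codons with w = 1 and w = 0.25 -> geometric mean 0.5
  ref2 <- codon_usage_table(paste(c(rep("GGC", 8), rep("GGA", 2)),
                                  collapse = ""))
  expect_equal(cai("GGCGGA", ref2), sqrt(1 * 0.25), tolerance = 1e-12)
  # pseudocount keeps unseen codons usable
  expect_gt(cai("GGGGGG", ref2), 0)
})

test_that("ENC hits its limits and matches the literal-formula oracle", {
  set.seed(3)
  degfam <- names(SYN_FAMILIES)[lengths(SYN_FAMILIES) > 1]
  aas <- sample(degfam, 3000, replace = TRUE)
  uniform <- paste(vapply(aas, function(a) sample(SYN_FAMILIES[[a]], 1), ""),
                   collapse = "")
  onecod <- paste(vapply(aas, function(a) sort(SYN_FAMILIES[[a]])[1], ""),
                  collapse = "")
  expect_gt(enc(uniform)$ENC, 59.5)  # approaches 61 in the uniform limit
  expect_equal(enc(onecod)$ENC, 20)
  # oracle equivalence on fuzzed coding sequences
  for (i in 1:30) {
    cds <- random_cds(sample(80:400, 1), gc_bias = runif(1, 0.15, 0.85))
    expect_equal(enc(cds)$ENC, enc_oracle(cds), tolerance = 1e-9, info = i)
  }
})

test_that("Fop and CBI behave at the optimal, uniform and avoided extremes", {
  set.seed(7)
  degfam <- names(SYN_FAMILIES)[lengths(SYN_FAMILIES) > 1]
  aas <- sample(degfam, 400, replace = TRUE)
  ref_cds <- paste(vapply(aas, function(a) sample(SYN_FAMILIES[[a]], 1), ""),
                   collapse = "")
  ref <- codon_usage_table(ref_cds)
  opt <- optimal_codons(ref)
  names(opt) <- GENETIC_CODE_1[opt]
  allopt <- paste(opt[aas], collapse = "")
  r <- cbi_fop(allopt, opt)
  expect_equal(r$Fop, 1)
  expect_equal(r$CBI, 1)
  # avoiding every optimal codon: Fop = 0 and CBI < 0
  nonopt <- paste(vapply(aas, function(a) {
    sort(setdiff(SYN_FAMILIES[[a]], opt))[1]
  }, ""), collapse = "")
  r0 <- cbi_fop(nonopt, opt)
  expect_equal(r0$Fop, 0)
  expect_lt(r0$CBI, 0)
  # two-fold family used evenly: Fop = 1/2, CBI = 0
  even <- paste(rep(c("TTT", "TTC"), 50), collapse = "")
  r_even <- cbi_fop(even, c(F = "TTC"))
  expect_equal(r_even$Fop, 0.5)
  expect_true(is.na(r_even$CBI) || abs(r_even$CBI) < 1e-12)
})

test_that("metric bounds hold and CAI/Fop are duplication-invariant", {
  set.seed(19)
  ref <- codon_usage_table(random_cds(2000, 0.6))
  opt <- optimal_codons(ref)
  for (i in 1:20) {
    cds <- random_cds(sample(60:200, 1), runif(1, 0.2, 0.8))
    m <- gene_metrics(cds, ref)
    expect_true(m[["GC"]] >= 0 && m[["GC"]] <= 1)
    expect_true(m[["GC3s"]] >= 0 && m[["GC3s"]] <= 1)
    expect_true(m[["CAI"]] > 0 && m[["CAI"]] <= 1)
    expect_true(m[["ENC"]] >= 20 && m[["ENC"]] <= 61)
    expect_true(m[["Fop"]] >= 0 && m[["Fop"]] <= 1)
    expect_true(m[["CBI"]] >= -1 && m[["CBI"]] <= 1)
    dup <- paste0(cds, cds)
    expect_equal(cai(dup, ref), cai(cds, ref), tolerance = 1e-12)
    expect_equal(cbi_fop(dup, opt)$Fop, cbi_fop(cds, opt)$Fop,
                 tolerance = 1e-12)
  }
})

test_that("background comparison separates ameliorated from unameliorated genes", {
  mk_bundle <- function(alpha) {
    simulate_hgt_dataset(sim_config(seed = 41, n_genes = 60, alpha = alpha))
  }
  for (case in list(list(alpha = 1, want = "HOST"),
                    list(alpha = 0, want = "DONOR"))) {
    b <- mk_bundle(case$alpha)
    ref <- codon_usage_table(b$host_background_cds)
    gene <- gene_metrics(b$cds_focal[[paste0("fish1_", b$hgt_gene)]], ref)
    host <- t(vapply(b$host_background_cds, gene_metrics, gene,
                     reference = ref))
    donor <- t(vapply(b$donor_background_cds, gene_metrics, gene,
                      reference = ref))
    rep <- compare_backgrounds(gene, host, donor)
    expect_identical(rep$call, case$want)
  }
  # a gene exactly at both background means is inconclusive
  g <- c(GC = 0.5, CAI = 0.5)
  mk_bg <- function(center, n = 60) {
    cbind(GC = center[1] + rep(c(-0.1, 0.1), n / 2),
          CAI = center[2] + rep(c(-0.1, 0.1), n / 2))
  }
  expect_identical(
    compare_backgrounds(g, mk_bg(c(0.5, 0.5)), mk_bg(c(0.5, 0.5)))$call,
    "INCONCLUSIVE")
})

test_that("amelioration sweep moves GC3s and host CAI monotonically", {
  alphas <- seq(0, 1, length.out = 9)
  gc3 <- cai_host <- numeric(length(alphas))
  for (i in seq_along(alphas)) {
    b <- simulate_hgt_dataset(sim_config(seed = 55, n_genes = 30,
                                         alpha = alphas[i]))
    ref <- codon_usage_table(b$host_background_cds)
    cds <- b$cds_focal[[paste0("fish1_", b$hgt_gene)]]
    gc3[i] <- composition(cds)$GC3s
    cai_host[i] <- cai(cds, ref)
  }
  expect_gt(cor(alphas, gc3, method = "spearman"), 0.9)
  expect_gt(cor(alphas, cai_host, method = "spearman"), 0.9)
})
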