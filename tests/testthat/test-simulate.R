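test_that("the bundle is fully determined by the seed", {
  b1 <- simulate_hgt_dataset(sim_config(seed = 5, n_genes = 25))
  b2 <- simulate_hgt_dataset(sim_config(seed = 5, n_genes = 25))
  expect_identical(b1$proteins, b2$proteins)
  expect_identical(b1$cds_focal, b2$cds_focal)
  expect_identical(b1$hits_animal, b2$hits_animal)
  expect_identical(b1$expression$counts, b2$expression$counts)
  b3 <- simulate_hgt_dataset(sim_config(seed = 6, n_genes = 25))
  expect_false(identical(b1$proteins, b3$proteins))
})

test_that("a zero-transfer configuration is a clean negative control", {
  b0 <- simulate_hgt_dataset(sim_config(seed = 9, n_genes = 25, n_hgt = 0))
  res <- screen_pipeline(b0$hits_animal, b0$hits_nonanimal,
                         b0$query_lengths, b0$index)
  expect_equal(nrow(res$candidates), 0L)
  expect_true(all(!b0$presence))
})

test_that("sequence evolution respects branch lengths and model constraints", {
  tr0 <- ape::read.tree(text = "(A:0,B:0,C:0);")
  s0 <- evolve_sequences(tr0, 50, model = "aa", seed = 2)
  expect_identical(unname(s0[["A"]]), unname(s0[["B"]]))
  expect_identical(unname(s0[["A"]]), unname(s0[["C"]]))
  # divergence grows with path length
  set.seed(33)
  bls <- seq(0.05, 1.5, length.out = 12)
  pdist <- vapply(bls, function(b) {
    tr <- ape::read.tree(text = sprintf("(A:%f,B:%f);", b / 2, b / 2))
    s <- evolve_sequences(tr, 400, model = "aa")
    mean(strsplit(s[["A"]], "")[[1]] != strsplit(s[["B"]], "")[[1]])
  }, numeric(1))
  expect_gt(cor(bls, pdist, method = "spearman"), 0.95)
  # omega 0 forbids amino-acid change
  trc <- ape::read.tree(text = "(A:0.5,B:0.5);")
  sc <- evolve_sequences(trc, 150, model = "codon", omega = 0, kappa = 2,
                         seed = 4)
  aa <- function(x) paste(translate_codon(
    substring(x, seq(1, nchar(x), 3), seq(3, nchar(x), 3))), collapse = "")
  expect_identical(aa(sc[["A"]]), aa(sc[["B"]]))
  expect_false(identical(sc[["A"]], sc[["B"]]))  # synonymous changes occur
})

test_that("surrogate hits are exact for identical pairs and silent for unrelated pairs", {
  h <- hit_table_from_sequences(c(q = "MKVLAAGGWT"), c(s = "MKVLAAGGWT"),
                                hit_floor = 1e2)
  expect_equal(h$pident, 100)
  expect_equal(h$evalue, 100 * 2^(-10))
  # E decreases as identity rises at fixed length
  set.seed(3)
  base <- paste(sample(c("A", "R", "N", "D", "C"), 100, TRUE), collapse = "")
  mut <- function(s, k) {
    x <- strsplit(s, "")[[1]]
    idx <- sample(100, k)
    x[idx] <- "G"
    paste(x, collapse = "")
  }
  e_vals <- vapply(c(5, 20, 40), function(k) {
    hit_table_from_sequences(setNames(base, "q"),
                             setNames(mut(base, k), "s"),
                             hit_floor = Inf)$evalue
  }, numeric(1))
  expect_true(all(diff(e_vals) > 0))
  # unrelated random pairs produce nothing above the floor
  set.seed(8)
  n_hits <- 0L
  for (i in 1:100) {
    a <- paste(sample(AA_ALPHABET, 120, TRUE), collapse = "")
    b <- paste(sample(AA_ALPHABET, 120, TRUE), collapse = "")
    n_hits <- n_hits + nrow(hit_table_from_sequences(setNames(a, "a"),
                                                     setNames(b, "b")))
  }
  expect_equal(n_hits, 0L)
})

test_that("simulated counts honour their means and zero stages", {
  means <- matrix(c(0, 50), 1000, 2, byrow = TRUE,
                  dimnames = list(sprintf("g%04d", 1:1000), c("off", "on")))
  cm <- simulate_counts(means, size = 10, seed = 3)
  expect_true(all(cm[, "off"] == 0))
  expect_lt(abs(mean(cm[, "on"]) - 50) / 50, 0.05)
  cm2 <- simulate_counts(means, size = 10, seed = 3)
  expect_identical(cm, cm2)
  expect_error(simulate_counts(means, size = -1), "size")
})

test_that("bundles written to disk round-trip through the standard readers", {
  b <- simulate_hgt_dataset(sim_config(seed = 12, n_genes = 15))
  dir <- tempfile("bundle")
  write_bundle(b, dir)
  hits <- read_hit_table(file.path(dir, "hits_animal.tsv"))
  expect_equal(nrow(hits), nrow(b$hits_animal))
  taxa <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  s2t <- read_seq2taxon(file.path(dir, "seq2taxon.tsv"))
  idx <- build_taxonomy_index(taxa, b$group_spec, s2t)
  res <- screen_pipeline(hits,
                         read_hit_table(file.path(dir, "hits_nonanimal.tsv")),
                         b$query_lengths, idx)
  expect_identical(res$candidates$query_id,
                   paste0(b$focal_species, "_", b$hgt_gene))
  aln <- read_alignment(file.path(dir, "hgt_family_alignment.faa"))
  expect_setequal(rownames(aln), names(b$hgt_alignment))
})
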