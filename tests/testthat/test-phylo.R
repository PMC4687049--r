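test_that("Poisson correction matches its closed form and caps saturation", {
  aln <- c(a = "AAAAAAAA", b = "AAAAAAAA")
  expect_equal(poisson_dist(aln)["a", "b"], 0)
  # p = 0.5 -> d = ln 2
  aln2 <- c(a = "AAAA", b = "AABB")
  expect_equal(poisson_dist(aln2)["a", "b"], log(2), tolerance = 1e-12)
  # saturated pair is capped and flagged
  aln3 <- c(a = "AAAA", b = "BBBB", c = "AABB")
  d3 <- poisson_dist(aln3)
  expect_equal(d3["a", "b"], -log(1 - 0.999))
  expect_true(attr(d3, "capped")["a", "b"])
  expect_false(attr(d3, "capped")["a", "c"])
})

test_that("Poisson distance is monotone in p below the cap and respects deletion mode", {
  p_vals <- seq(0.05, 0.95, by = 0.05)
  d_vals <- vapply(p_vals, function(p) {
    n <- 100
    a <- paste(rep("A", n), collapse = "")
    b <- paste(c(rep("B", round(p * n)), rep("A", n - round(p * n))),
               collapse = "")
    poisson_dist(c(x = a, y = b))["x", "y"]
  }, numeric(1))
  expect_true(all(diff(d_vals) > 0))
  # complete deletion drops the gapped column; pairwise keeps it per pair
  aln <- c(a = "A-AA", b = "ABAA", c = "ABBA")
  d_comp <- poisson_dist(aln, deletion = "complete")
  d_pair <- poisson_dist(aln, deletion = "pairwise")
  expect_equal(d_comp["b", "c"], -log(1 - 1 / 3), tolerance = 1e-12)
  expect_equal(d_pair["b", "c"], -log(1 - 1 / 4), tolerance = 1e-12)
})

test_that("NJ resolves the additive 4-taxon case and the 3-taxon closed form", {
  d <- matrix(c(0, 0.3, 1.1, 1.2,
                0.3, 0, 1.0, 1.1,
                1.1, 1.0, 0, 0.7,
                1.2, 1.1, 0.7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  expect_setequal(tree_bipartitions(tr), "C|D")  # the AB|CD split
  # exact 3-taxon solution
  d3 <- matrix(c(0, 0.4, 0.6, 0.4, 0, 0.8, 0.6, 0.8, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr3 <- nj_tree(d3)
  pl <- setNames(tr3$edge.length[match(1:3, tr3$edge[, 2])], tr3$tip.label)
  expect_equal(pl[["x"]], 0.1, tolerance = 1e-12)
  expect_equal(pl[["y"]], 0.3, tolerance = 1e-12)
  expect_equal(pl[["z"]], 0.5, tolerance = 1e-12)
  expect_error(nj_tree(d3[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers the generating topology from random additive matrices", {
  # additivity certificate: the NJ tree's patristic distances must
  # reproduce the input matrix exactly, which pins the unique topology
  n_cases <- 40
  ok <- 0L
  for (i in seq_len(n_cases)) {
    fx <- random_additive(n_taxa = sample(4:8, 1), seed = 1000 + i)
    tr <- nj_tree(fx$d)
    dd <- ape::cophenetic.phylo(tr)
    dd <- dd[rownames(fx$d), colnames(fx$d)]
    same_metric <- max(abs(dd - fx$d)) < 1e-8
    same_topo <- setequal(split_set(tr), split_set(fx$tree))
    if (same_metric && same_topo) ok <- ok + 1L
  }
  expect_equal(ok, n_cases)
})

test_that("NJ topology is invariant under taxon-order permutation", {
  fx <- random_additive(7, seed = 77)
  base <- split_set(nj_tree(fx$d))
  for (s in 1:5) {
    set.seed(s)
    p <- sample(nrow(fx$d))
    expect_setequal(split_set(nj_tree(fx$d[p, p])), base)
  }
})

test_that("majority-rule consensus counts clades like a hand tally", {
  t1 <- ape::read.tree(text = "((a,b),(c,d),e);")
  t2 <- ape::read.tree(text = "((a,b),(c,e),d);")
  t3 <- ape::read.tree(text = "((a,c),(b,d),e);")
  cm <- consensus_majority(list(t1, t2, t3))
  # the a+b | c,d,e split appears in 2 of 3 trees -> support 66.7, retained
  # (splits are keyed by the side not containing the reference tip "a")
  expect_equal(unname(cm$split_freq[["c|d|e"]]), 200 / 3, tolerance = 1e-9)
  labs <- suppressWarnings(as.numeric(cm$consensus$node.label))
  expect_true(any(abs(labs - 200 / 3) < 1e-6, na.rm = TRUE))
  # {c,d} appears once -> excluded from the consensus
  expect_false("c|d" %in% unlist(lapply(
    list(cm$consensus), tree_bipartitions, ref_order = sort(t1$tip.label))))
})

test_that("bootstrap supports are reproducible and strong splits reach 100", {
  set.seed(31)
  # two clearly separated pairs: a long internal branch
  m <- rbind(
    t1 = strsplit(paste(rep("ARNDCQEGHI", 6), collapse = ""), "")[[1]],
    t2 = strsplit(paste(rep("ARNDCQEGHI", 6), collapse = ""), "")[[1]],
    t3 = strsplit(paste(rep("LKMFPSTWYV", 6), collapse = ""), "")[[1]],
    t4 = strsplit(paste(rep("LKMFPSTWYV", 6), collapse = ""), "")[[1]])
  m["t2", 1:3] <- c("G", "G", "G")
  m["t4", 1:3] <- c("A", "A", "A")
  b1 <- bootstrap_consensus(m, n_reps = 100, seed = 5)
  b2 <- bootstrap_consensus(m, n_reps = 100, seed = 5)
  expect_identical(b1$split_freq, b2$split_freq)
  expect_equal(unname(b1$split_freq[["t3|t4"]]), 100)
  # support times n_reps equals an integer replicate count
  counts <- b1$split_freq * b1$n_reps / 100
  expect_true(all(abs(counts - round(counts)) < 1e-9))
})
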