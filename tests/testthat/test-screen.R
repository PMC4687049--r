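test_that("hit filtering applies the E-value ceiling and continuous-overlap floor", {
  # 120/300 = 40% coverage at E = 1e-12: passes the default thresholds
  h1 <- make_hit("q", "s1", 1e-12, qstart = 101, qend = 220)
  expect_equal(nrow(filter_hits(h1, 300)), 1L)
  # 90/300 = 30% coverage: below the 33% floor
  h2 <- make_hit("q", "s2", 1e-12, qstart = 101, qend = 190)
  expect_equal(nrow(filter_hits(h2, 300)), 0L)
  # E above the 1e-10 ceiling
  h3 <- make_hit("q", "s3", 1e-9, qstart = 1, qend = 300)
  expect_equal(nrow(filter_hits(h3, 300)), 0L)
  # self-hit removal and survivor order preservation
  h <- rbind(make_hit("q", "s1", 1e-50, qend = 300),
             make_hit("q", "q", 1e-200, qend = 300),
             make_hit("q", "s2", 1e-20, qend = 300))
  out <- filter_hits(h, 300)
  expect_identical(out$sseqid, c("s1", "s2"))
  # malformed coordinates
  expect_error(filter_hits(make_hit("q", "s", 1e-12, qend = 400), 300),
               "exceed query length")
})

test_that("filtering is monotone in its thresholds", {
  set.seed(9)
  hits <- do.call(rbind, lapply(1:40, function(i) {
    st <- sample(1:150, 1)
    make_hit("q", paste0("s", i), 10^runif(1, -30, 0),
             qstart = st, qend = st + sample(10:149, 1))
  }))
  hits <- hits[hits$qend <= 200, ]
  base <- nrow(filter_hits(hits, 200, e_max = 1e-10, min_overlap = 0.33))
  looser_e <- nrow(filter_hits(hits, 200, e_max = 1e-5, min_overlap = 0.33))
  looser_ov <- nrow(filter_hits(hits, 200, e_max = 1e-10, min_overlap = 0.1))
  expect_gte(looser_e, base)
  expect_gte(looser_ov, base)
  # boundary: min_overlap 0 keeps every E-passing non-self hit
  all_e <- nrow(filter_hits(hits, 200, e_max = 1e-10, min_overlap = 0))
  expect_equal(all_e, sum(hits$evalue <= 1e-10))
})

test_that("phyletic profiles count distinct taxa and keep best hits per group", {
  fx <- toy_taxonomy()
  s2t <- rbind(fx$seq2taxon,
               data.frame(seq_id = c("vibrio_p2", "q"),
                          taxon_id = c("t_vibrio", "t_zeb")))
  idx <- build_taxonomy_index(fx$taxa, fx$group_spec, s2t)
  hits <- rbind(make_hit("q", "vibrio_p1", 1e-30, qend = 100, bitscore = 120),
                make_hit("q", "vibrio_p2", 1e-20, qend = 100, bitscore = 90),
                make_hit("q", "ecoli_p1", 1e-15, qend = 100))
  p <- phyletic_profile("q", hits, idx)
  # two hits to the same donor taxon count once
  expect_equal(unname(p$counts["DONOR_CANDIDATE"]), 1L)
  expect_equal(unname(p$counts["BACTERIA"]), 1L)
  expect_equal(unname(p$counts["NON_FISH_ANIMAL"]), 0L)
  expect_identical(p$best_hit$DONOR_CANDIDATE$sseqid, "vibrio_p1")
  # empty hit set gives the all-zero profile
  p0 <- phyletic_profile("q", hits[0, ], idx)
  expect_true(all(p0$counts == 0L))
})

test_that("candidate selection demands fish-restriction plus donor evidence", {
  fx <- toy_taxonomy()
  s2t <- rbind(fx$seq2taxon,
               data.frame(seq_id = c("qA", "qB", "qC", "zeb_p2"),
                          taxon_id = c("t_zeb", "t_zeb", "t_zeb", "t_zeb")))
  idx <- build_taxonomy_index(fx$taxa, fx$group_spec, s2t)
  pa <- list(
    qA = phyletic_profile("qA", make_hit("qA", "zeb_p2", 1e-40, qend = 100), idx),
    qB = phyletic_profile("qB", rbind(
      make_hit("qB", "zeb_p2", 1e-40, qend = 100),
      make_hit("qB", "mouse_p1", 1e-30, qend = 100)), idx),
    qC = phyletic_profile("qC", make_hit("qC", "zeb_p2", 1e-40, qend = 100), idx))
  pn <- list(
    qA = phyletic_profile("qA", make_hit("qA", "vibrio_p1", 1e-25, qend = 100), idx),
    qB = phyletic_profile("qB", make_hit("qB", "vibrio_p1", 1e-25, qend = 100), idx),
    qC = phyletic_profile("qC", make_hit("qC", "vibrio_p1", 0, qend = 100)[0, ], idx))
  out <- select_candidates(pa, pn)
  # qB excluded (mammal homolog); qC excluded (no donor evidence)
  expect_identical(out$query_id, "qA")
  expect_identical(out$donor_group, "DONOR_CANDIDATE")
})

test_that("the screening cascade recovers the planted transfer and only it", {
  b <- simulate_hgt_dataset(sim_config(seed = 17))
  res <- screen_pipeline(b$hits_animal, b$hits_nonanimal, b$query_lengths,
                         b$index)
  planted <- paste0(b$focal_species, "_", b$hgt_gene)
  expect_identical(res$candidates$query_id, planted)
  expect_identical(res$candidates$donor_group, "DONOR_CANDIDATE")
  # funnel counts decrease along the cascade
  expect_true(all(diff(res$funnel) <= 0))
  # determinism: identical rerun
  res2 <- screen_pipeline(b$hits_animal, b$hits_nonanimal, b$query_lengths,
                          b$index)
  expect_identical(res$candidates, res2$candidates)
  expect_identical(res$funnel, res2$funnel)
})

test_that("hit tables round-trip through the 12-column format", {
  b <- simulate_hgt_dataset(sim_config(seed = 2, n_genes = 15))
  f <- tempfile(fileext = ".tsv")
  write_hit_table(b$hits_animal, f)
  back <- read_hit_table(f)
  expect_equal(nrow(back), nrow(b$hits_animal))
  expect_equal(back$evalue, b$hits_animal$evalue, tolerance = 1e-12)
  expect_identical(back$sseqid, b$hits_animal$sseqid)
})
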