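# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately written as literal, brute-force implementations
# independent of the package's code paths.

# --- toy taxonomy -----------------------------------------------------------

toy_taxonomy <- function() {
  taxa <- data.frame(
    taxon_id = c("r", "bac", "marine", "met", "fish", "mam",
                 "t_ecoli", "t_vibrio", "t_zeb", "t_mouse"),
    parent_id = c("r", "r", "bac", "r", "met", "met",
                  "bac", "marine", "fish", "mam"),
    name = c("root", "Bacteria", "Marine", "Metazoa", "Fish", "Mammal",
             "ecoli", "vibrio", "zebrafish", "mouse"),
    stringsAsFactors = FALSE)
  seq2taxon <- data.frame(
    seq_id = c("zeb_p1", "mouse_p1", "ecoli_p1", "vibrio_p1"),
    taxon_id = c("t_zeb", "t_mouse", "t_ecoli", "t_vibrio"),
    stringsAsFactors = FALSE)
  group_spec <- c(bac = "BACTERIA", marine = "DONOR_CANDIDATE",
                  fish = "FISH_CORE", met = "NON_FISH_ANIMAL")
  list(taxa = taxa, seq2taxon = seq2taxon, group_spec = group_spec)
}

make_hit <- function(q, s, e, qstart = 1, qend = 100, pident = 50,
                     bitscore = 100, len = qend - qstart + 1) {
  data.frame(qseqid = q, sseqid = s, pident = pident, length = len,
             mismatch = 0, gapopen = 0, qstart = qstart, qend = qend,
             sstart = 1, send = len, evalue = e, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

# --- random additive distance matrices --------------------------------------

# random unrooted binary topology with positive branch lengths; returns the
# tree and its (exactly additive) patristic distance matrix
random_additive <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) runif(n, 0.1, 1))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  d <- ape::cophenetic.phylo(tr)
  d <- d[order(rownames(d)), order(colnames(d))]
  list(tree = tr, d = d)
}

split_set <- function(tree) {
  sort(xenoscreen::tree_bipartitions(tree, sort(tree$tip.label)))
}

# --- literal ENC oracle -----------------------------------------------------

# Wright's statistic written out with hard-coded family lists, no shared
# code with the package implementation
enc_oracle <- function(cds) {
  fams <- list(
    c("TTT", "TTC"), c("TAT", "TAC"), c("TGT", "TGC"), c("CAT", "CAC"),
    c("CAA", "CAG"), c("AAT", "AAC"), c("AAA", "AAG"), c("GAT", "GAC"),
    c("GAA", "GAG"),
    c("ATT", "ATC", "ATA"),
    c("GTT", "GTC", "GTA", "GTG"), c("CCT", "CCC", "CCA", "CCG"),
    c("ACT", "ACC", "ACA", "ACG"), c("GCT", "GCC", "GCA", "GCG"),
    c("GGT", "GGC", "GGA", "GGG"),
    c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
    c("TCT", "TCC", "TCA", "TCG", "AGT", "AGC"),
    c("CGT", "CGC", "CGA", "CGG", "AGA", "AGG"))
  ks <- vapply(fams, length, integer(1))
  s <- toupper(cds)
  codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  codons <- codons[!codons %in% c("TAA", "TAG", "TGA")]
  Fk <- list(`2` = c(), `3` = c(), `4` = c(), `6` = c())
  for (i in seq_along(fams)) {
    ni <- vapply(fams[[i]], function(co) sum(codons == co), numeric(1))
    n <- sum(ni)
    if (n < 2) next
    p <- ni / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    Fk[[as.character(ks[i])]] <- c(Fk[[as.character(ks[i])]], f)
  }
  Fbar <- vapply(Fk, function(v) if (length(v)) mean(v) else NA_real_,
                 numeric(1))
  if (is.na(Fbar[["3"]]) && !is.na(Fbar[["2"]]) && !is.na(Fbar[["4"]])) {
    Fbar[["3"]] <- (Fbar[["2"]] + Fbar[["4"]]) / 2
  }
  kk <- c(2, 3, 4, 6)
  obs <- !is.na(Fbar)
  if (any(!obs)) {
    sp <- mean((1 / Fbar[obs] - 1) / (kk[obs] - 1))
    Fbar[!obs] <- 1 / (1 + sp * (kk[!obs] - 1))
  }
  Fbar <- pmax(Fbar, 1e-6)
  val <- 2 + 9 / Fbar[["2"]] + 1 / Fbar[["3"]] + 5 / Fbar[["4"]] +
    3 / Fbar[["6"]]
  min(max(val, 20), 61)
}

# random valid CDS (no stops), biased usage
random_cds <- function(n_codons, gc_bias = 0.5) {
  sense <- names(xenoscreen::GENETIC_CODE_1)[
    xenoscreen::GENETIC_CODE_1 != "*"]
  gc3 <- substring(sense, 3, 3) %in% c("G", "C")
  w <- ifelse(gc3, gc_bias, 1 - gc_bias)
  paste(sample(sense, n_codons, replace = TRUE, prob = w / sum(w)),
        collapse = "")
}

# --- brute-force Dollo oracle ------------------------------------------------

# minimal number of present->absent transition edges over all internal-state
# assignments with the root present and no absent->present edge
brute_dollo_losses <- function(tree, presence) {
  n <- length(tree$tip.label)
  nn <- tree$Nnode
  tip_state <- as.integer(tree$tip.label %in% presence)
  best <- Inf
  for (mask in 0:(2^nn - 1)) {
    int_state <- as.integer(intToBits(mask))[seq_len(nn)]
    if (int_state[1] != 1L) next  # root (node n+1) must carry the gene
    state <- c(tip_state, int_state)
    ok <- TRUE; losses <- 0L
    for (k in seq_len(nrow(tree$edge))) {
      a <- state[tree$edge[k, 1]]; b <- state[tree$edge[k, 2]]
      if (a == 0L && b == 1L) { ok <- FALSE; break }
      if (a == 1L && b == 0L) losses <- losses + 1L
    }
    if (ok) best <- min(best, losses)
  }
  best
}

# --- independent M0 likelihood oracle (2 taxa) -------------------------------

# literal Goldman-Yang rate matrix + matrix exponential + direct summation;
# shares no code with the package implementation
m0_oracle_loglik_pair <- function(s1, s2, kappa, omega, pi, t_total) {
  code <- c(
    TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
    CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
    GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
    TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
    ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
    GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", CAT = "H", CAC = "H",
    CAA = "Q", CAG = "Q", AAT = "N", AAC = "N", AAA = "K", AAG = "K",
    GAT = "D", GAC = "D", GAA = "E", GAG = "E", TGT = "C", TGC = "C",
    TGG = "W", CGT = "R", CGC = "R", CGA = "R", CGG = "R", AGT = "S",
    AGC = "S", AGA = "R", AGG = "R", GGT = "G", GGC = "G", GGA = "G",
    GGG = "G")
  sense <- names(code)
  stopifnot(length(pi) == 61, !is.null(names(pi)))
  pi <- stats::setNames(as.numeric(pi[sense]), sense)
  Q <- matrix(0, 61, 61, dimnames = list(sense, sense))
  for (i in sense) for (j in sense) {
    if (i == j) next
    ci <- strsplit(i, "")[[1]]; cj <- strsplit(j, "")[[1]]
    diff <- which(ci != cj)
    if (length(diff) != 1) next
    ts <- all(c(ci[diff], cj[diff]) %in% c("A", "G")) ||
      all(c(ci[diff], cj[diff]) %in% c("C", "T"))
    r <- pi[[j]]
    if (ts) r <- r * kappa
    if (code[[i]] != code[[j]]) r <- r * omega
    Q[i, j] <- r
  }
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(pi * diag(Q)))
  P <- as.matrix(Matrix::expm(Q * t_total))
  cod <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  c1 <- cod(s1); c2 <- cod(s2)
  sum(log(pi[c1] * P[cbind(c1, c2)]))
}
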