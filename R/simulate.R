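# Seeded synthetic-data generator. Emits a complete, truth-labelled dataset
# with the statistical structure the analysis assumes: a clade structure
# (bacteria including a marine donor group, fungi, another non-animal
# eukaryote, invertebrates, basal fishes lacking the planted gene, core
# fishes, tetrapods), one planted donor->fish transfer, partial
# amelioration of the transferred gene's codon usage toward the host,
# intron-bearing recipient gene models flanked by native genes, an
# intronless contaminant contig, and stage-wise expression counts.

#' The 20 amino acids used by the sequence simulator
#' @format character vector of one-letter codes
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default simulation configuration
#'
#' @param seed RNG seed driving every random choice in the bundle
#' @param n_genes total gene families in the focal proteome (default 200,
#'   including the planted transfer)
#' @param n_hgt 0 or 1 planted transfers (default 1)
#' @param alpha amelioration mixing weight in `[0, 1]`: 0 = transferred
#'   gene keeps donor codon usage, 1 = fully host-like (default 0.5)
#' @param contamination include an intronless bacterial contaminant contig
#'   (default TRUE)
#' @param aa_len_range protein length range (residues)
#' @param theta_host,theta_donor GC3 odds weights of the host and donor
#'   codon-sampling profiles (host GC3-rich, donor AT3-rich)
#' @param n_donor_background donor-genome background CDS count for the
#'   amelioration comparison (default 60)
#' @param nb_size negative-binomial size (inverse overdispersion) for
#'   expression counts
#' @return list of configuration values
#' @export
sim_config <- function(seed = 1L, n_genes = 200L, n_hgt = 1L, alpha = 0.5,
                       contamination = TRUE, aa_len_range = c(120L, 300L),
                       theta_host = 2.5, theta_donor = 0.35,
                       n_donor_background = 60L, nb_size = 10) {
  stopifnot(alpha >= 0, alpha <= 1, n_hgt %in% c(0L, 1L), n_genes >= 10L)
  list(seed = seed, n_genes = as.integer(n_genes), n_hgt = as.integer(n_hgt),
       alpha = alpha, contamination = isTRUE(contamination),
       aa_len_range = aa_len_range, theta_host = theta_host,
       theta_donor = theta_donor,
       n_donor_background = as.integer(n_donor_background),
       nb_size = nb_size,
       stages = c("sperm", "oocyte", "cell1", "cell4", "cell16", "cell64",
                  "cell128", "cell256", "cell1k", "sphere"),
       hgt_stage_means = c(sperm = 40, oocyte = 0, cell1 = 0, cell4 = 2,
                           cell16 = 4, cell64 = 8, cell128 = 12,
                           cell256 = 20, cell1k = 30, sphere = 25))
}

# species grouped by clade; fish1 is the focal (query) species
SIM_SPECIES <- list(
  DONOR_CANDIDATE = c("marbac1", "marbac2", "marbac3"),
  BACTERIA = c("bac1", "bac2"),
  FUNGI = c("fung1", "fung2"),
  OTHER_NON_ANIMAL = c("alga1"),
  NON_FISH_ANIMAL = c("invert1", "invert2", "tetra1", "tetra2"),
  FISH_BASAL = c("basalfish1", "basalfish2"),
  FISH_CORE = c("fish1", "fish2", "fish3", "fish4", "fish5")
)

# species phylogeny in amino-acid substitutions per site
SIM_SPECIES_TREE <- paste0(
  "((((marbac1:0.03,marbac2:0.03):0.03,marbac3:0.05):0.15,",
  "(bac1:0.1,bac2:0.1):0.1):0.5,",
  "((fung1:0.1,fung2:0.1):0.25,alga1:0.35,",
  "(((invert1:0.12,invert2:0.12):0.1,",
  "(((basalfish1:0.05,basalfish2:0.05):0.08,",
  "(fish1:0.04,(fish2:0.03,(fish3:0.025,(fish4:0.02,fish5:0.02):0.01)",
  ":0.01):0.01):0.06):0.05,",
  "(tetra1:0.06,tetra2:0.06):0.1):0.08):0.1):0.12):0.3);"
)

# transferred-gene phylogeny: the fish copies nest inside the marine
# (donor) bacteria, sister to marbac1+marbac2, on a short post-transfer stem
SIM_HGT_TREE <- paste0(
  "((((marbac1:0.03,marbac2:0.03):0.03,",
  "(fish1:0.04,(fish2:0.03,(fish3:0.025,(fish4:0.02,fish5:0.02):0.01)",
  ":0.01):0.01):0.1):0.02,marbac3:0.06):0.15,",
  "(bac1:0.25,bac2:0.25):0.1,(fung1:0.35,fung2:0.35):0.1);"
)

#' Synthetic taxonomy tables for the simulated clades
#'
#' @return list with `taxa` (taxon_id, parent_id, name), `group_spec`
#'   (clade root -> group label) and `species_taxon` (species -> taxon_id)
#' @export
sim_taxonomy <- function() {
  taxa <- data.frame(
    taxon_id = c("1", "2", "3", "4", "5", "6", "7", "8", "9", "10",
                 "11", "12", "13"),
    parent_id = c("1", "1", "2", "1", "4", "4", "4", "7", "7", "9",
                  "9", "11", "11"),
    name = c("root", "Bacteria", "MarineBacteria", "Eukaryota", "Fungi",
             "OtherEukaryota", "Metazoa", "Invertebrata", "Vertebrata",
             "Tetrapoda", "Fishes", "BasalFishes", "CoreFishes"),
    stringsAsFactors = FALSE)
  parent_of_group <- c(DONOR_CANDIDATE = "3", BACTERIA = "2", FUNGI = "5",
                       OTHER_NON_ANIMAL = "6", FISH_BASAL = "12",
                       FISH_CORE = "13")
  sp <- unlist(SIM_SPECIES, use.names = FALSE)
  grp <- rep(names(SIM_SPECIES), lengths(SIM_SPECIES))
  # invertebrates vs tetrapods sit under different internal clades
  par <- ifelse(grp == "NON_FISH_ANIMAL",
                ifelse(grepl("^invert", sp), "8", "10"),
                parent_of_group[grp])
  sp_tax <- stats::setNames(paste0("t_", sp), sp)
  taxa <- rbind(taxa, data.frame(taxon_id = unname(sp_tax), parent_id = par,
                                 name = sp, stringsAsFactors = FALSE))
  group_spec <- c("2" = "BACTERIA", "3" = "DONOR_CANDIDATE", "5" = "FUNGI",
                  "4" = "OTHER_NON_ANIMAL", "7" = "NON_FISH_ANIMAL",
                  "12" = "FISH_BASAL", "13" = "FISH_CORE")
  list(taxa = taxa, group_spec = group_spec, species_taxon = sp_tax)
}

#' Evolve sequences along a tree
#'
#' Independent-site Markov substitution from a root sequence drawn from the
#' model's equilibrium frequencies. Amino-acid mode uses a 20-state
#' equal-exchangeability (Jukes-Cantor-like) model; codon mode uses the
#' one-ratio codon model with the supplied omega and kappa (61 sense
#' codons, uniform codon frequencies unless `pi` is given).
#'
#' @param tree `phylo` with branch lengths (expected substitutions per
#'   site, or per codon in codon mode)
#' @param n_sites sequence length (residues or codons)
#' @param model `"aa"` or `"codon"`
#' @param omega,kappa codon-model parameters (codon mode only)
#' @param pi optional codon equilibrium frequencies (length 61)
#' @param seed optional RNG seed
#' @param root optional root sequence (character string) overriding the
#'   equilibrium draw
#' @return named character vector of tip sequences
#' @export
evolve_sequences <- function(tree, n_sites, model = c("aa", "codon"),
                             omega = 0.2, kappa = 2, pi = NULL, seed = NULL,
                             root = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (any(tree$edge.length < 0)) stop("negative branch lengths")
  n <- length(tree$tip.label)
  seqs <- vector("list", n + tree$Nnode)

  if (model == "aa") {
    nstate <- 20L
    draw_root <- function() sample.int(nstate, n_sites, replace = TRUE)
    transition <- function(parent_states, b) {
      p_change <- (nstate - 1) / nstate * (1 - exp(-nstate / (nstate - 1) * b))
      change <- stats::runif(n_sites) < p_change
      out <- parent_states
      if (any(change)) {
        # uniform over the 19 other states
        shift <- sample.int(nstate - 1L, sum(change), replace = TRUE)
        out[change] <- ((parent_states[change] - 1L + shift) %% nstate) + 1L
      }
      out
    }
    to_string <- function(states) paste(AA_ALPHABET[states], collapse = "")
    from_string <- function(s) match(strsplit(s, "")[[1]], AA_ALPHABET)
  } else {
    if (omega < 0 || kappa <= 0) stop("invalid omega/kappa")
    if (is.null(pi)) pi <- rep(1 / 61, 61)
    names(pi) <- SENSE_CODONS
    Q <- m0_rate_matrix(kappa, max(omega, 1e-12), pi)
    if (omega == 0) {
      # forbid nonsynonymous changes outright
      cp <- codon_pairs()
      Q[cbind(cp$from, cp$to)[!cp$synonymous, , drop = FALSE]] <- 0
      diag(Q) <- 0; diag(Q) <- -rowSums(Q)
    }
    Pfun <- .m0_propagator(Q, pi)
    draw_root <- function() sample.int(61L, n_sites, replace = TRUE, prob = pi)
    transition <- function(parent_states, b) {
      P <- Pfun(b)
      out <- integer(n_sites)
      for (s in unique(parent_states)) {
        idx <- which(parent_states == s)
        p <- pmax(P[s, ], 0)
        out[idx] <- sample.int(61L, length(idx), replace = TRUE, prob = p)
      }
      out
    }
    to_string <- function(states) paste(SENSE_CODONS[states], collapse = "")
    from_string <- function(s) {
      match(substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)),
            SENSE_CODONS)
    }
  }

  root_node <- n + 1L
  seqs[[root_node]] <- if (is.null(root)) draw_root() else from_string(root)
  if (length(seqs[[root_node]]) != n_sites || anyNA(seqs[[root_node]])) {
    stop("root sequence inconsistent with model/length")
  }
  # cladewise edge order guarantees parents are simulated before children
  po <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(po$edge))) {
    seqs[[po$edge[k, 2]]] <- transition(seqs[[po$edge[k, 1]]],
                                        po$edge.length[k])
  }
  out <- vapply(seq_len(n), function(i) to_string(seqs[[i]]), character(1))
  names(out) <- tree$tip.label
  out
}

# codon sampling profile: per amino acid, probability over its codons with
# GC3-ending codons weighted by theta
.codon_profile <- function(theta) {
  prof <- list()
  for (aa in names(SYN_FAMILIES)) {
    fam <- SYN_FAMILIES[[aa]]
    w <- ifelse(substring(fam, 3, 3) %in% c("G", "C"), theta, 1)
    prof[[aa]] <- stats::setNames(w / sum(w), fam)
  }
  prof
}

# back-translate a protein using a codon profile (or a mixture of two)
.sample_cds <- function(protein, prof_a, prof_b = NULL, alpha = 1) {
  aas <- strsplit(protein, "")[[1]]
  codons <- vapply(aas, function(a) {
    pa <- prof_a[[a]]
    p <- if (is.null(prof_b)) pa else alpha * pa + (1 - alpha) * prof_b[[a]]
    sample(names(p), 1L, prob = p)
  }, character(1))
  paste(codons, collapse = "")
}

#' Deterministic surrogate homology hits between simulated sequences
#'
#' Simulated family members are alignable by construction (equal length, no
#' indels), so identity is the fraction of matching positions. A hit is
#' emitted when the pair shares at least one exact k-mer (the seed anchor)
#' and the E-value surrogate E = len_q * len_s * 2^(-S), with score
#' S = bits_per_identity * (number of identical residues), is at or below
#' `hit_floor`. E is monotone decreasing in identity at fixed length by
#' construction. Pairs of unequal length produce no hit.
#'
#' @param queries named character vector of query sequences
#' @param subjects named character vector of subject sequences
#' @param k anchor k-mer size (default 4)
#' @param bits_per_identity score per identical residue (default 1)
#' @param hit_floor report hits with E at or below this value (default 1e-3)
#' @return data.frame in 12-column hit-table layout
#' @export
hit_table_from_sequences <- function(queries, subjects, k = 4L,
                                     bits_per_identity = 1,
                                     hit_floor = 1e-3) {
  stopifnot(length(queries) > 0, length(subjects) > 0)
  if (is.null(names(queries)) || is.null(names(subjects))) {
    stop("queries and subjects must be named")
  }
  qs <- strsplit(queries, "")
  ss <- strsplit(subjects, "")
  kmers <- function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    unique(substring(s, 1:(n - k + 1L), k:n))
  }
  qk <- lapply(queries, kmers)
  sk <- lapply(subjects, kmers)
  # only equal-length pairs can align in this indel-free generator
  subj_by_len <- split(seq_along(subjects), nchar(subjects))

  qid <- sid <- character(0)
  nid_v <- len_v <- integer(0)
  for (qi in seq_along(queries)) {
    lq <- length(qs[[qi]])
    cand <- subj_by_len[[as.character(lq)]]
    if (is.null(cand)) next
    for (si in cand) {
      if (!any(qk[[qi]] %in% sk[[si]])) next
      nid <- sum(qs[[qi]] == ss[[si]])
      if (lq * lq * 2^(-bits_per_identity * nid) > hit_floor) next
      qid <- c(qid, names(queries)[qi])
      sid <- c(sid, names(subjects)[si])
      nid_v <- c(nid_v, nid)
      len_v <- c(len_v, lq)
    }
  }
  S <- bits_per_identity * nid_v
  data.frame(qseqid = qid, sseqid = sid,
             pident = round(100 * nid_v / pmax(len_v, 1L), 2),
             length = len_v, mismatch = len_v - nid_v,
             gapopen = rep(0L, length(qid)),
             qstart = rep(1L, length(qid)), qend = len_v,
             sstart = rep(1L, length(qid)), send = len_v,
             evalue = as.numeric(len_v) * len_v * 2^(-S), bitscore = S,
             stringsAsFactors = FALSE)
}

#' Simulate stage-wise expression counts
#'
#' Negative-binomial counts per gene and stage around configured means.
#'
#' @param means numeric matrix genes x stages of expected counts (zero
#'   means give structurally zero counts)
#' @param size negative-binomial size parameter (> 0)
#' @param seed optional RNG seed
#' @return integer matrix of counts with the dimnames of `means`
#' @export
simulate_counts <- function(means, size = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(means < 0)) stop("negative means")
  if (size <= 0) stop("negative-binomial size must be positive")
  counts <- means
  pos <- means > 0
  counts[pos] <- stats::rnbinom(sum(pos), mu = means[pos], size = size)
  counts[!pos] <- 0
  storage.mode(counts) <- "integer"
  counts
}

#' Simulate a complete truth-labelled dataset bundle
#'
#' Generates gene families on the simulated species phylogeny, plants one
#' donor-to-fish transfer (nested inside the marine bacteria, partially
#' ameliorated codon usage), builds proteomes, coding sequences, gene
#' models (transferred gene intron-bearing and flanked by native genes; an
#' optional intronless contaminant contig), surrogate hit tables against
#' the animal and non-animal databases, taxonomy tables, per-genome
#' presence of the transferred gene, and a stage-wise expression count
#' table. Everything derives from `config$seed`.
#'
#' @param config list from [sim_config()]
#' @return a bundle list; see Details in the package vignette. Key
#'   elements: `proteins` (per species), `cds_focal`, `hits_animal`,
#'   `hits_nonanimal`, `query_lengths`, `index`, `taxonomy`, `seq2taxon`,
#'   `gene_models`, `presence`, `expression` (counts/lengths/totals),
#'   `hgt_alignment`, `host_background_cds`, `donor_background_cds`,
#'   `truth` (gene_id, class), `config`
#' @export
simulate_hgt_dataset <- function(config = sim_config()) {
  set.seed(config$seed)
  tax <- sim_taxonomy()
  sp_tree <- ape::read.tree(text = SIM_SPECIES_TREE)
  hgt_tree <- ape::read.tree(text = SIM_HGT_TREE)
  all_species <- unlist(SIM_SPECIES, use.names = FALSE)
  animal_species <- c(SIM_SPECIES$FISH_CORE, SIM_SPECIES$FISH_BASAL,
                      SIM_SPECIES$NON_FISH_ANIMAL)
  nonanimal_species <- setdiff(all_species, animal_species)
  focal <- "fish1"

  n_genes <- config$n_genes
  n_bg <- n_genes - config$n_hgt
  # background family presence classes
  bg_class <- sample(c("broad", "animal_only", "fish_only"), n_bg,
                     replace = TRUE, prob = c(0.55, 0.25, 0.20))
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  hgt_gene <- if (config$n_hgt == 1L) gene_ids[1] else NA_character_
  classes <- c(if (config$n_hgt == 1L) "HGT", rep("VERTICAL", n_bg))
  names(classes) <- gene_ids
  fam_class <- c(if (config$n_hgt == 1L) "hgt", bg_class)

  lens <- sample(seq(config$aa_len_range[1], config$aa_len_range[2]),
                 n_genes, replace = TRUE)

  prof_host <- .codon_profile(config$theta_host)
  prof_donor <- .codon_profile(config$theta_donor)

  proteins <- stats::setNames(
    lapply(all_species, function(s) character(0)), all_species)
  cds_focal <- character(0)
  host_bg_cds <- character(0)
  hgt_alignment <- NULL
  hgt_cds_by_fish <- character(0)

  for (gi in seq_len(n_genes)) {
    gid <- gene_ids[gi]
    cls <- fam_class[gi]
    members <- switch(cls,
      hgt = c(SIM_SPECIES$FISH_CORE, SIM_SPECIES$DONOR_CANDIDATE,
              SIM_SPECIES$BACTERIA, SIM_SPECIES$FUNGI),
      broad = c(animal_species, sample(nonanimal_species,
                                       sample(2:4, 1))),
      animal_only = animal_species,
      fish_only = c(SIM_SPECIES$FISH_CORE,
                    if (stats::runif(1) < 0.5) SIM_SPECIES$FISH_BASAL))
    gtree <- if (cls == "hgt") hgt_tree else
      ape::keep.tip(sp_tree, intersect(sp_tree$tip.label, members))
    tips <- evolve_sequences(gtree, lens[gi], model = "aa")
    for (s in names(tips)) {
      nm <- paste0(s, "_", gid)
      proteins[[s]][nm] <- tips[[s]]
    }
    if (cls == "hgt") {
      hgt_alignment <- tips  # equal-length, alignable by construction
      for (s in SIM_SPECIES$FISH_CORE) {
        hgt_cds_by_fish[s] <- .sample_cds(tips[[s]], prof_host, prof_donor,
                                          alpha = config$alpha)
      }
      cds_focal[paste0(focal, "_", gid)] <- hgt_cds_by_fish[focal]
    } else if (focal %in% names(tips)) {
      cdsf <- .sample_cds(tips[[focal]], prof_host)
      cds_focal[paste0(focal, "_", gid)] <- cdsf
      host_bg_cds[paste0(focal, "_", gid)] <- cdsf
    }
  }

  # contaminant contig: two bacterial genes nearly identical to marbac1
  # copies of dedicated bacteria-only families
  contaminant_ids <- character(0)
  if (config$contamination) {
    for (ci in 1:2) {
      gid <- sprintf("cont%02d", ci)
      contaminant_ids <- c(contaminant_ids, paste0(focal, "_", gid))
      ctree <- ape::keep.tip(sp_tree, c(SIM_SPECIES$DONOR_CANDIDATE,
                                        SIM_SPECIES$BACTERIA))
      clen <- sample(seq(config$aa_len_range[1], config$aa_len_range[2]), 1)
      tips <- evolve_sequences(ctree, clen, model = "aa")
      for (s in names(tips)) {
        proteins[[s]][paste0(s, "_", gid)] <- tips[[s]]
      }
      # the contaminant in the focal assembly is a near-copy of marbac1's
      prot <- tips[["marbac1"]]
      proteins[[focal]][paste0(focal, "_", gid)] <- prot
      cds_focal[paste0(focal, "_", gid)] <- .sample_cds(prot, prof_donor)
      classes[paste0("cont", sprintf("%02d", ci))] <- "CONTAMINANT"
    }
  }

  # donor-genome background CDS set (codon-usage comparison)
  donor_bg_cds <- character(config$n_donor_background)
  names(donor_bg_cds) <- sprintf("marbac1_bg%03d",
                                 seq_len(config$n_donor_background))
  for (i in seq_len(config$n_donor_background)) {
    prot <- paste(sample(AA_ALPHABET, 200, replace = TRUE), collapse = "")
    donor_bg_cds[i] <- .sample_cds(prot, prof_donor)
  }

  # taxonomy index over every emitted sequence
  seq_ids <- unlist(lapply(names(proteins),
                           function(s) names(proteins[[s]])), use.names = FALSE)
  seq_sp <- sub("_[^_]+$", "", seq_ids)
  seq2taxon <- data.frame(seq_id = seq_ids,
                          taxon_id = unname(tax$species_taxon[seq_sp]),
                          stringsAsFactors = FALSE)
  index <- build_taxonomy_index(tax$taxa, tax$group_spec, seq2taxon)

  # surrogate hit tables: focal proteome vs animal and non-animal databases
  queries <- proteins[[focal]]
  db_animal <- unlist(unname(proteins[animal_species]))
  db_nonanimal <- unlist(unname(proteins[nonanimal_species]))
  hits_animal <- hit_table_from_sequences(queries, db_animal)
  hits_nonanimal <- hit_table_from_sequences(queries, db_nonanimal)
  query_lengths <- stats::setNames(nchar(queries), names(queries))

  # gene models for the focal assembly: a host contig with the transferred
  # gene (3 exons) inserted between native single- and multi-exon genes,
  # and the contaminant contig (intronless)
  gene_models <- list()
  native_on_contig <- names(classes)[classes == "VERTICAL"][1:4]
  layout <- c(native_on_contig[1:2],
              if (!is.na(hgt_gene)) hgt_gene,
              native_on_contig[3:4])
  pos <- 1000
  for (g in layout) {
    gid_full <- paste0(focal, "_", g)
    cds_len <- nchar(cds_focal[[gid_full]])
    n_ex <- if (!is.na(hgt_gene) && g == hgt_gene) 3L else sample(2:4, 1L)
    cut <- sort(sample(seq_len(cds_len - 1), n_ex - 1L))
    ex_lens <- diff(c(0, cut, cds_len))
    starts <- numeric(n_ex); ends <- numeric(n_ex)
    p <- pos
    for (e in seq_len(n_ex)) {
      starts[e] <- p
      ends[e] <- p + ex_lens[e] - 1
      p <- ends[e] + 200  # intron length
    }
    gene_models[[gid_full]] <- gene_model(gid_full, "chrA", "+",
                                          cbind(starts, ends))
    pos <- p + 500
  }
  if (config$contamination) {
    pos <- 500
    for (cid in contaminant_ids) {
      cds_len <- nchar(cds_focal[[cid]])
      gene_models[[cid]] <- gene_model(cid, "contamB", "+",
                                       cbind(pos, pos + cds_len - 1))
      pos <- pos + cds_len + 300
    }
  }

  # splice-junction read support for the multi-exon genes
  junctions <- do.call(rbind, lapply(gene_models, function(m) {
    ni <- nrow(m$exons) - 1L
    if (ni < 1L) return(NULL)
    data.frame(gene_id = m$gene_id, junction = seq_len(ni),
               reads = stats::rpois(ni, 15) + 1L, stringsAsFactors = FALSE)
  }))
  rownames(junctions) <- NULL

  # per-genome presence of the transferred gene (basal fishes lack it)
  presence <- stats::setNames(
    c(rep(TRUE, length(SIM_SPECIES$FISH_CORE)),
      rep(FALSE, length(SIM_SPECIES$FISH_BASAL))),
    c(SIM_SPECIES$FISH_CORE, SIM_SPECIES$FISH_BASAL))
  if (config$n_hgt == 0L) presence[] <- FALSE

  # stage-wise expression counts for the focal genes
  stages <- config$stages
  focal_genes <- names(cds_focal)
  base_mean <- stats::rlnorm(length(focal_genes), log(20), 0.6)
  means <- matrix(rep(base_mean, length(stages)), ncol = length(stages),
                  dimnames = list(focal_genes, stages))
  if (!is.na(hgt_gene)) {
    means[paste0(focal, "_", hgt_gene), ] <-
      config$hgt_stage_means[stages] *
      nchar(cds_focal[[paste0(focal, "_", hgt_gene)]]) / 1000
  }
  counts <- simulate_counts(means, size = config$nb_size)
  totals <- stats::setNames(round(stats::runif(length(stages), 8e5, 1.2e6)),
                            stages)
  expr <- list(counts = counts,
               lengths = stats::setNames(nchar(cds_focal), focal_genes),
               totals = totals, stages = stages)

  truth <- data.frame(gene_id = names(classes), class = unname(classes),
                      donor_clade = ifelse(classes == "HGT",
                                           "DONOR_CANDIDATE", NA_character_),
                      stringsAsFactors = FALSE)

  list(proteins = proteins, cds_focal = cds_focal,
       hits_animal = hits_animal, hits_nonanimal = hits_nonanimal,
       query_lengths = query_lengths, index = index,
       taxonomy = tax$taxa, group_spec = tax$group_spec,
       seq2taxon = seq2taxon, gene_models = gene_models,
       junctions = junctions, presence = presence, expression = expr,
       hgt_alignment = hgt_alignment, hgt_gene = hgt_gene,
       hgt_cds_by_fish = hgt_cds_by_fish,
       host_background_cds = host_bg_cds,
       donor_background_cds = donor_bg_cds,
       truth = truth, focal_species = focal, config = config)
}

#' Write a simulated bundle to standard file formats
#'
#' Emits per-species protein FASTAs, the focal CDS FASTA, 12-column hit
#' tables, taxonomy and seq2taxon TSVs, a GFF3 of the focal gene models, a
#' counts TSV (plus lengths and totals), and the transferred-gene
#' alignment.
#'
#' @param bundle result of [simulate_hgt_dataset()]
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in names(bundle$proteins)) {
    if (!length(bundle$proteins[[s]])) next
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(bundle$proteins[[s]]),
      file.path(dir, paste0(s, ".faa")))
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(bundle$cds_focal),
                              file.path(dir, "focal_cds.fna"))
  write_hit_table(bundle$hits_animal, file.path(dir, "hits_animal.tsv"))
  write_hit_table(bundle$hits_nonanimal, file.path(dir, "hits_nonanimal.tsv"))
  utils::write.table(bundle$taxonomy, file.path(dir, "taxonomy.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(bundle$seq2taxon, file.path(dir, "seq2taxon.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  write_gene_models_gff3(bundle$gene_models, file.path(dir, "models.gff3"))
  if (!is.null(bundle$hgt_alignment)) {
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(bundle$hgt_alignment),
      file.path(dir, "hgt_family_alignment.faa"))
  }
  utils::write.table(bundle$expression$counts, file.path(dir, "counts.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(
    data.frame(gene_id = names(bundle$expression$lengths),
               length = unname(bundle$expression$lengths)),
    file.path(dir, "gene_lengths.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(bundle$expression$totals),
               total = unname(bundle$expression$totals)),
    file.path(dir, "mapped_totals.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(bundle$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Write gene models as GFF3
#'
#' @param models named list of `gene_model`s
#' @param path output file
#' @export
write_gene_models_gff3 <- function(models, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (m in models) {
    span <- c(min(m$exons[, 1]), max(m$exons[, 2]))
    writeLines(sprintf("%s\txenoscreen\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       m$contig, span[1], span[2], m$strand, m$gene_id), con)
    writeLines(sprintf("%s\txenoscreen\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s.t1;Parent=%s",
                       m$contig, span[1], span[2], m$strand, m$gene_id,
                       m$gene_id), con)
    for (e in seq_len(nrow(m$exons))) {
      writeLines(sprintf(
        "%s\txenoscreen\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s.t1",
        m$contig, m$exons[e, 1], m$exons[e, 2], m$strand, m$gene_id, e,
        m$gene_id), con)
    }
  }
  invisible(path)
}
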