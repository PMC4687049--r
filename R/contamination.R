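# Anti-contamination rules for a transfer candidate: intron presence
# (bacterial contaminant DNA is intronless), physical linkage to native
# genes on the assembly, and recurrence across independently sequenced
# recipient genomes.

#' Read gene models from a GFF3 file
#'
#' Uses `rtracklayer` for parsing; keeps `gene` and `exon` records and
#' groups exons under their gene via the `Parent`/`ID` chain (exons may be
#' parented by mRNAs, which are resolved to their gene).
#'
#' @param path GFF3 file
#' @return named list of gene models; each is a list with `gene_id`,
#'   `contig`, `strand`, `exons` (2-column matrix of 1-based inclusive
#'   start/end, sorted)
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$ID <- as.character(df$ID)
  par <- vapply(df$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
                character(1))
  df$parent1 <- par
  # map any feature id to its owning gene id
  owner <- stats::setNames(df$ID, df$ID)
  gene_ids <- df$ID[df$type == "gene"]
  resolve <- function(id) {
    seen <- character(0)
    while (!is.na(id) && !(id %in% gene_ids) && !(id %in% seen)) {
      seen <- c(seen, id)
      row <- match(id, df$ID)
      id <- if (is.na(row)) NA_character_ else df$parent1[row]
    }
    id
  }
  models <- list()
  for (g in gene_ids) {
    grow <- df[match(g, df$ID), ]
    ex <- df[df$type == "exon", , drop = FALSE]
    ex_owner <- vapply(ifelse(is.na(ex$parent1), ex$ID, ex$parent1),
                       resolve, character(1))
    ex <- ex[!is.na(ex_owner) & ex_owner == g, , drop = FALSE]
    exons <- if (nrow(ex)) {
      m <- cbind(start = ex$start, end = ex$end)
      m[order(m[, "start"]), , drop = FALSE]
    } else {
      cbind(start = grow$start, end = grow$end)
    }
    models[[g]] <- gene_model(g, as.character(grow$seqnames),
                              as.character(grow$strand), exons)
  }
  models
}

#' Construct a gene model
#'
#' @param gene_id identifier
#' @param contig contig/chromosome name
#' @param strand "+" or "-"
#' @param exons 2-column matrix (start, end), 1-based inclusive
#' @return object of class `gene_model`
#' @export
gene_model <- function(gene_id, contig, strand, exons) {
  exons <- matrix(as.numeric(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) > 1L &&
      any(exons[-1L, 1] <= exons[-nrow(exons), 2])) {
    stop("gene model '", gene_id, "' has overlapping exons")
  }
  structure(list(gene_id = gene_id, contig = contig, strand = strand,
                 exons = exons),
            class = "gene_model")
}

#' Intron check
#'
#' Passes iff the model has at least one intron (intron count = exon count
#' minus one). Bacterial contaminant DNA carries intronless genes, so an
#' intron-bearing, optionally splice-supported model argues against
#' contamination.
#'
#' @param model a `gene_model`
#' @param splice_support optional integer: junction-spanning read count from
#'   an RNA-seq junction table (reported, not required to pass)
#' @return list with `intron_count`, `splice_support`, `pass`
#' @export
intron_check <- function(model, splice_support = NA_integer_) {
  stopifnot(inherits(model, "gene_model"))
  n_introns <- nrow(model$exons) - 1L
  list(intron_count = n_introns, splice_support = splice_support,
       pass = n_introns >= 1L)
}

#' Physical-linkage check
#'
#' Passes iff, within `window` genes on each side of the candidate on its
#' contig, at least one neighbour is animal-affiliated: its phyletic
#' profile has at least one fish or other-animal taxon and animals
#' outnumber donor-side (bacterial) taxa. A candidate with no neighbours at
#' all fails with the reason "no context".
#'
#' @param candidate the candidate's `gene_model`
#' @param neighbours list of `gene_model`s on the same contig (the
#'   candidate itself is ignored if present)
#' @param neighbour_profiles named list of `phyletic_profile`s keyed by
#'   neighbour gene id
#' @param window genes considered per side (default 2)
#' @return list with `pass`, `reason`, and `neighbour_class` (named
#'   character vector: "animal", "non_animal" or "no_profile")
#' @export
linkage_check <- function(candidate, neighbours, neighbour_profiles,
                          window = 2L) {
  stopifnot(inherits(candidate, "gene_model"))
  neighbours <- Filter(function(m) m$gene_id != candidate$gene_id, neighbours)
  same <- vapply(neighbours, function(m) m$contig == candidate$contig, logical(1))
  neighbours <- neighbours[same]
  if (!length(neighbours)) {
    return(list(pass = FALSE, reason = "no context",
                neighbour_class = character(0)))
  }
  starts <- vapply(neighbours, function(m) m$exons[1, 1], numeric(1))
  cand_start <- candidate$exons[1, 1]
  ordn <- order(starts)
  neighbours <- neighbours[ordn]; starts <- starts[ordn]
  left <- which(starts < cand_start)
  right <- which(starts > cand_start)
  take <- c(utils::tail(left, window), utils::head(right, window))
  neighbours <- neighbours[take]

  classify_neighbour <- function(gid) {
    p <- neighbour_profiles[[gid]]
    if (is.null(p)) return("no_profile")
    animal_n <- sum(p$counts[ANIMAL_LABELS])
    donor_n <- sum(p$counts[DONOR_SIDE_LABELS])
    if (animal_n >= 1L && animal_n > donor_n) "animal" else "non_animal"
  }
  cls <- vapply(vapply(neighbours, `[[`, character(1), "gene_id"),
                classify_neighbour, character(1))
  pass <- any(cls == "animal")
  list(pass = pass,
       reason = if (pass) "linked to animal-affiliated gene(s)"
                else "no animal-affiliated neighbour in window",
       neighbour_class = cls)
}

#' Recurrence check across recipient genomes
#'
#' Independent genome assemblies are independent samples; identical
#' contamination across many of them is implausible, so presence of the
#' candidate in several recipient genomes argues for genuine integration.
#'
#' @param presence named logical vector (or character vector of genome
#'   names) recording which recipient genomes carry a homolog
#' @param min_genomes minimum number of distinct genomes (default 2)
#' @return list with `genomes_present`, `pass`
#' @export
recurrence_check <- function(presence, min_genomes = 2L) {
  genomes <- if (is.logical(presence)) names(presence)[presence]
             else as.character(presence)
  n <- length(unique(genomes))
  list(genomes_present = n, pass = n >= min_genomes)
}

#' Combined contamination report
#'
#' `CLEAN` requires every enabled check to pass; otherwise `SUSPECT`.
#'
#' @param gene_id candidate id
#' @param intron result of [intron_check()] (or NULL to skip)
#' @param linkage result of [linkage_check()] (or NULL to skip)
#' @param recurrence result of [recurrence_check()] (or NULL to skip)
#' @return object of class `contamination_report`
#' @export
contamination_report <- function(gene_id, intron = NULL, linkage = NULL,
                                 recurrence = NULL) {
  checks <- Filter(Negate(is.null),
                   list(intron = intron, linkage = linkage,
                        recurrence = recurrence))
  if (!length(checks)) stop("at least one check must be supplied")
  all_pass <- all(vapply(checks, `[[`, logical(1), "pass"))
  structure(list(gene_id = gene_id, checks = checks,
                 flag = if (all_pass) "CLEAN" else "SUSPECT"),
            class = "contamination_report")
}

#' @export
print.contamination_report <- function(x, ...) {
  cat("contamination report for", x$gene_id, "->", x$flag, "\n")
  for (nm in names(x$checks)) {
    cat(sprintf("  %-10s %s\n", nm,
                if (x$checks[[nm]]$pass) "pass" else "FAIL"))
  }
  invisible(x)
}
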