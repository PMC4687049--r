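# Candidate-discovery cascade: homology-hit filtering, phyletic profiling
# and fish-only candidate selection. Hits arrive as 12-column tabular files
# (the BLAST outfmt-6 dialect); filtering uses an E-value ceiling and a
# continuous-overlap floor, where "continuous overlap" is the single longest
# aligned query segment (one HSP) measured on the query.

#' Read a 12-column homology hit table
#'
#' Columns (tab-separated, no header): qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore.
#'
#' @param path file path
#' @return data.frame of hits
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = cols,
                          colClasses = c("character", "character",
                                         rep("numeric", 10)))
  df
}

#' Write a hit table in the 12-column tabular format
#' @param hits data.frame as returned by [read_hit_table()]
#' @param path output path
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Filter homology hits by E-value and continuous query overlap
#'
#' A hit passes iff its E-value is at most `e_max` and its single aligned
#' query segment covers at least `min_overlap` of the query length.
#' Self-hits (same subject id, or subject mapping to the same taxon as the
#' query when an index is supplied) are removed. Survivor order is preserved.
#'
#' @param hits data.frame of hits for one query (see [read_hit_table()])
#' @param query_length query protein length in residues
#' @param e_max E-value ceiling (default 1e-10)
#' @param min_overlap minimum fraction of the query covered by one aligned
#'   segment, in (0, 1] (default 0.33)
#' @param index optional `taxonomy_index`; when given, hits whose subject is
#'   from the query's own taxon are treated as self-hits
#' @param query_id query identifier (defaults to the table's qseqid)
#' @return the passing subset of `hits`
#' @export
filter_hits <- function(hits, query_length, e_max = 1e-10, min_overlap = 0.33,
                        index = NULL, query_id = NULL) {
  stopifnot(query_length > 0, min_overlap >= 0, min_overlap <= 1)
  if (nrow(hits) == 0L) return(hits)
  if (is.null(query_id)) query_id <- hits$qseqid[1]
  if (any(hits$qstart > hits$qend)) {
    stop("malformed hit: qstart > qend for query ", query_id)
  }
  if (any(hits$qend > query_length)) {
    stop("malformed hit: query coordinates exceed query length (",
         query_length, ") for query ", query_id)
  }
  if (any(hits$evalue < 0)) stop("malformed hit: negative E-value")
  seg <- (hits$qend - hits$qstart + 1) / query_length
  keep <- hits$evalue <= e_max & seg >= min_overlap
  self <- hits$sseqid == hits$qseqid
  if (!is.null(index) && query_id %in% names(index$seq2taxon)) {
    qt <- seq_taxon(query_id, index)
    known <- hits$sseqid %in% names(index$seq2taxon)
    self[known] <- self[known] | (seq_taxon(hits$sseqid[known], index) == qt)
  }
  hits[keep & !self, , drop = FALSE]
}

#' Phyletic profile of one query across analysis groups
#'
#' Counts, per group label, the number of distinct subject taxa with at
#' least one passing hit, and records the best (lowest-E; ties by higher bit
#' score then lexicographic subject id) passing hit per group.
#'
#' @param query_id query identifier
#' @param hits passing hits for this query (after [filter_hits()])
#' @param index a `taxonomy_index`
#' @return an object of class `phyletic_profile` with elements `query_id`,
#'   `counts` (named integer vector over [GROUP_LABELS]) and `best_hit`
#'   (named list of single-row data.frames)
#' @export
phyletic_profile <- function(query_id, hits, index) {
  counts <- stats::setNames(integer(length(GROUP_LABELS)), GROUP_LABELS)
  best <- stats::setNames(vector("list", length(GROUP_LABELS)), GROUP_LABELS)
  if (nrow(hits) > 0L) {
    lab <- classify_seq(hits$sseqid, index)
    taxa <- seq_taxon(hits$sseqid, index)
    for (g in unique(lab)) {
      sel <- which(lab == g)
      counts[g] <- length(unique(taxa[sel]))
      sub <- hits[sel, , drop = FALSE]
      ord <- order(sub$evalue, -sub$bitscore, sub$sseqid)
      best[[g]] <- sub[ord[1], , drop = FALSE]
    }
  }
  structure(list(query_id = query_id, counts = counts, best_hit = best),
            class = "phyletic_profile")
}

#' @export
print.phyletic_profile <- function(x, ...) {
  cat("phyletic_profile for", x$query_id, "\n")
  print(x$counts[x$counts > 0])
  invisible(x)
}

#' Select HGT candidates from animal-side and non-animal-side profiles
#'
#' A query is a candidate iff, against the animal database, it has zero
#' passing hits in non-fish animals and at least one in fishes, and, against
#' the non-animal database, it has at least one passing hit. The donor group
#' is the non-animal group holding the overall best passing hit (lowest E,
#' ties by bit score then subject id).
#'
#' @param profiles_animal named list of `phyletic_profile`s from the animal
#'   database search (one per query)
#' @param profiles_nonanimal named list of `phyletic_profile`s from the
#'   non-animal database search, same queries
#' @param fish_labels group labels counted as "fish" on the animal side
#' @return data.frame with one row per candidate: `query_id`, `donor_group`,
#'   `top_donor_subject`, `fish_taxa`, `nonanimal_taxa`,
#'   `animal_restricted`, `nonanimal_homologs`
#' @export
select_candidates <- function(profiles_animal, profiles_nonanimal,
                              fish_labels = FISH_LABELS) {
  rows <- lapply(names(profiles_animal), function(q) {
    pa <- profiles_animal[[q]]
    pn <- profiles_nonanimal[[q]]
    fish_n <- sum(pa$counts[fish_labels])
    animal_restricted <- pa$counts[["NON_FISH_ANIMAL"]] == 0L && fish_n >= 1L
    if (is.null(pn)) return(NULL)
    nonanimal_groups <- setdiff(GROUP_LABELS, ANIMAL_LABELS)
    na_counts <- pn$counts[nonanimal_groups]
    if (!animal_restricted || sum(na_counts) < 1L) return(NULL)
    cand <- do.call(rbind, Filter(Negate(is.null), pn$best_hit[nonanimal_groups]))
    grp <- rep(nonanimal_groups, vapply(pn$best_hit[nonanimal_groups],
                                        function(b) if (is.null(b)) 0L else 1L,
                                        integer(1)))
    ord <- order(cand$evalue, -cand$bitscore, cand$sseqid)
    data.frame(query_id = q,
               donor_group = grp[ord[1]],
               top_donor_subject = cand$sseqid[ord[1]],
               fish_taxa = fish_n,
               nonanimal_taxa = sum(na_counts),
               animal_restricted = TRUE,
               nonanimal_homologs = TRUE,
               stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(query_id = character(0), donor_group = character(0),
                      top_donor_subject = character(0),
                      fish_taxa = integer(0), nonanimal_taxa = integer(0),
                      animal_restricted = logical(0),
                      nonanimal_homologs = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the whole screening cascade over a proteome
#'
#' Applies [filter_hits()] to the animal-side and non-animal-side hit
#' tables, profiles every query, and selects candidates. The report mirrors
#' the funnel shape of a genome-wide screen: queries in, queries with
#' passing animal hits, fish-restricted queries, final candidates.
#'
#' @param hits_animal data.frame of hits of all queries vs the animal
#'   database
#' @param hits_nonanimal data.frame of hits vs the non-animal database
#' @param query_lengths named numeric vector: query id -> protein length
#' @param index a `taxonomy_index` covering all subjects (and ideally the
#'   queries, for taxon-aware self-hit removal)
#' @param e_max,min_overlap filtering thresholds (see [filter_hits()])
#' @return list with `candidates` (data.frame, see [select_candidates()])
#'   and `funnel` (named integer vector of per-stage survivor counts)
#' @export
screen_pipeline <- function(hits_animal, hits_nonanimal, query_lengths,
                            index, e_max = 1e-10, min_overlap = 0.33) {
  queries <- names(query_lengths)
  pa <- vector("list", length(queries)); names(pa) <- queries
  pn <- vector("list", length(queries)); names(pn) <- queries
  for (q in queries) {
    ha <- hits_animal[hits_animal$qseqid == q, , drop = FALSE]
    hn <- hits_nonanimal[hits_nonanimal$qseqid == q, , drop = FALSE]
    fa <- filter_hits(ha, query_lengths[[q]], e_max, min_overlap,
                      index = index, query_id = q)
    fn <- filter_hits(hn, query_lengths[[q]], e_max, min_overlap,
                      index = index, query_id = q)
    pa[[q]] <- phyletic_profile(q, fa, index)
    pn[[q]] <- phyletic_profile(q, fn, index)
  }
  with_animal_hits <- vapply(pa, function(p) sum(p$counts) > 0L, logical(1))
  fish_restricted <- vapply(pa, function(p) {
    p$counts[["NON_FISH_ANIMAL"]] == 0L && sum(p$counts[FISH_LABELS]) >= 1L
  }, logical(1))
  candidates <- select_candidates(pa, pn)
  funnel <- c(queries = length(queries),
              with_animal_hits = sum(with_animal_hits),
              fish_restricted = sum(fish_restricted),
              candidates = nrow(candidates))
  list(candidates = candidates, funnel = funnel,
       profiles_animal = pa, profiles_nonanimal = pn)
}
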