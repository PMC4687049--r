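# Taxonomy model: lineage structure and classification of sequences into the
# analysis groups the screening cascade needs. The recipient clade (for the
# motivating use case, the teleost clade Clupeocephala) is configuration, not
# hard-coded, so the same machinery serves other recipients.

#' Analysis group labels
#'
#' The screening logic partitions taxa into these groups. `DONOR_CANDIDATE`
#' is a configurable subgroup of `BACTERIA` (for example, marine bacteria);
#' a taxon inside the donor clade is labelled `DONOR_CANDIDATE`, never plain
#' `BACTERIA`, by the most-specific-clade rule.
#'
#' @export
GROUP_LABELS <- c("FISH_CORE", "FISH_BASAL", "NON_FISH_ANIMAL",
                  "FUNGI", "BACTERIA", "OTHER_NON_ANIMAL",
                  "DONOR_CANDIDATE")

#' Group labels counted as "animal" and as potential donors
#' @rdname GROUP_LABELS
#' @export
ANIMAL_LABELS <- c("FISH_CORE", "FISH_BASAL", "NON_FISH_ANIMAL")

#' @rdname GROUP_LABELS
#' @export
FISH_LABELS <- c("FISH_CORE", "FISH_BASAL")

#' @rdname GROUP_LABELS
#' @export
DONOR_SIDE_LABELS <- c("BACTERIA", "DONOR_CANDIDATE")

#' Read a taxonomy table
#'
#' Expects a 3-column tab-separated file `taxon_id, parent_id, name`
#' (NCBI-taxonomy-dump compatible column semantics; the root's parent is
#' itself or empty). No header.
#'
#' @param path file path
#' @return data.frame with columns `taxon_id`, `parent_id`, `name`
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 3L) stop("taxonomy file must have 3 columns: ", path)
  names(df)[1:3] <- c("taxon_id", "parent_id", "name")
  df[, 1:3]
}

#' Read a sequence-to-taxon mapping
#'
#' 2-column tab-separated `sequence_id, taxon_id`, no header.
#'
#' @param path file path
#' @return data.frame with columns `seq_id`, `taxon_id`
#' @export
read_seq2taxon <- function(path) {
  if (!file.exists(path)) stop("seq2taxon file not found: ", path)
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("seq2taxon file must have 2 columns: ", path)
  names(df)[1:2] <- c("seq_id", "taxon_id")
  df[, 1:2]
}

#' Build a taxonomy index
#'
#' Labels every taxon by the most specific configured clade root found on
#' its path to the taxonomy root, and records the sequence-to-taxon mapping.
#' `DONOR_CANDIDATE` clades nest inside `BACTERIA` clades naturally under
#' this rule (the nearer root wins).
#'
#' @param taxa data.frame with columns `taxon_id`, `parent_id`, `name`
#'   (see [read_taxonomy()]); parent chains must reach a single root without
#'   cycles
#' @param group_spec named character vector mapping clade-root `taxon_id`s to
#'   group labels in [GROUP_LABELS]
#' @param seq2taxon data.frame with columns `seq_id`, `taxon_id`
#' @param unmatched how to label taxa under no configured clade root:
#'   `"OTHER_NON_ANIMAL"` (default) or `"error"`
#' @return an object of class `taxonomy_index`
#' @export
build_taxonomy_index <- function(taxa, group_spec, seq2taxon,
                                 unmatched = c("OTHER_NON_ANIMAL", "error")) {
  unmatched <- match.arg(unmatched)
  stopifnot(is.character(group_spec), !is.null(names(group_spec)))
  bad_lab <- setdiff(unname(group_spec), GROUP_LABELS)
  if (length(bad_lab)) {
    stop("unknown group labels in group_spec: ", paste(bad_lab, collapse = ", "))
  }
  missing_roots <- setdiff(names(group_spec), taxa$taxon_id)
  if (length(missing_roots)) {
    stop("group_spec clade roots absent from taxonomy: ",
         paste(missing_roots, collapse = ", "))
  }
  parent <- stats::setNames(taxa$parent_id, taxa$taxon_id)

  # Walk each taxon rootwards; the first configured clade root encountered
  # (including the taxon itself) is the most specific match.
  label_one <- function(tid) {
    cur <- tid
    for (step in seq_len(length(parent) + 1L)) {
      if (cur %in% names(group_spec)) return(unname(group_spec[[cur]]))
      nxt <- parent[[cur]]
      if (is.na(nxt) || nxt == "" || nxt == cur) break
      if (!nxt %in% names(parent)) {
        stop("taxonomy parent '", nxt, "' of taxon '", cur, "' is unknown")
      }
      cur <- nxt
    }
    if (step > length(parent)) stop("taxonomy contains a cycle at '", tid, "'")
    NA_character_
  }
  labels <- vapply(taxa$taxon_id, label_one, character(1))
  if (anyNA(labels)) {
    if (unmatched == "error") {
      stop("taxa not covered by any configured clade root: ",
           paste(utils::head(taxa$taxon_id[is.na(labels)], 5), collapse = ", "))
    }
    labels[is.na(labels)] <- "OTHER_NON_ANIMAL"
  }
  names(labels) <- taxa$taxon_id

  unknown <- setdiff(seq2taxon$taxon_id, taxa$taxon_id)
  if (length(unknown)) {
    stop("seq2taxon refers to unknown taxon ids: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  structure(
    list(
      seq2taxon = stats::setNames(seq2taxon$taxon_id, seq2taxon$seq_id),
      taxon_label = labels,
      taxon_name = stats::setNames(taxa$name, taxa$taxon_id),
      group_spec = group_spec
    ),
    class = "taxonomy_index"
  )
}

#' @export
print.taxonomy_index <- function(x, ...) {
  cat("taxonomy_index:", length(x$taxon_label), "taxa,",
      length(x$seq2taxon), "sequences\n")
  print(table(x$taxon_label))
  invisible(x)
}

#' Classify sequences into analysis groups
#'
#' @param seq_id character vector of sequence identifiers
#' @param index a `taxonomy_index` from [build_taxonomy_index()]
#' @return character vector of group labels (see [GROUP_LABELS])
#' @export
classify_seq <- function(seq_id, index) {
  stopifnot(inherits(index, "taxonomy_index"))
  tid <- index$seq2taxon[seq_id]
  if (anyNA(tid)) {
    stop("sequence id(s) not in taxonomy index: ",
         paste(utils::head(seq_id[is.na(tid)], 5), collapse = ", "))
  }
  unname(index$taxon_label[tid])
}

#' Taxon id for a sequence
#' @inheritParams classify_seq
#' @return character vector of taxon ids
#' @export
seq_taxon <- function(seq_id, index) {
  stopifnot(inherits(index, "taxonomy_index"))
  tid <- index$seq2taxon[seq_id]
  if (anyNA(tid)) {
    stop("sequence id(s) not in taxonomy index: ",
         paste(utils::head(seq_id[is.na(tid)], 5), collapse = ", "))
  }
  unname(tid)
}
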