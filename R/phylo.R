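# Distance phylogenetics for transfer validation: Poisson-corrected amino
# acid distances, Saitou-Nei neighbour joining, column bootstrap with
# majority-rule consensus. Trees are `ape` "phylo" objects; consensus
# supports are percentages attached as internal node labels.

#' Read an aligned FASTA file into a character matrix
#'
#' @param path aligned FASTA (protein or nucleotide); all records must have
#'   equal length
#' @return character matrix, rows = taxa (named), columns = sites
#' @export
read_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(unique(Biostrings::width(ss))) != 1L) {
    stop("alignment rows have unequal lengths: ", path)
  }
  m <- do.call(rbind, strsplit(toupper(as.character(ss)), ""))
  rownames(m) <- names(ss)
  m
}

#' Coerce alignment input to a character matrix
#' @keywords internal
as_aln_matrix <- function(aln) {
  if (is.matrix(aln)) {
    if (is.null(rownames(aln))) stop("alignment matrix must have row names")
    return(aln)
  }
  if (is.character(aln) && !is.null(names(aln))) {
    if (length(unique(nchar(aln))) != 1L) stop("alignment rows differ in length")
    m <- do.call(rbind, strsplit(toupper(aln), ""))
    rownames(m) <- names(aln)
    return(m)
  }
  stop("alignment must be a character matrix or a named character vector")
}

GAP_CHARS <- c("-", ".", "?", "X", "*")

#' Poisson-corrected distance matrix
#'
#' For each pair, p = differing sites / compared sites and
#' d = -ln(1 - p). Pairs with p at or above `cap` get the capped distance
#' -ln(1 - cap) and are flagged (attribute `capped`, a logical matrix).
#'
#' @param aln alignment (matrix or named character vector of equal-length
#'   strings)
#' @param deletion `"complete"` (drop columns containing any gap, default)
#'   or `"pairwise"` (drop gapped sites per pair)
#' @param cap saturation cap on p (default 0.999)
#' @return symmetric distance matrix (class `dist`-like plain matrix) with
#'   attribute `capped`
#' @export
poisson_dist <- function(aln, deletion = c("complete", "pairwise"),
                         cap = 0.999) {
  deletion <- match.arg(deletion)
  m <- as_aln_matrix(aln)
  n <- nrow(m)
  if (n < 2L) stop("need at least 2 sequences")
  is_gap <- matrix(m %in% GAP_CHARS, nrow = n)
  if (deletion == "complete") {
    keep <- colSums(is_gap) == 0L
    m <- m[, keep, drop = FALSE]
    is_gap <- is_gap[, keep, drop = FALSE]
  }
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  capped <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      use <- !is_gap[i, ] & !is_gap[j, ]
      nc <- sum(use)
      if (nc < 2L) {
        stop("no comparable sites between '", rownames(m)[i], "' and '",
             rownames(m)[j], "'")
      }
      p <- sum(m[i, use] != m[j, use]) / nc
      if (p >= cap) {
        p <- cap
        capped[i, j] <- capped[j, i] <- TRUE
      }
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  attr(d, "capped") <- capped
  d
}

#' Neighbour-joining tree
#'
#' Standard Saitou-Nei agglomeration on a symmetric distance matrix.
#' Negative branch lengths are clamped to zero. Ties in the Q criterion are
#' broken by the lexicographically smallest label pair, so the result is
#' deterministic under input-order permutation.
#'
#' @param d symmetric distance matrix with row/column names
#' @return unrooted `phylo` tree
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbour joining needs at least 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) stop("distance matrix must have labels")
  # work on a canonical label order so input permutations cannot change
  # tie-breaking
  ord <- order(labels)
  d <- d[ord, ord, drop = FALSE]
  labels <- labels[ord]

  # active nodes carry partial newick strings; agglomerate until 3 remain
  newick <- labels
  while (nrow(d) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    Q <- (r - 2) * d - outer(R, R, `+`)
    diag(Q) <- Inf
    # smallest Q; ties -> smallest (i, j) in current (sorted-label) order
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    vi <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- d[i, j] - vi
    merged <- sprintf("(%s:%.12g,%s:%.12g)",
                      newick[i], max(vi, 0), newick[j], max(vj, 0))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    nm <- c(rownames(d)[keep], paste0("__n", r))
    dimnames(d2) <- list(nm, nm)
    d <- d2
    newick <- c(newick[keep], merged)
  }
  # final 3-node star
  a <- d[1, 2]; b <- d[1, 3]; cc <- d[2, 3]
  v <- pmax(c((a + b - cc) / 2, (a + cc - b) / 2, (b + cc - a) / 2), 0)
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 newick[1], v[1], newick[2], v[2], newick[3], v[3])
  ape::read.tree(text = txt)
}

# --- bipartition utilities -------------------------------------------------

#' Unrooted bipartitions of a tree
#'
#' Each internal edge induces a split of the tips; splits are keyed by the
#' sorted tip set on the side NOT containing the reference tip (the first
#' label in `ref_order`), so keys are comparable across trees on the same
#' taxa. Trivial splits (single tips) are excluded.
#'
#' @param tree `phylo`
#' @param ref_order character vector fixing the reference taxon set/order
#' @return character vector of split keys (tips joined by "|")
#' @export
tree_bipartitions <- function(tree, ref_order = sort(tree$tip.label)) {
  ref <- ref_order[1]
  n <- length(tree$tip.label)
  desc <- tip_descendants(tree)
  keys <- character(0)
  for (node in (n + 1L):(n + tree$Nnode)) {
    tips <- tree$tip.label[desc[[node - n]]]
    if (ref %in% tips) tips <- setdiff(ref_order, tips)
    if (length(tips) >= 2L && length(tips) <= n - 2L) {
      keys <- c(keys, paste(sort(tips), collapse = "|"))
    }
  }
  unique(keys)
}

# tip index sets below each internal node (postorder accumulation)
tip_descendants <- function(tree) {
  n <- length(tree$tip.label)
  res <- vector("list", tree$Nnode)
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1] - n
    ch <- po$edge[k, 2]
    add <- if (ch <= n) ch else res[[ch - n]]
    res[[par]] <- c(res[[par]], add)
  }
  res
}

#' Bootstrap a distance tree and build the majority-rule consensus
#'
#' Resamples alignment columns with replacement, rebuilds a Poisson-distance
#' NJ tree per pseudoreplicate, counts unrooted bipartitions, and returns
#' the >50% majority-rule consensus with clade supports (percent of
#' replicates containing the bipartition) as internal node labels.
#'
#' @param aln alignment (see [poisson_dist()])
#' @param n_reps number of pseudoreplicates (>= 1; 1000 in typical use)
#' @param seed RNG seed for reproducibility
#' @param deletion gap-deletion mode passed to [poisson_dist()]
#' @return list with `consensus` (`phylo` with `node.label` supports),
#'   `split_freq` (named numeric vector, percent per observed split) and
#'   `n_reps`
#' @export
bootstrap_consensus <- function(aln, n_reps = 1000L, seed = NULL,
                                deletion = "complete") {
  m <- as_aln_matrix(aln)
  stopifnot(n_reps >= 1L)
  if (!is.null(seed)) set.seed(seed)
  if (deletion == "complete") {
    keep <- colSums(matrix(m %in% GAP_CHARS, nrow = nrow(m))) == 0L
    m <- m[, keep, drop = FALSE]
  }
  nc <- ncol(m)
  if (nc < 2L) stop("too few usable columns to bootstrap")
  ref_order <- sort(rownames(m))
  counts <- new.env(parent = emptyenv())
  for (b in seq_len(n_reps)) {
    cols <- sample.int(nc, nc, replace = TRUE)
    tr <- nj_tree(poisson_dist(m[, cols, drop = FALSE], deletion = "pairwise"))
    for (k in tree_bipartitions(tr, ref_order)) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  keys <- ls(counts)
  freq <- vapply(keys, function(k) counts[[k]], integer(1))
  split_freq <- 100 * freq / n_reps
  names(split_freq) <- keys
  cons <- consensus_from_splits(ref_order,
                                split_freq[split_freq > 50],
                                all_tips = rownames(m))
  list(consensus = cons, split_freq = sort(split_freq, decreasing = TRUE),
       n_reps = n_reps)
}

#' Majority-rule consensus tree from hand-supplied replicate trees
#'
#' Convenience wrapper used when replicate trees come from elsewhere (for
#' example, an external likelihood program): counts unrooted bipartitions
#' across `trees` and keeps those present in more than half.
#'
#' @param trees list of `phylo` trees on the same tip set
#' @return list with `consensus` and `split_freq` as in
#'   [bootstrap_consensus()]
#' @export
consensus_majority <- function(trees) {
  stopifnot(length(trees) >= 1L)
  tips <- sort(trees[[1]]$tip.label)
  ref_order <- tips
  tab <- table(unlist(lapply(trees, tree_bipartitions, ref_order = ref_order)))
  split_freq <- 100 * as.numeric(tab) / length(trees)
  names(split_freq) <- names(tab)
  cons <- consensus_from_splits(ref_order, split_freq[split_freq > 50],
                                all_tips = tips)
  list(consensus = cons, split_freq = sort(split_freq, decreasing = TRUE),
       n_reps = length(trees))
}

# Build a (rooted-representation) consensus tree from mutually compatible
# majority splits. Splits are keyed as in tree_bipartitions(): tip sets not
# containing the reference tip. Node labels carry the split's support.
consensus_from_splits <- function(ref_order, split_freq, all_tips) {
  clades <- lapply(names(split_freq), function(k) strsplit(k, "|", fixed = TRUE)[[1]])
  supp <- unname(split_freq)
  ord <- order(vapply(clades, length, integer(1)), decreasing = TRUE)
  clades <- clades[ord]; supp <- supp[ord]

  # recursive container: each node = list(tips=..., support=..., children=list())
  root <- list(tips = all_tips, support = NA_real_, children = list())
  insert <- function(node, clade, s) {
    for (ci in seq_along(node$children)) {
      ch <- node$children[[ci]]
      if (all(clade %in% ch$tips)) {
        node$children[[ci]] <- insert(ch, clade, s)
        return(node)
      }
    }
    newn <- list(tips = clade, support = s, children = list())
    # move children fully inside the clade under the new node
    move <- vapply(node$children, function(ch) all(ch$tips %in% clade), logical(1))
    newn$children <- node$children[move]
    node$children <- node$children[!move]
    node$children <- c(node$children, list(newn))
    node
  }
  for (i in seq_along(clades)) root <- insert(root, clades[[i]], supp[i])

  to_newick <- function(node) {
    covered <- unlist(lapply(node$children, function(ch) ch$tips))
    loose <- setdiff(node$tips, covered)
    parts <- c(sort(loose), vapply(node$children, to_newick, character(1)))
    lab <- if (is.na(node$support)) "" else sprintf("%.10g", node$support)
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  txt <- paste0(to_newick(root), ";")
  ape::read.tree(text = txt)
}
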