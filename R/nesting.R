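# Tree-based validation of a transfer: does the fish clade nest inside the
# candidate donor group with strong support, and which direction of
# transfer, and how many events does each hypothesis (vertical inheritance
# with losses vs a single gain) require under Dollo parsimony.

#' Test whether fish sequences nest inside a donor group
#'
#' Searches the tree's unrooted bipartitions for sides that contain every
#' fish tip plus at least one other member, with all other members in the
#' donor group — each such split is evidence that the fish sequences nest
#' inside the donor radiation. The transfer is `validated` when the
#' best-supported of these splits reaches `support_min` (resolution inside
#' the donor clade itself is irrelevant to the nesting claim, so the
#' strongest certifying split is judged). Direction calls:
#' \itemize{
#'   \item `DONOR_TO_RECIPIENT` - the fish tips sit inside a donor-dominated
#'     context (all extra members of their enclosing split are donors);
#'   \item `RECIPIENT_TO_DONOR` - the donor tips are instead embedded within
#'     a larger clade of recipient-side eukaryotes;
#'   \item `UNRESOLVED` otherwise.
#' }
#'
#' Support values come from the tree's internal node labels (percentages,
#' e.g. bootstrap or posterior-probability-derived supports on imported
#' trees); a split without a label is treated as support 0.
#'
#' @param tree `phylo` with support percentages as internal node labels
#' @param labels named character vector tip label -> group label
#'   (see [GROUP_LABELS])
#' @param support_min validation threshold on the percentage scale
#'   (default 90)
#' @param fish_labels,donor_labels group labels counted as recipient fish
#'   and as donor
#' @return object of class `nesting_verdict`: list with `clade_found`,
#'   `clade_tips`, `support`, `decision` ("validated"/"unvalidated"),
#'   `direction`
#' @export
nesting_test <- function(tree, labels, support_min = 90,
                         fish_labels = FISH_LABELS,
                         donor_labels = "DONOR_CANDIDATE") {
  tips <- tree$tip.label
  missing <- setdiff(tips, names(labels))
  if (length(missing)) {
    stop("tips without group labels: ", paste(utils::head(missing, 5),
                                              collapse = ", "))
  }
  lab <- labels[tips]
  fish <- tips[lab %in% fish_labels]
  donor <- tips[lab %in% donor_labels]
  if (!length(fish)) stop("tree contains no fish tips")
  if (!length(donor)) stop("tree contains no donor-group tips")

  sp <- tree_splits_with_support(tree)

  # split sides strictly containing `target` whose other members all fall
  # in `allowed` groups; the best-supported one certifies the nesting
  # (resolution inside the surrounding group is irrelevant to the claim)
  nesting_side <- function(target, allowed) {
    sides <- Filter(function(s) {
      all(target %in% s$tips) && length(s$tips) > length(target) &&
        all(lab[setdiff(s$tips, target)] %in% allowed)
    }, sp)
    if (!length(sides)) return(NULL)
    supp <- vapply(sides, function(s) s$support, numeric(1))
    if (all(is.na(supp))) return(sides[[1]])
    sides[[which.max(ifelse(is.na(supp), -Inf, supp))]]
  }
  clade_found <- FALSE; support <- NA_real_; clade_tips <- character(0)
  decision <- "unvalidated"; direction <- "UNRESOLVED"
  side_f <- nesting_side(fish, donor_labels)
  if (!is.null(side_f)) {
    clade_found <- TRUE
    clade_tips <- side_f$tips
    support <- side_f$support
    if (!is.na(support) && support >= support_min) decision <- "validated"
    direction <- "DONOR_TO_RECIPIENT"
  } else {
    # opposite pattern: donors embedded among recipient-side eukaryotes
    euk <- c(fish_labels, "NON_FISH_ANIMAL", "FUNGI", "OTHER_NON_ANIMAL")
    side_d <- nesting_side(donor, euk)
    if (!is.null(side_d)) {
      direction <- "RECIPIENT_TO_DONOR"
      clade_tips <- side_d$tips
      support <- side_d$support
    }
  }
  structure(list(clade_found = clade_found, clade_tips = clade_tips,
                 support = support, decision = decision,
                 direction = direction, support_min = support_min),
            class = "nesting_verdict")
}

#' @export
print.nesting_verdict <- function(x, ...) {
  cat("nesting verdict:", x$decision,
      sprintf("(support %s, threshold %g)",
              ifelse(is.na(x$support), "NA", format(x$support)), x$support_min),
      "\n  direction:", x$direction, "\n")
  invisible(x)
}

# All unrooted split sides of a tree with their supports. For each internal
# node (except the root of the representation) both sides of its edge are
# usable; we return each side once, with the node's label as support.
tree_splits_with_support <- function(tree) {
  n <- length(tree$tip.label)
  desc <- tip_descendants(tree)
  supports <- rep(NA_real_, tree$Nnode)
  if (!is.null(tree$node.label)) {
    suppressWarnings(supports <- as.numeric(tree$node.label))
  }
  out <- list()
  root <- n + 1L
  for (node in (n + 1L):(n + tree$Nnode)) {
    tips_in <- tree$tip.label[desc[[node - n]]]
    s <- supports[node - n]
    if (node == root) s <- NA_real_  # representation root, not a split
    if (length(tips_in) >= 2L && length(tips_in) <= n - 1L && node != root) {
      out <- c(out, list(list(tips = sort(tips_in), support = s)),
               list(list(tips = sort(setdiff(tree$tip.label, tips_in)),
                         support = s)))
    }
  }
  out
}

#' Gene-loss vs transfer parsimony
#'
#' Compares two explanations of a patchy phyletic distribution on a rooted
#' species tree. Under vertical inheritance the gene is present at the root
#' and each absence is explained by losses (Dollo parsimony: one gain,
#' unlimited losses), so the cost is the minimal number of independent loss
#' branches. Under transfer the gene is gained once on the stem of the
#' smallest clade containing the presence set, plus any losses needed
#' inside that clade.
#'
#' @param species_tree rooted `phylo`
#' @param presence character vector of tips carrying the gene
#' @return list with `losses_under_vertical`, `events_under_hgt`
#'   (1 gain + internal losses) and `preferred`
#'   ("HGT", "VERTICAL" or "UNRESOLVED" on ties)
#' @export
loss_parsimony <- function(species_tree, presence) {
  tips <- species_tree$tip.label
  if (!length(presence)) stop("presence set is empty")
  bad <- setdiff(presence, tips)
  if (length(bad)) stop("presence tips not in tree: ", paste(bad, collapse = ", "))

  n <- length(tips)
  desc <- tip_descendants(species_tree)
  has_present <- function(node) {
    if (node <= n) return(tips[node] %in% presence)
    any(tips[desc[[node - n]]] %in% presence)
  }
  # losses below `node`, assuming the gene is present on the branch into it:
  # an edge from a "present-below" node into a "nothing-present-below" child
  # is one loss; subtrees with presence recurse.
  losses_below <- function(node) {
    if (node <= n) return(0L)
    children <- species_tree$edge[species_tree$edge[, 1] == node, 2]
    sum(vapply(children, function(ch) {
      if (has_present(ch)) losses_below(ch) else 1L
    }, integer(1)))
  }
  root <- n + 1L
  losses_vertical <- losses_below(root)

  mrca_node <- if (length(presence) == 1L) {
    which(tips == presence)
  } else {
    ape::getMRCA(species_tree, presence)
  }
  events_hgt <- 1L + if (mrca_node <= n) 0L else losses_below(mrca_node)

  preferred <- if (events_hgt < losses_vertical) "HGT"
  else if (events_hgt > losses_vertical) "VERTICAL"
  else "UNRESOLVED"
  list(losses_under_vertical = losses_vertical,
       events_under_hgt = events_hgt,
       preferred = preferred)
}
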