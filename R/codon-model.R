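# One-ratio (M0) codon substitution model: Goldman-Yang-style 61-state
# Markov model with transition/transversion ratio kappa, nonsynonymous/
# synonymous ratio omega shared across branches and sites, F3x4 codon
# frequencies, likelihood by Felsenstein pruning, and numerical
# maximization over branch lengths, kappa and omega.

PURINES <- c("A", "G")

.is_transition <- function(b1, b2) {
  (b1 %in% PURINES) == (b2 %in% PURINES)
}

# precomputed structure of single-nucleotide neighbours among sense codons:
# for each ordered pair differing at one position, whether the change is a
# transition and whether it is synonymous
.codon_pair_structure <- function() {
  ns <- length(SENSE_CODONS)
  from <- integer(0); to <- integer(0); ts <- logical(0); syn <- logical(0)
  split_mat <- do.call(rbind, strsplit(SENSE_CODONS, ""))
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (i == j) next
      diff <- which(split_mat[i, ] != split_mat[j, ])
      if (length(diff) != 1L) next
      from <- c(from, i); to <- c(to, j)
      ts <- c(ts, .is_transition(split_mat[i, diff], split_mat[j, diff]))
      syn <- c(syn, GENETIC_CODE_1[[SENSE_CODONS[i]]] ==
                 GENETIC_CODE_1[[SENSE_CODONS[j]]])
    }
  }
  list(from = from, to = to, transition = ts, synonymous = syn)
}

# computed once at load time; 3,660 ordered single-step codon pairs
CODON_PAIRS <- .codon_pair_structure()
codon_pairs <- function() CODON_PAIRS

#' F3x4 codon frequencies from a codon alignment
#'
#' Position-specific nucleotide frequencies are estimated from the codon
#' columns; each sense codon's frequency is the product over its three
#' positions, renormalized over the 61 sense codons. Frequencies are
#' floored at 1e-8 (then renormalized) so the rate matrix stays reversible
#' and well-conditioned even when a nucleotide is unseen at some position.
#'
#' @param aln a `codon_alignment` (see [codon_alignment()])
#' @return numeric vector of length 61, named by codon
#' @export
f3x4_frequencies <- function(aln) {
  codons <- SENSE_CODONS[as.vector(aln$states)]
  mat <- do.call(rbind, strsplit(codons, ""))
  f <- sapply(1:3, function(p) {
    tab <- table(factor(mat[, p], levels = c("T", "C", "A", "G")))
    as.numeric(tab) / sum(tab)
  })
  rownames(f) <- c("T", "C", "A", "G")
  sense_mat <- do.call(rbind, strsplit(SENSE_CODONS, ""))
  pi <- f[sense_mat[, 1], 1] * f[sense_mat[, 2], 2] * f[sense_mat[, 3], 3]
  pi <- pmax(pi / sum(pi), 1e-8)
  pi <- pi / sum(pi)
  names(pi) <- SENSE_CODONS
  pi
}

#' Build the M0 rate matrix
#'
#' q_ij = pi_j * kappa^[transition] * omega^[nonsynonymous] for codon pairs
#' one nucleotide apart, 0 otherwise; diagonal makes rows sum to zero; the
#' matrix is scaled so the expected substitution rate at equilibrium is 1,
#' i.e. branch lengths are in expected substitutions per codon.
#'
#' @param kappa transition/transversion rate ratio (> 0)
#' @param omega nonsynonymous/synonymous rate ratio (>= 0)
#' @param pi equilibrium codon frequencies (length 61)
#' @return 61 x 61 rate matrix
#' @export
m0_rate_matrix <- function(kappa, omega, pi) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61)
  cp <- codon_pairs()
  ns <- 61L
  Q <- matrix(0, ns, ns, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  rate <- pi[cp$to] * ifelse(cp$transition, kappa, 1) *
    ifelse(cp$synonymous, 1, omega)
  Q[cbind(cp$from, cp$to)] <- rate
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix (omega and kappa too small?)")
  Q / scale
}

# eigen-decomposition of the reversible rate matrix via symmetrization;
# returns a closure computing P(t)
.m0_propagator <- function(Q, pi) {
  sp <- sqrt(pi)
  A <- (sp * Q) %*% diag(1 / sp)  # row-scale by sp, col-scale by 1/sp
  A <- (A + t(A)) / 2             # enforce symmetry against rounding
  e <- eigen(A, symmetric = TRUE)
  U <- e$vectors
  left <- (1 / sp) * U            # diag(1/sp) %*% U
  right <- t(U * sp)              # t(U) %*% diag(sp)
  function(t) {
    P <- left %*% (exp(e$values * t) * right)
    P[P < 0] <- 0
    P
  }
}

#' Build a codon alignment from aligned coding sequences
#'
#' Columns containing gaps, ambiguity characters or stop codons are
#' dropped. Sequences must be aligned (equal length, length divisible
#' by 3).
#'
#' @param cds named character vector of aligned CDS strings
#' @return object of class `codon_alignment`: list with `states` (integer
#'   matrix taxa x codon columns, values indexing [SENSE_CODONS]), `taxa`,
#'   `n_dropped` (columns removed)
#' @export
codon_alignment <- function(cds) {
  if (is.null(names(cds))) stop("sequences must be named")
  lens <- nchar(cds)
  if (length(unique(lens)) != 1L) stop("sequences are not aligned")
  if (lens[1] %% 3L != 0L) stop("alignment length not a multiple of 3")
  ncod <- lens[1] %/% 3L
  codmat <- t(vapply(cds, function(s) {
    s <- toupper(s)
    substring(s, seq(1L, lens[1], 3L), seq(3L, lens[1], 3L))
  }, character(ncod)))
  if (ncod == 1L) codmat <- matrix(codmat, ncol = 1L,
                                   dimnames = list(names(cds), NULL))
  idx <- matrix(match(codmat, SENSE_CODONS), nrow = nrow(codmat))
  keep <- colSums(is.na(idx)) == 0L
  structure(list(states = idx[, keep, drop = FALSE], taxa = names(cds),
                 n_dropped = sum(!keep)),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$taxa), "taxa,", ncol(x$states),
      "codon columns (", x$n_dropped, "dropped )\n")
  invisible(x)
}

# site-pattern compression: unique columns and their weights
.site_patterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ",")
  tab <- table(key)
  first <- match(names(tab), key)
  list(states = states[, first, drop = FALSE], weights = as.numeric(tab))
}

# log-likelihood by pruning; tree is an ape phylo (rooted representation is
# fine for this reversible model), bl is a vector of branch lengths ordered
# as tree$edge rows
.m0_loglik <- function(tree, pat, pi, kappa, omega, bl) {
  Q <- m0_rate_matrix(kappa, omega, pi)
  Pfun <- .m0_propagator(Q, pi)
  n <- length(tree$tip.label)
  npat <- ncol(pat$states)
  po <- ape::reorder.phylo(tree, "postorder")
  partial <- vector("list", n + tree$Nnode)
  scalevec <- vector("list", n + tree$Nnode)  # per-pattern log scaling
  tip_row <- match(tree$tip.label, rownames(pat$states))

  for (k in seq_len(nrow(po$edge))) {
    parent <- po$edge[k, 1]; child <- po$edge[k, 2]
    P <- Pfun(max(bl[k], 0))
    if (child <= n) {
      msg <- P[, pat$states[tip_row[child], ], drop = FALSE]
      child_scale <- 0
    } else {
      msg <- P %*% partial[[child]]
      child_scale <- scalevec[[child]]
    }
    if (is.null(partial[[parent]])) {
      partial[[parent]] <- msg
      scalevec[[parent]] <- rep(0, npat) + child_scale
    } else {
      partial[[parent]] <- partial[[parent]] * msg
      scalevec[[parent]] <- scalevec[[parent]] + child_scale
    }
    mx <- apply(partial[[parent]], 2, max)  # rescale against underflow
    mx[mx <= 0] <- 1
    partial[[parent]] <- sweep(partial[[parent]], 2, mx, "/")
    scalevec[[parent]] <- scalevec[[parent]] + log(mx)
  }
  root <- po$edge[nrow(po$edge), 1]
  L <- colSums(pi * partial[[root]])
  sum(pat$weights * (log(L) + scalevec[[root]]))
}

#' Fit the one-ratio (M0) codon model
#'
#' Maximizes the likelihood over branch lengths, kappa and omega on the
#' supplied topology, with F3x4 codon frequencies estimated from the
#' alignment. Parameters are optimized on the log scale with L-BFGS-B from
#' several fixed starting points; the best fit is returned, so results are
#' deterministic.
#'
#' @param aln a `codon_alignment`
#' @param tree `phylo` whose tip labels match the alignment taxa
#' @param n_starts number of deterministic starting points (default 3)
#' @param control list passed to [stats::optim()] (default
#'   `list(maxit = 300)`)
#' @return `selection_result` with `lnL`, `kappa`, `omega`,
#'   `branch_lengths` (ordered as `tree$edge`), `pi`, `model = "M0"`,
#'   `convergence`
#' @export
m0_fit <- function(aln, tree, n_starts = 3L, control = list(maxit = 300)) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (!setequal(tree$tip.label, aln$taxa)) {
    stop("tree tips and alignment taxa differ")
  }
  if (length(aln$taxa) < 2L) stop("need at least 2 taxa")
  if (ncol(aln$states) < 1L) stop("no usable codon columns")
  states <- aln$states
  rownames(states) <- aln$taxa
  pat <- .site_patterns(states)
  pat$states <- pat$states[tree$tip.label, , drop = FALSE]
  rownames(pat$states) <- tree$tip.label
  pi <- f3x4_frequencies(aln)
  nb <- nrow(tree$edge)

  obj <- function(par) {
    bl <- exp(par[seq_len(nb)])
    kappa <- exp(par[nb + 1L])
    omega <- exp(par[nb + 2L])
    ll <- tryCatch(.m0_loglik(tree, pat, pi, kappa, omega, bl),
                   error = function(e) -Inf)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  starts <- list(c(bl = 0.1, kappa = 2, omega = 0.2),
                 c(bl = 0.3, kappa = 4, omega = 0.05),
                 c(bl = 0.05, kappa = 1, omega = 1))
  starts <- starts[seq_len(min(n_starts, length(starts)))]
  best <- NULL
  for (s in starts) {
    par0 <- log(c(rep(s[["bl"]], nb), s[["kappa"]], s[["omega"]]))
    fit <- stats::optim(par0, obj, method = "L-BFGS-B",
                        lower = rep(log(1e-6), nb + 2L),
                        upper = rep(log(50), nb + 2L),
                        control = control)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (!is.finite(best$value) || best$value >= 1e10) {
    stop("M0 optimization failed: non-finite likelihood at optimum")
  }
  bl <- exp(best$par[seq_len(nb)])
  structure(list(lnL = -best$value,
                 kappa = exp(best$par[nb + 1L]),
                 omega = exp(best$par[nb + 2L]),
                 branch_lengths = bl, pi = pi, model = "M0",
                 convergence = best$convergence,
                 tree = tree),
            class = "selection_result")
}
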