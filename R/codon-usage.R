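# Composition and codon-usage-bias metrics used to assess amelioration of a
# transferred gene toward its host genome: GC, GC3s, CAI, CBI, Fop, ENC,
# and a host-vs-donor background comparison. Conventions: six-fold families
# are treated as single families; Met, Trp and stops are excluded from all
# synonymous-usage statistics.

#' Codon usage table from one or more coding sequences
#'
#' @param cds character vector of CDS strings (terminal stops trimmed)
#' @return object of class `codon_usage_table`: list with `counts`
#'   (named integer vector over the 64 codons), `rel_freq` (within-family
#'   relative synonymous frequencies) and `n_seq`
#' @export
codon_usage_table <- function(cds) {
  counts <- stats::setNames(integer(64), names(GENETIC_CODE_1))
  for (i in seq_along(cds)) {
    codons <- validate_cds(cds[[i]], id = if (!is.null(names(cds))) names(cds)[i] else i)
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  rel <- rep(NA_real_, 64)
  names(rel) <- names(counts)
  for (fam in SYN_FAMILIES) {
    tot <- sum(counts[fam])
    if (tot > 0) rel[fam] <- counts[fam] / tot
  }
  structure(list(counts = counts, rel_freq = rel, n_seq = length(cds)),
            class = "codon_usage_table")
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat("codon_usage_table:", sum(x$counts), "codons from", x$n_seq,
      "sequence(s)\n")
  invisible(x)
}

#' GC content and GC3s of a coding sequence
#'
#' GC is the G+C fraction over all positions. GC3s is the G+C fraction at
#' third positions of synonymously variable codons only (Met, Trp and stop
#' codons excluded); it is `NA` when no such codon occurs.
#'
#' @param cds a CDS string
#' @return list with `GC` and `GC3s`
#' @export
composition <- function(cds) {
  codons <- validate_cds(cds)
  all_nt <- strsplit(paste(codons, collapse = ""), "")[[1]]
  gc <- mean(all_nt %in% c("G", "C"))
  deg <- CODON_DEGENERACY[codons]
  synvar <- !is.na(deg) & deg > 1L
  gc3s <- if (any(synvar)) {
    third <- substring(codons[synvar], 3, 3)
    mean(third %in% c("G", "C"))
  } else NA_real_
  list(GC = gc, GC3s = gc3s)
}

#' Codon adaptation index
#'
#' Relative adaptiveness w(c) = f(c) / max f within c's synonymous family,
#' from the reference usage table; CAI is the geometric mean of w over the
#' gene's codons, excluding Met, Trp and stops. Codons unseen in the
#' reference receive a 0.5 pseudocount so w is always positive.
#'
#' @param cds a CDS string
#' @param reference a `codon_usage_table` for the reference (host) gene set
#' @return CAI value in (0, 1]
#' @export
cai <- function(cds, reference) {
  stopifnot(inherits(reference, "codon_usage_table"))
  codons <- validate_cds(cds)
  w <- rep(NA_real_, 64)
  names(w) <- names(GENETIC_CODE_1)
  for (fam in SYN_FAMILIES) {
    if (length(fam) == 1L) { w[fam] <- 1; next }
    cnt <- pmax(reference$counts[fam], 0) + ifelse(reference$counts[fam] == 0, 0.5, 0)
    w[fam] <- cnt / max(cnt)
  }
  deg <- CODON_DEGENERACY[codons]
  use <- !is.na(deg) & deg > 1L
  if (!any(use)) stop("no synonymously variable codons; CAI undefined")
  exp(mean(log(w[codons[use]])))
}

#' Effective number of codons (Wright's ENC)
#'
#' Per-family homozygosity F = (n * sum p_i^2 - 1) / (n - 1) for families
#' with n >= 2 observations; class means over families of degeneracy 2, 3,
#' 4 and 6 enter ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6. A degeneracy class
#' with no usable family is imputed from the observed classes (see
#' Details) and the result is flagged. The value is clipped to [20, 61].
#'
#' Details: the 3-fold class (Ile only) is imputed as the mean of the 2-
#' and 4-fold class means when absent, following Wright; any other absent
#' class k is imputed by matching the average within-family "spread"
#' s = (1/F - 1)/(k - 1) of the observed classes.
#'
#' @param cds a CDS string
#' @return list with `ENC`, `imputed_classes` (character vector, possibly
#'   empty)
#' @export
enc <- function(cds) {
  codons <- validate_cds(cds)
  counts <- table(codons)
  fam_F <- list(`2` = numeric(0), `3` = numeric(0), `4` = numeric(0),
                `6` = numeric(0))
  for (fam in SYN_FAMILIES) {
    k <- length(fam)
    if (k == 1L) next
    n_i <- as.numeric(counts[fam]); n_i[is.na(n_i)] <- 0
    n <- sum(n_i)
    if (n < 2) next
    p <- n_i / n
    f <- (n * sum(p^2) - 1) / (n - 1)
    fam_F[[as.character(k)]] <- c(fam_F[[as.character(k)]], f)
  }
  # class means; families with F = 0 would make 1/F blow up -- Wright's
  # estimator averages F across a class first, which we follow
  Fbar <- vapply(fam_F, function(v) if (length(v)) mean(v) else NA_real_,
                 numeric(1))
  if (all(is.na(Fbar))) stop("no multi-codon family observed; ENC undefined")
  imputed <- character(0)
  if (is.na(Fbar[["3"]]) && !is.na(Fbar[["2"]]) && !is.na(Fbar[["4"]])) {
    Fbar[["3"]] <- (Fbar[["2"]] + Fbar[["4"]]) / 2
    imputed <- c(imputed, "3")
  }
  ks <- c(2, 3, 4, 6)
  obs <- !is.na(Fbar)
  if (any(!obs)) {
    s <- mean((1 / Fbar[obs] - 1) / (ks[obs] - 1))
    for (k in which(!obs)) {
      Fbar[k] <- 1 / (1 + s * (ks[k] - 1))
      imputed <- c(imputed, names(Fbar)[k])
    }
  }
  Fbar <- pmax(Fbar, 1e-6)
  val <- 2 + 9 / Fbar[["2"]] + 1 / Fbar[["3"]] + 5 / Fbar[["4"]] +
    3 / Fbar[["6"]]
  list(ENC = min(max(val, 20), 61), imputed_classes = unique(imputed))
}

#' Optimal codons from a reference usage table
#'
#' The most frequent codon of each degenerate family; deterministic ties go
#' to the alphabetically first codon.
#'
#' @param reference a `codon_usage_table`
#' @return character vector, one codon per degenerate family
#' @export
optimal_codons <- function(reference) {
  stopifnot(inherits(reference, "codon_usage_table"))
  out <- character(0)
  for (fam in SYN_FAMILIES) {
    if (length(fam) == 1L) next
    cnt <- reference$counts[fam]
    fam_sorted <- sort(fam)
    cnt <- cnt[fam_sorted]
    out <- c(out, fam_sorted[which.max(cnt)])
  }
  out
}

#' Frequency of optimal codons and codon bias index
#'
#' Over codons in degenerate families: Fop = N_opt / N_tot and
#' CBI = (N_opt - N_rand) / (N_tot - N_rand), where N_rand is the optimal
#' usage expected under uniform synonymous choice,
#' sum over families of n_family / k_family.
#'
#' @param cds a CDS string
#' @param optimal character vector with one codon per degenerate family
#'   (see [optimal_codons()])
#' @return list with `Fop`, `CBI` (`CBI` is NA when N_tot == N_rand)
#' @export
cbi_fop <- function(cds, optimal) {
  codons <- validate_cds(cds)
  fam_of <- stats::setNames(GENETIC_CODE_1[optimal], optimal)
  if (anyDuplicated(fam_of)) stop("more than one optimal codon in a family")
  deg <- CODON_DEGENERACY[codons]
  use <- !is.na(deg) & deg > 1L
  codons <- codons[use]
  if (!length(codons)) stop("no codons in degenerate families")
  n_tot <- length(codons)
  n_opt <- sum(codons %in% optimal)
  n_rand <- sum(1 / CODON_DEGENERACY[codons])
  fop <- n_opt / n_tot
  cbi_val <- if (abs(n_tot - n_rand) < 1e-12) NA_real_
             else (n_opt - n_rand) / (n_tot - n_rand)
  list(Fop = fop, CBI = cbi_val)
}

#' All amelioration metrics for one gene
#'
#' @param cds a CDS string
#' @param reference a `codon_usage_table` used for CAI and the optimal-codon
#'   set
#' @return named numeric vector GC, GC3s, CAI, CBI, Fop, ENC
#' @export
gene_metrics <- function(cds, reference) {
  comp <- composition(cds)
  opt <- optimal_codons(reference)
  cf <- cbi_fop(cds, opt)
  c(GC = comp$GC, GC3s = comp$GC3s, CAI = cai(cds, reference),
    CBI = cf$CBI, Fop = cf$Fop, ENC = enc(cds)$ENC)
}

#' Compare a gene's metrics to host and donor backgrounds
#'
#' For each metric the gene's z-score is computed within the host and the
#' donor background distributions (per-gene metric values across each
#' background set); the nearer background has the smaller absolute z. The
#' overall call is the majority across metrics; a tie gives
#' `INCONCLUSIVE`. Zero-variance backgrounds fall back to the absolute
#' difference from the background mean and are flagged.
#'
#' @param gene named numeric vector of the gene's metrics
#' @param host_metrics matrix/data.frame, one row per host background gene,
#'   columns matching `gene`
#' @param donor_metrics same for the donor background
#' @param min_background minimum background size (default 50)
#' @return object of class `amelioration_report`: per-metric table plus
#'   `call` ("HOST", "DONOR" or "INCONCLUSIVE")
#' @export
compare_backgrounds <- function(gene, host_metrics, donor_metrics,
                                min_background = 50L) {
  host_metrics <- as.matrix(host_metrics)
  donor_metrics <- as.matrix(donor_metrics)
  if (nrow(host_metrics) < min_background ||
      nrow(donor_metrics) < min_background) {
    stop("background sets must each contain at least ", min_background,
         " genes")
  }
  metrics <- intersect(names(gene),
                       intersect(colnames(host_metrics), colnames(donor_metrics)))
  if (!length(metrics)) stop("no shared metrics between gene and backgrounds")
  zscore <- function(x, bg) {
    mu <- mean(bg, na.rm = TRUE); sdv <- stats::sd(bg, na.rm = TRUE)
    if (!is.finite(sdv) || sdv == 0) {
      list(z = abs(x - mu), fallback = TRUE)
    } else {
      list(z = (x - mu) / sdv, fallback = FALSE)
    }
  }
  rows <- lapply(metrics, function(mn) {
    zh <- zscore(gene[[mn]], host_metrics[, mn])
    zd <- zscore(gene[[mn]], donor_metrics[, mn])
    nearer <- if (abs(zh$z) < abs(zd$z)) "HOST"
              else if (abs(zd$z) < abs(zh$z)) "DONOR" else "TIE"
    data.frame(metric = mn, value = gene[[mn]],
               z_host = zh$z, z_donor = zd$z,
               fallback = zh$fallback || zd$fallback,
               nearer = nearer, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  n_host <- sum(tab$nearer == "HOST"); n_donor <- sum(tab$nearer == "DONOR")
  call <- if (n_host > n_donor) "HOST"
          else if (n_donor > n_host) "DONOR" else "INCONCLUSIVE"
  structure(list(table = tab, call = call), class = "amelioration_report")
}

#' @export
print.amelioration_report <- function(x, ...) {
  cat("amelioration report: nearest background =", x$call, "\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
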