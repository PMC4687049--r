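# Nei-Gojobori (1986) pairwise Ka/Ks: synonymous/nonsynonymous site
# counting with equal-path averaging over substitution pathways for codons
# differing at more than one position, and Jukes-Cantor multiple-hit
# correction d = -3/4 ln(1 - 4p/3). Changes that create a stop codon are
# counted as nonsynonymous in site counting; pathways are averaged with
# equal weight.

# synonymous site count of one codon: sum over positions of
# (synonymous one-step changes at that position) / 3
.ng86_syn_sites <- function(codon) {
  aa <- GENETIC_CODE_1[[codon]]
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(CODON_BASES, substring(codon, pos, pos))) {
      mut <- codon
      substring(mut, pos, pos) <- b
      if (GENETIC_CODE_1[[mut]] != "*" && GENETIC_CODE_1[[mut]] == aa) {
        s <- s + 1 / 3
      }
    }
  }
  s
}

# synonymous/nonsynonymous difference counts between two codons, averaged
# with equal weight over all substitution orderings
.ng86_diffs <- function(c1, c2) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  step <- function(a, b) {
    aa1 <- GENETIC_CODE_1[[a]]; aa2 <- GENETIC_CODE_1[[b]]
    if (aa1 != "*" && aa1 == aa2) c(1, 0) else c(0, 1)
  }
  paths <- if (length(pos) == 1L) list(pos) else
    lapply(asplit(.permutations(pos), 1), as.integer)
  acc <- c(0, 0)
  for (p in paths) {
    cur <- c1
    contrib <- c(0, 0)
    for (k in p) {
      nxt <- cur
      substring(nxt, k, k) <- substring(c2, k, k)
      contrib <- contrib + step(cur, nxt)
      cur <- nxt
    }
    acc <- acc + contrib
  }
  acc <- acc / length(paths)
  c(sd = acc[1], nd = acc[2])
}

.permutations <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x)) {
    rest <- .permutations(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Pairwise Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Sites S and N are averaged between the two sequences; proportions
#' pS = Sd/S and pN = Nd/N are Jukes-Cantor corrected to dS (Ks) and dN
#' (Ka). The ratio omega = Ka/Ks is `NA` when Ks is 0 or its correction is
#' undefined (p >= 3/4, reported via `saturated`).
#'
#' @param cds1,cds2 aligned coding sequences of equal length (no gaps;
#'   terminal stops trimmed)
#' @return object of class `selection_result`: list with `Ka`, `Ks`,
#'   `omega`, `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `saturated`, `model`
#' @export
ng86 <- function(cds1, cds2) {
  co1 <- validate_cds(cds1, "cds1")
  co2 <- validate_cds(cds2, "cds2")
  if (length(co1) != length(co2)) stop("sequences differ in codon length")
  if (!length(co1)) stop("empty alignment")
  S <- (sum(vapply(co1, .ng86_syn_sites, numeric(1))) +
          sum(vapply(co2, .ng86_syn_sites, numeric(1)))) / 2
  N <- 3 * length(co1) - S
  diffs <- mapply(function(a, b) .ng86_diffs(a, b), co1, co2)
  Sd <- sum(diffs["sd", ]); Nd <- sum(diffs["nd", ])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  jc <- function(p) {
    if (is.na(p)) return(NA_real_)
    if (p >= 3 / 4) return(NA_real_)
    -3 / 4 * log(1 - 4 * p / 3)
  }
  Ks <- jc(pS); Ka <- jc(pN)
  saturated <- (!is.na(pS) && pS >= 3 / 4) || (!is.na(pN) && pN >= 3 / 4)
  omega <- if (!is.na(Ks) && Ks > 0 && !is.na(Ka)) Ka / Ks else NA_real_
  structure(list(Ka = Ka, Ks = Ks, omega = omega, S = S, N = N,
                 Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 saturated = saturated, model = "NG86"),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(x$model, "selection result\n")
  if (!is.null(x$Ka)) {
    cat(sprintf("  Ka = %s  Ks = %s  omega = %s\n",
                format(x$Ka, digits = 5), format(x$Ks, digits = 5),
                format(x$omega, digits = 5)))
  }
  if (!is.null(x$lnL)) {
    cat(sprintf("  lnL = %.4f  kappa = %.4f  omega = %.5f\n",
                x$lnL, x$kappa, x$omega))
  }
  invisible(x)
}

#' Likelihood ratio test for nested codon models
#'
#' Statistic 2 * (lnL_alt - lnL_null) against the upper tail of a
#' chi-square distribution with `df` degrees of freedom.
#'
#' @param lnL_null,lnL_alt maximized log-likelihoods of the nested and the
#'   richer model
#' @param df degrees of freedom (difference in parameter count)
#' @param tol tolerance for a slightly negative statistic from numerical
#'   optimization (default 1e-6)
#' @return list with `statistic`, `df`, `p_value`
#' @export
lrt <- function(lnL_null, lnL_alt, df, tol = 1e-6) {
  stat <- 2 * (lnL_alt - lnL_null)
  if (stat < -tol) {
    stop("alternative model has lower likelihood than the null ",
         "(2*delta = ", format(stat), "); models are not nested or the ",
         "optimization failed")
  }
  stat <- max(stat, 0)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE))
}
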