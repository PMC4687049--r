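# RPKM quantification and developmental-stage expression profiling.

#' RPKM from a count table
#'
#' RPKM(g, s) = 1e9 * C(g, s) / (N(s) * L(g)) with C the mapped-read count,
#' N the sample's total mapped reads and L the gene's exon-model length in
#' nucleotides.
#'
#' @param counts numeric matrix, genes x samples (integer read counts)
#' @param lengths named numeric vector of exon-model lengths (nt) covering
#'   all genes
#' @param totals named numeric vector of per-sample mapped-read totals
#' @return numeric matrix of RPKM values, same dimnames as `counts`
#' @export
rpkm <- function(counts, lengths, totals) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must have gene and sample names")
  }
  if (any(counts < 0)) stop("negative read counts")
  L <- lengths[rownames(counts)]
  N <- totals[colnames(counts)]
  if (anyNA(L)) stop("missing exon-model length for gene(s): ",
                     paste(utils::head(rownames(counts)[is.na(L)], 5),
                           collapse = ", "))
  if (anyNA(N)) stop("missing mapped-read total for sample(s): ",
                     paste(utils::head(colnames(counts)[is.na(N)], 5),
                           collapse = ", "))
  if (any(L <= 0)) stop("non-positive exon-model length for gene(s): ",
                        paste(rownames(counts)[L <= 0], collapse = ", "))
  if (any(N <= 0)) stop("non-positive mapped-read total for sample(s): ",
                        paste(colnames(counts)[N <= 0], collapse = ", "))
  1e9 * sweep(sweep(counts, 2, N, "/"), 1, L, "/")
}

#' Exon-model lengths from gene models
#'
#' Union length of the exon intervals of each model, in nucleotides.
#'
#' @param models named list of `gene_model`s (see [gene_model()])
#' @return named numeric vector of lengths
#' @export
exon_model_lengths <- function(models) {
  vapply(models, function(m) sum(m$exons[, 2] - m$exons[, 1] + 1),
         numeric(1))
}

#' Developmental-stage expression profile of one gene
#'
#' Orders the gene's RPKM values along the supplied stage sequence, flags
#' each stage as expressed when RPKM meets `expressed_min`, and reports
#' whether the profile is non-decreasing over a designated stage window.
#'
#' @param rpkm_table RPKM matrix from [rpkm()]
#' @param gene_id gene to profile
#' @param stages character vector of sample names in developmental order
#' @param expressed_min expression threshold on the RPKM scale (default 1)
#' @param monotone_window optional character vector (subset of `stages`, in
#'   order) over which monotone increase is assessed; default is all stages
#' @return object of class `stage_profile`: list with `gene_id`, `stages`,
#'   `rpkm`, `expressed`, `monotone_window`, `monotone_increasing`
#' @export
stage_profile <- function(rpkm_table, gene_id, stages, expressed_min = 1,
                          monotone_window = stages) {
  if (!gene_id %in% rownames(rpkm_table)) {
    stop("gene '", gene_id, "' not in RPKM table")
  }
  missing <- setdiff(stages, colnames(rpkm_table))
  if (length(missing)) {
    stop("stage(s) missing from RPKM table: ", paste(missing, collapse = ", "))
  }
  vals <- rpkm_table[gene_id, stages]
  win <- rpkm_table[gene_id, monotone_window]
  structure(list(gene_id = gene_id, stages = stages,
                 rpkm = stats::setNames(as.numeric(vals), stages),
                 expressed = stats::setNames(as.numeric(vals) >= expressed_min,
                                             stages),
                 monotone_window = monotone_window,
                 monotone_increasing = !is.unsorted(as.numeric(win))),
            class = "stage_profile")
}

#' @export
print.stage_profile <- function(x, ...) {
  cat("stage profile for", x$gene_id, "\n")
  print(round(x$rpkm, 3))
  cat("expressed:", paste(x$stages[x$expressed], collapse = ", "), "\n")
  invisible(x)
}
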