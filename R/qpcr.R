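# Relative qPCR expression (Livak 2^-ddCt) and RNA-seq concordance.

#' Relative expression by the 2^(-ddCt) method
#'
#' For each gene: `dCt = Ct_target - Ct_reference` per reaction, replicates are
#' averaged at the dCt level within the experimental and control groups,
#' `ddCt = mean dCt(experimental) - mean dCt(control)`, and
#' `fold = 2^(-ddCt)`.
#'
#' Note on the exponent sign: the method is universally written 2^(-ddCt)
#' (fold > 1 when the target amplifies earlier, i.e. is up-regulated, in the
#' experimental group); sources occasionally print 2^(ddCt) by typo. This
#' implementation uses the negative-exponent convention, so
#' `log2(fold) == -ddCt` exactly.
#'
#' @param records Data.frame with columns `sample`, `group` (`"experimental"`
#'   or `"control"`), `gene`, `ct_target`, `ct_reference`; Ct values must lie
#'   in (0, 50). Each gene needs at least one record per group.
#' @return Data.frame `gene, ddct, fold, log2_fold`, one row per gene, sorted
#'   by gene id.
#' @examples
#' ct <- data.frame(sample = c("e1", "c1"),
#'                  group = c("experimental", "control"),
#'                  gene = "g1", ct_target = c(20, 22), ct_reference = 18)
#' relative_expression(ct) # ddct -2, fold 4
#' @export
relative_expression <- function(records) {
  need <- c("sample", "group", "gene", "ct_target", "ct_reference")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("Ct records must have columns: ", paste(need, collapse = ", "))
  bad <- setdiff(unique(records$group), c("experimental", "control"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  ct <- c(records$ct_target, records$ct_reference)
  if (any(!is.finite(ct)) || any(ct <= 0) || any(ct >= 50))
    stop("Ct values must lie in (0, 50)")
  records$dct <- records$ct_target - records$ct_reference
  genes <- sort(unique(as.character(records$gene)))
  res <- lapply(genes, function(g) {
    r <- records[records$gene == g, ]
    exp_d <- r$dct[r$group == "experimental"]
    ctl_d <- r$dct[r$group == "control"]
    if (length(exp_d) == 0 || length(ctl_d) == 0)
      stop("gene '", g, "' lacks an experimental or control group")
    ddct <- mean(exp_d) - mean(ctl_d)
    data.frame(gene = g, ddct = ddct, fold = 2^(-ddct), log2_fold = -ddct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' qPCR / RNA-seq concordance (R squared)
#'
#' Squared Pearson correlation between per-gene log2 fold changes measured by
#' qPCR and by RNA-seq, over the genes present in both. Invariant under affine
#' rescaling of either axis and symmetric in its arguments.
#'
#' @param qpcr_log2fc Named numeric vector of qPCR log2 fold changes.
#' @param rnaseq_log2fc Named numeric vector of RNA-seq log2 fold changes.
#' @return List with `r_squared` and `n_genes` (shared genes, >= 3 required).
#' @examples
#' x <- c(g1 = 1, g2 = -2, g3 = 0.5)
#' concordance(x, 2 * x + 1)$r_squared # 1
#' @export
concordance <- function(qpcr_log2fc, rnaseq_log2fc) {
  if (is.null(names(qpcr_log2fc)) || is.null(names(rnaseq_log2fc)))
    stop("log2FC vectors must be named by gene id")
  shared <- intersect(names(qpcr_log2fc), names(rnaseq_log2fc))
  if (length(shared) < 3)
    stop("concordance requires >= 3 shared genes (got ", length(shared), ")")
  r <- cor(qpcr_log2fc[shared], rnaseq_log2fc[shared])
  list(r_squared = r^2, n_genes = length(shared))
}
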