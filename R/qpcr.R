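#' Relative gene expression by the 2^-ddCt (Livak) method
#'
#' For each biological sample and gene of interest, the Ct is normalized to
#' the reference gene's Ct from the same sample (dCt = Ct_gene - Ct_ref).
#' Each dCt is then normalized to the mean dCt of the untreated samples of
#' that gene (ddCt = dCt - mean dCt_untreated) and the fold change is
#' 2^-ddCt. Technical replicate Cts, if several rows share a
#' (sample, gene), are averaged before dCt so there is one dCt per biological
#' sample. If a batch column is supplied and present, the untreated
#' normalization is performed within each batch (e.g. per independent
#' experiment); otherwise all untreated samples are pooled.
#'
#' @param ct_table data frame with columns `sample`, `gene`, `condition`,
#'   `ct` (cycles), optionally a batch column.
#' @param reference_gene reference (housekeeping) gene id; default `"ACTB"`
#'   (beta-actin).
#' @param untreated_label `condition` value marking the untreated baseline
#'   group.
#' @param batch_col name of the batch column (default `"experiment"`); ignored
#'   when absent. Set NULL to pool across batches explicitly.
#' @return Data frame with one row per (sample, gene of interest):
#'   sample, gene, condition, (batch,) ct, delta_ct, delta_delta_ct,
#'   fold_change.
#' @export
relative_expression <- function(ct_table, reference_gene = "ACTB",
                                untreated_label = "untreated",
                                batch_col = "experiment") {
  need <- c("sample", "gene", "condition", "ct")
  miss <- setdiff(need, names(ct_table))
  if (length(miss)) stop("ct_table missing column(s): ", paste(miss, collapse = ", "))
  if (!all(is.finite(ct_table$ct))) stop("non-finite Ct values")
  has_batch <- !is.null(batch_col) && batch_col %in% names(ct_table)
  ct_table$..batch <- if (has_batch) as.character(ct_table[[batch_col]]) else "all"

  # average technical replicates: one Ct per (batch, sample, gene)
  avg <- aggregate(ct ~ ..batch + sample + gene + condition, ct_table, mean)

  ref <- avg[avg$gene == reference_gene, ]
  goi <- avg[avg$gene != reference_gene, ]
  if (nrow(goi) == 0L) stop("no genes of interest besides the reference gene")
  key <- function(df) paste(df$..batch, df$sample)
  ref_ct <- setNames(ref$ct, key(ref))
  missing_ref <- setdiff(unique(key(goi)), names(ref_ct))
  if (length(missing_ref))
    stop("missing reference-gene Ct for sample(s): ",
         paste(sub("^\\S+ ", "", missing_ref), collapse = ", "))
  goi$delta_ct <- goi$ct - ref_ct[key(goi)]

  out <- list()
  for (b in unique(goi$..batch)) {
    gb <- goi[goi$..batch == b, ]
    for (g in unique(gb$gene)) {
      gg <- gb[gb$gene == g, ]
      base <- gg$delta_ct[gg$condition == untreated_label]
      if (length(base) == 0L)
        stop(sprintf("gene %s has no untreated samples%s", g,
                     if (has_batch) sprintf(" in batch %s", b) else ""))
      gg$delta_delta_ct <- gg$delta_ct - mean(base)
      gg$fold_change <- 2^(-gg$delta_delta_ct)
      out[[length(out) + 1L]] <- gg
    }
  }
  res <- do.call(rbind, out)
  if (has_batch) names(res)[names(res) == "..batch"] <- batch_col
  else res$..batch <- NULL
  rownames(res) <- NULL
  res
}
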