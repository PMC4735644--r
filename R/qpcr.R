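# Relative quantification by the delta-delta-Ct method, normalized to a
# reference (housekeeping) gene and expressed relative to the control
# group. Amplification efficiency is taken as 2 (one cycle = twofold).

#' Fold changes by the delta-delta-Ct method
#'
#' Technical replicates (duplicate rows for the same sample and gene)
#' are averaged to a mean Ct first. Per sample,
#' `dCt = Ct_target - Ct_reference`; per gene,
#' `ddCt = dCt - mean(dCt over control samples)`; the fold change is
#' `2^(-ddCt)`. Group means and standard errors are computed over the
#' per-sample fold changes, so the control group averages to ~1 by
#' construction.
#'
#' @param table long-format data.frame with columns `sample_id`,
#'   `group`, `gene`, `ct`.
#' @param reference_gene housekeeping gene used for dCt normalization
#'   (default "CASQ2", calsequestrin).
#' @param control_group group the fold changes are expressed against;
#'   defaults to the first group in the table.
#' @return a `fold_change_result`: list with `per_sample` (data.frame
#'   `sample_id`, `group`, `gene`, `dct`, `ddct`, `fold`) and `summary`
#'   (data.frame `group`, `gene`, `mean_fold`, `sem`, `n`). Samples
#'   lacking a reference-gene Ct are dropped with a warning; an empty
#'   control group is an error.
#' @export
delta_delta_ct <- function(table, reference_gene = "CASQ2",
                           control_group = NULL) {
  req <- c("sample_id", "group", "gene", "ct")
  if (!all(req %in% names(table)))
    stop("`table` needs columns sample_id, group, gene, ct")
  if (!reference_gene %in% table$gene)
    stop(sprintf("reference gene '%s' absent from the table", reference_gene))
  if (is.null(control_group)) control_group <- as.character(table$group[1])
  if (!control_group %in% table$group)
    stop(sprintf("control group '%s' absent from the table", control_group))

  # mean Ct over technical replicates
  agg <- stats::aggregate(ct ~ sample_id + group + gene, data = table,
                          FUN = mean)

  ref <- agg[agg$gene == reference_gene, c("sample_id", "ct")]
  names(ref)[2] <- "ct_ref"
  tgt <- agg[agg$gene != reference_gene, , drop = FALSE]
  no_ref <- setdiff(unique(tgt$sample_id), ref$sample_id)
  if (length(no_ref)) {
    warning(sprintf("dropping %d sample(s) without a reference-gene Ct: %s",
                    length(no_ref), paste(no_ref, collapse = ", ")))
    tgt <- tgt[!tgt$sample_id %in% no_ref, , drop = FALSE]
  }
  tgt <- merge(tgt, ref, by = "sample_id")
  tgt$dct <- tgt$ct - tgt$ct_ref

  if (!any(tgt$group == control_group))
    stop("control group has no usable samples")

  per_gene <- split(tgt, tgt$gene)
  out <- lapply(per_gene, function(df) {
    ctrl <- df$dct[df$group == control_group]
    if (!length(ctrl)) stop("control group has no usable samples")
    df$ddct <- df$dct - mean(ctrl)
    df$fold <- 2^(-df$ddct)
    df
  })
  per_sample <- do.call(rbind, out)
  rownames(per_sample) <- NULL
  per_sample <- per_sample[, c("sample_id", "group", "gene",
                               "dct", "ddct", "fold")]

  sum_rows <- list()
  for (gene in unique(per_sample$gene)) {
    for (g in unique(per_sample$group)) {
      x <- per_sample$fold[per_sample$gene == gene & per_sample$group == g]
      sum_rows[[length(sum_rows) + 1L]] <- data.frame(
        group = g, gene = gene, mean_fold = mean(x), sem = sem(x),
        n = length(x))
    }
  }
  structure(list(per_sample = per_sample,
                 summary = do.call(rbind, sum_rows),
                 reference_gene = reference_gene,
                 control_group = control_group),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("<fold_change_result> reference %s, control group %s\n",
              x$reference_gene, x$control_group))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
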