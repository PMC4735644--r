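# Synthetic upstroke-velocity cohorts and qPCR Ct tables.

#' Generate a cohort of maximal upstroke velocities with planted outliers
#'
#' Draws `n_normal` values from a normal distribution and appends the
#' given outlier values, recording which entries were planted. Used to
#' validate the Tukey-fence rapid-depolarizer classifier. Defaults follow
#' the reported group means of 24 mV/ms for ventricular-like cells and
#' 88 mV/ms for rapid depolarizers.
#'
#' @param n_normal number of background cells (>= 4 for stable quartiles).
#' @param normal_mean,normal_sd mean and sd of the background
#'   distribution (mV/ms).
#' @param outlier_values numeric vector of planted rapid-depolarizer
#'   values (mV/ms); may be empty.
#' @param seed integer seed.
#' @return list with `cohort` (data.frame `cell_id`, `dvdt_max`,
#'   `planted_outlier`) and `truth` (planted flags and parameters).
#' @export
gen_cohort <- function(n_normal, normal_mean = 24, normal_sd = 3,
                       outlier_values = numeric(), seed = 1) {
  if (n_normal < 4) stop("`n_normal` must be at least 4")
  with_seed(seed, {
    vals <- stats::rnorm(n_normal, normal_mean, normal_sd)
    all_vals <- c(vals, outlier_values)
    planted <- c(rep(FALSE, n_normal), rep(TRUE, length(outlier_values)))
    cohort <- data.frame(
      cell_id = sprintf("cell%03d", seq_along(all_vals)),
      dvdt_max = all_vals,
      planted_outlier = planted
    )
    truth <- structure(list(seed = seed, planted = planted,
                            n_normal = n_normal,
                            normal_mean = normal_mean, normal_sd = normal_sd,
                            outlier_values = outlier_values),
                       class = "ground_truth")
    list(cohort = cohort, truth = truth)
  })
}

#' Generate a qPCR Ct table with known fold changes
#'
#' Ct values follow `Ct = baseline_gene + sample_offset - log2(fold) +
#' noise`, so the delta-delta-Ct method recovers `fold` exactly at zero
#' noise. The reference gene has fold 1 in every group; per-sample
#' offsets emulate global pipetting/loading differences that delta-Ct
#' normalization must remove.
#'
#' @param genes character vector of target gene names (the reference gene
#'   is added automatically if absent).
#' @param groups character vector of group names; the first is the
#'   control unless `control_group` is given.
#' @param true_fold_changes matrix of fold changes (genes x groups), or a
#'   single number applied to all non-control groups; control-group and
#'   reference-gene folds are forced to 1.
#' @param reference_gene housekeeping gene name (default "CASQ2",
#'   calsequestrin).
#' @param control_group name of the control group.
#' @param n_replicates biological replicates per group.
#' @param ct_noise_sd Gaussian noise on each Ct (cycles).
#' @param sample_offset_sd sd of the per-sample global Ct offset (cycles).
#' @param baseline_ct named vector of per-gene baseline Ct values;
#'   defaults to 20 cycles for every gene.
#' @param seed integer seed.
#' @return list with `table` (long data.frame `sample_id`, `group`,
#'   `gene`, `ct`) and `truth` (the fold-change matrix used).
#' @export
gen_ct_table <- function(genes, groups, true_fold_changes = 1,
                         reference_gene = "CASQ2",
                         control_group = groups[1], n_replicates = 3,
                         ct_noise_sd = 0, sample_offset_sd = 0,
                         baseline_ct = NULL, seed = 1) {
  genes <- union(genes, reference_gene)
  if (!control_group %in% groups) stop("`control_group` must be one of `groups`")
  if (is.matrix(true_fold_changes)) {
    fold <- true_fold_changes
    if (is.null(rownames(fold)) || is.null(colnames(fold)))
      stop("fold-change matrix needs gene rownames and group colnames")
    missing_g <- setdiff(genes, rownames(fold))
    if (length(missing_g)) {
      add <- matrix(1, length(missing_g), ncol(fold),
                    dimnames = list(missing_g, colnames(fold)))
      fold <- rbind(fold, add)
    }
    fold <- fold[genes, groups, drop = FALSE]
  } else {
    fold <- matrix(true_fold_changes, length(genes), length(groups),
                   dimnames = list(genes, groups))
  }
  fold[reference_gene, ] <- 1
  fold[, control_group] <- 1
  if (is.null(baseline_ct)) baseline_ct <- stats::setNames(
    rep(20, length(genes)), genes)

  with_seed(seed, {
    rows <- list()
    for (g in groups) {
      for (r in seq_len(n_replicates)) {
        sid <- sprintf("%s_rep%d", g, r)
        offset <- if (sample_offset_sd > 0)
          stats::rnorm(1, sd = sample_offset_sd) else 0
        for (gene in genes) {
          ct <- baseline_ct[[gene]] + offset - log2(fold[gene, g])
          if (ct_noise_sd > 0) ct <- ct + stats::rnorm(1, sd = ct_noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample_id = sid, group = g, gene = gene, ct = ct)
        }
      }
    }
    table <- do.call(rbind, rows)
    rownames(table) <- NULL
    truth <- structure(list(seed = seed, fold = fold,
                            reference_gene = reference_gene,
                            control_group = control_group),
                       class = "ground_truth")
    list(table = table, truth = truth)
  })
}
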