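#' Relative expression by the 2^-ddCt method
#'
#' Computes, per biological replicate: technical replicates averaged at the
#' Ct level; \eqn{\Delta Ct = Ct_{gene} - Ct_{ref}} within each sample;
#' \eqn{\Delta\Delta Ct} against the matching control-condition replicate;
#' and the fold change \eqn{2^{-\Delta\Delta Ct}}.
#'
#' @param ct_table Data frame with `sample`, `condition`, `gene`, `ct`, and
#'   a `replicate` column pairing conditions across biological replicates
#'   (derived from sample order within condition when absent).
#' @param reference_gene Housekeeping gene used for within-sample
#'   normalization.
#' @param control_condition Condition serving as the ddCt baseline.
#' @return Object of class `relative_expression`: a data frame with `gene`,
#'   `condition`, `replicate`, `delta_ct`, `delta_delta_ct`, `fold`.
#' @export
ddct <- function(ct_table, reference_gene, control_condition) {
  need <- c("sample", "condition", "gene", "ct")
  if (!all(need %in% names(ct_table))) {
    stop("ct_table must have columns: ", paste(need, collapse = ", "))
  }
  if (!reference_gene %in% ct_table$gene) {
    stop("reference gene '", reference_gene, "' not present")
  }
  if (!control_condition %in% ct_table$condition) {
    stop("control condition '", control_condition, "' not present")
  }
  if (is.null(ct_table$replicate)) {
    ct_table$replicate <- stats::ave(
      seq_len(nrow(ct_table)), ct_table$condition,
      FUN = function(i) match(ct_table$sample[i], unique(ct_table$sample[i])))
  }
  # average technical replicates
  agg <- stats::aggregate(
    list(ct = ct_table$ct),
    by = list(condition = ct_table$condition, replicate = ct_table$replicate,
              gene = ct_table$gene),
    FUN = mean)
  ref <- agg[agg$gene == reference_gene,
             c("condition", "replicate", "ct")]
  names(ref)[3] <- "ct_ref"
  d <- merge(agg, ref, by = c("condition", "replicate"))
  if (nrow(d) < nrow(agg)) {
    stop("reference gene missing from some biological replicate")
  }
  d$delta_ct <- d$ct - d$ct_ref
  ctrl <- d[d$condition == control_condition,
            c("replicate", "gene", "delta_ct")]
  names(ctrl)[3] <- "delta_ct_control"
  d <- merge(d, ctrl, by = c("replicate", "gene"))
  d$delta_delta_ct <- d$delta_ct - d$delta_ct_control
  d$fold <- 2^(-d$delta_delta_ct)
  d <- d[order(d$gene, d$condition, d$replicate),
         c("gene", "condition", "replicate", "delta_ct",
           "delta_delta_ct", "fold")]
  rownames(d) <- NULL
  structure(d, class = c("relative_expression", "data.frame"),
            reference_gene = reference_gene,
            control_condition = control_condition)
}

#' Standardize fold changes across biological replicates
#'
#' Replicate standardization for inherently variable biological material:
#' within each biological replicate, fold changes are log-transformed
#' (natural log; the base cancels), mean-centered and autoscaled (divided
#' by the replicate SD).  Per gene x condition the function reports the
#' mean standardized value with a Student-t 95% confidence interval
#' (n_bio - 1 df), alongside the back-transformed geometric mean fold and
#' its t-based 95% CI on the log scale.
#'
#' @param rel A [ddct()] result (or a data frame with `gene`, `condition`,
#'   `replicate`, `fold`).
#' @param conf_level Confidence level for the intervals.
#' @param exclude_reference Drop the reference gene before standardizing
#'   (it carries no information; default `TRUE` when the attribute is
#'   available).
#' @return Data frame per gene x condition: `mean_std`, `ci_low_std`,
#'   `ci_high_std` (standardized scale), `fold_geomean`, `fold_ci_low`,
#'   `fold_ci_high` (fold scale), `n_replicates`.
#' @export
standardize_replicates <- function(rel, conf_level = 0.95,
                                   exclude_reference = TRUE) {
  d <- as.data.frame(rel)
  refg <- attr(rel, "reference_gene")
  if (exclude_reference && !is.null(refg)) d <- d[d$gene != refg, , drop = FALSE]
  reps <- unique(d$replicate)
  if (length(reps) < 2) stop("need at least 2 biological replicates")
  d$logf <- log(d$fold)
  d$std <- stats::ave(d$logf, d$replicate, FUN = function(v) {
    s <- stats::sd(v)
    if (s == 0) stop("replicate has zero variance across genes/conditions; ",
                     "cannot autoscale")
    (v - mean(v)) / s
  })
  alpha <- 1 - conf_level
  out <- do.call(rbind, lapply(
    split(d, list(d$gene, d$condition), drop = TRUE), function(g) {
      n <- nrow(g)
      tq <- stats::qt(1 - alpha / 2, df = n - 1)
      m_std <- mean(g$std); se_std <- stats::sd(g$std) / sqrt(n)
      m_log <- mean(g$logf); se_log <- stats::sd(g$logf) / sqrt(n)
      data.frame(gene = g$gene[1], condition = g$condition[1],
                 n_replicates = n,
                 mean_std = m_std,
                 ci_low_std = m_std - tq * se_std,
                 ci_high_std = m_std + tq * se_std,
                 fold_geomean = exp(m_log),
                 fold_ci_low = exp(m_log - tq * se_log),
                 fold_ci_high = exp(m_log + tq * se_log))
    }))
  rownames(out) <- NULL
  out[order(out$gene, out$condition), , drop = FALSE]
}

#' Per-cell count knockdown between two conditions
#'
#' Percent change of the mean per-cell count (control vs shRNA) with a
#' Welch two-tailed t-test.  Also applicable to per-cell colocalized-pair
#' counts to quantify knockdown of physically associated transcripts.
#'
#' @param counts_control,counts_treated Numeric vectors of per-cell counts.
#' @return List: `pct_reduction` (positive = loss under treatment),
#'   `mean_control`, `mean_treated`, `t`, `p`.
#' @export
count_knockdown <- function(counts_control, counts_treated) {
  if (!length(counts_control) || !length(counts_treated)) {
    stop("both conditions need at least one cell")
  }
  mc <- mean(counts_control); mt <- mean(counts_treated)
  ht <- tryCatch(stats::t.test(counts_control, counts_treated),
                 error = function(e) NULL)
  if (is.null(ht)) {  # constant data
    p <- if (isTRUE(all.equal(mc, mt))) 1 else 0
    tt <- if (p == 1) 0 else sign(mc - mt) * Inf
  } else {
    p <- ht$p.value; tt <- unname(ht$statistic)
  }
  list(pct_reduction = 100 * (1 - mt / mc),
       mean_control = mc, mean_treated = mt, t = tt, p = p)
}
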