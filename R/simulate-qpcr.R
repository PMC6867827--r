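#' Simulate an RT-qPCR Ct table with known fold changes
#'
#' Generates cycle-threshold (Ct) values for a conditions x genes design with
#' biological and technical replication.  Each sample (condition x biological
#' replicate) receives a shared loading offset (cancelled by within-sample
#' normalization to the reference gene), each sample x gene a biological
#' noise term, and each technical replicate a smaller technical noise term:
#'
#' \deqn{Ct = Ct_{base}(gene) - \log_2(fold(cond, gene)) + L_{sample}
#'   + \epsilon_{bio} + \epsilon_{tech}}
#'
#' The reference gene and all genes in the control condition have fold 1.
#'
#' @param conditions Character vector; first element is the control unless
#'   `control_condition` says otherwise.
#' @param genes Character vector of assayed genes (must include
#'   `reference_gene`).
#' @param fold_changes Named list: `fold_changes[[condition]]` is a named
#'   numeric vector of true fold changes vs control per gene (unlisted genes
#'   default to 1).
#' @param reference_gene Housekeeping gene, e.g. beta-actin.
#' @param control_condition Condition used as the ddCt baseline.
#' @param ct_reference Baseline Ct, either a single number or a named vector
#'   per gene.
#' @param n_bio Biological replicates per condition (>= 2).
#' @param n_tech Technical replicates per sample x gene.
#' @param noise_sd_ct Biological Ct noise SD (per sample x gene).
#' @param tech_sd_ct Technical Ct noise SD (per well).
#' @param sample_effect_sd SD of the per-sample loading offset.
#' @param seed Integer seed.
#'
#' @return Data frame (`ct_table`): `sample`, `condition`, `replicate`,
#'   `gene`, `tech_rep`, `ct`, with the true fold changes in
#'   `attr(, "true_folds")`.
#' @export
simulate_qpcr <- function(conditions = c("scrambled", "shRNA_hERG1a"),
                          genes = c("hERG1a", "hERG1b", "SCN5A", "RYR2", "ACTB"),
                          fold_changes = list(),
                          reference_gene = "ACTB",
                          control_condition = conditions[1],
                          ct_reference = 22,
                          n_bio = 6L,
                          n_tech = 3L,
                          noise_sd_ct = 0.2,
                          tech_sd_ct = 0.1,
                          sample_effect_sd = 0.5,
                          seed = 1L) {
  if (!reference_gene %in% genes) {
    stop("reference gene '", reference_gene, "' missing from 'genes'")
  }
  if (!control_condition %in% conditions) {
    stop("control condition '", control_condition, "' missing from 'conditions'")
  }
  if (n_bio < 2L) stop("'n_bio' must be at least 2")
  ct_base <- if (length(ct_reference) == 1L) {
    stats::setNames(rep(ct_reference, length(genes)), genes)
  } else {
    if (!all(genes %in% names(ct_reference))) {
      stop("'ct_reference' must name every gene")
    }
    ct_reference[genes]
  }

  fold_of <- function(cond, gene) {
    if (cond == control_condition || gene == reference_gene) return(1)
    fc <- fold_changes[[cond]]
    if (is.null(fc) || is.na(fc[gene]) || is.null(fc[gene][[1]])) 1 else unname(fc[gene])
  }

  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (cond in conditions) {
      for (b in seq_len(n_bio)) {
        loading <- stats::rnorm(1, 0, sample_effect_sd)
        for (g in genes) {
          mu <- ct_base[[g]] - log2(fold_of(cond, g)) + loading +
            stats::rnorm(1, 0, noise_sd_ct)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = sprintf("%s_b%d", cond, b),
            condition = cond, replicate = b, gene = g,
            tech_rep = seq_len(n_tech),
            ct = mu + stats::rnorm(n_tech, 0, tech_sd_ct),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    tab <- do.call(rbind, rows)
    true <- expand.grid(condition = conditions, gene = genes,
                        stringsAsFactors = FALSE)
    true$fold <- mapply(fold_of, true$condition, true$gene)
    attr(tab, "true_folds") <- true
    tab
  })
}
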