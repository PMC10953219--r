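#' Relative expression by the comparative Ct (2^-ddCt) method
#'
#' Ct values are averaged over replicates per (gene, condition); `dCt =
#' mean Ct_target - mean Ct_ref`; `ddCt = dCt_treatment - dCt_control`;
#' `FC = 2^-ddCt`. Direction is `up` for FC > 1, `down` for FC < 1,
#' `unchanged` only at FC = 1 exactly. Welch's two-sample t-test on
#' per-replicate dCt (treatment vs control) provides the per-cell p-value
#' with marks `**` (< 0.01), `*` (< 0.05), `ns`; a Benjamini-Hochberg
#' column is added but not used for the marks. The amplification
#' efficiency is fixed at 2 (Livak assumption).
#'
#' @param ct_table data.frame with columns `gene`, `condition`,
#'   `is_control` (logical, one control condition), `replicate`, `ct`;
#'   optional grouping columns are ignored.
#' @param ref_gene id of the reference gene (must be measured in every
#'   condition).
#' @return data.frame per (target gene, condition): `gene`, `condition`,
#'   `delta_ct`, `delta_delta_ct`, `fold_change`, `direction`, `p_value`,
#'   `p_adj`, `mark`.
#' @export
delta_delta_ct <- function(ct_table, ref_gene) {
  need <- c("gene", "condition", "is_control", "replicate", "ct")
  if (!all(need %in% names(ct_table))) {
    stop("ct table needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (!ref_gene %in% ct_table$gene) {
    stop("reference gene '", ref_gene, "' absent from table", call. = FALSE)
  }
  conds <- unique(ct_table$condition)
  control <- unique(ct_table$condition[ct_table$is_control])
  if (length(control) != 1) {
    stop("exactly one control condition must be flagged", call. = FALSE)
  }
  ref <- ct_table[ct_table$gene == ref_gene, , drop = FALSE]
  missing_ref <- setdiff(conds, unique(ref$condition))
  if (length(missing_ref) > 0) {
    stop("reference gene not measured in condition(s): ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  ref_mean <- tapply(ref$ct, ref$condition, mean)
  targets <- setdiff(unique(ct_table$gene), ref_gene)
  rows <- list()
  for (g in c(targets, ref_gene)) {
    sub <- ct_table[ct_table$gene == g, , drop = FALSE]
    tmean <- tapply(sub$ct, sub$condition, mean)
    dct <- tmean - ref_mean[names(tmean)]
    if (!control %in% names(dct)) {
      stop(sprintf("gene '%s' not measured in control condition", g), call. = FALSE)
    }
    # per-replicate dCt for the Welch test: pair replicates by index
    rep_dct <- function(cond) {
      tg <- sub[sub$condition == cond, , drop = FALSE]
      rf <- ref[ref$condition == cond, , drop = FALSE]
      tg <- tg[order(tg$replicate), , drop = FALSE]
      rf <- rf[order(rf$replicate), , drop = FALSE]
      k <- min(nrow(tg), nrow(rf))
      tg$ct[seq_len(k)] - rf$ct[seq_len(k)]
    }
    d0 <- rep_dct(control)
    for (cond in names(dct)) {
      ddct <- unname(dct[cond] - dct[control])
      fc <- 2^(-ddct)
      p <- NA_real_
      if (cond != control) {
        d1 <- rep_dct(cond)
        if (length(d0) >= 2 && length(d1) >= 2) {
          p <- if (stats::sd(c(d0, d1)) == 0) 1 else {
            tryCatch(t.test(d1, d0)$p.value, error = function(e) NA_real_)
          }
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        gene = g, condition = cond,
        delta_ct = unname(dct[cond]), delta_delta_ct = ddct,
        fold_change = fc,
        direction = if (fc > 1) "up" else if (fc < 1) "down" else "unchanged",
        p_value = p, stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_value, method = "BH")
  out$mark <- ifelse(is.na(out$p_value), "na",
                     ifelse(out$p_value < 0.01, "**",
                            ifelse(out$p_value < 0.05, "*", "ns")))
  out
}

#' Welch test on per-replicate dCt for one gene and condition
#'
#' Two-sided Welch two-sample t-test of treatment vs control dCt values.
#' Fewer than 2 replicates in either group is not assessable (`NA`).
#'
#' @param ct_table as in [delta_delta_ct].
#' @param ref_gene reference gene id.
#' @param gene target gene.
#' @param condition treatment condition.
#' @return p-value (or NA).
#' @export
ddct_significance <- function(ct_table, ref_gene, gene, condition) {
  control <- unique(ct_table$condition[ct_table$is_control])
  get_dct <- function(g, cond) {
    tg <- ct_table[ct_table$gene == g & ct_table$condition == cond, , drop = FALSE]
    rf <- ct_table[ct_table$gene == ref_gene & ct_table$condition == cond, , drop = FALSE]
    tg <- tg[order(tg$replicate), , drop = FALSE]
    rf <- rf[order(rf$replicate), , drop = FALSE]
    k <- min(nrow(tg), nrow(rf))
    tg$ct[seq_len(k)] - rf$ct[seq_len(k)]
  }
  d1 <- get_dct(gene, condition)
  d0 <- get_dct(gene, control)
  if (length(d0) < 2 || length(d1) < 2) return(NA_real_)
  if (stats::sd(c(d0, d1)) == 0) return(1)
  t.test(d1, d0)$p.value
}

#' Relative water content (percent)
#'
#' `RWC% = 100 (WF - WD) / (WS - WD)` with fresh (WF), dry (WD) and
#' turgid (WS) weights in the same units, `WS >= WF >= WD > 0`.
#'
#' @param WF,WD,WS weights.
#' @return percent in [0, 100].
#' @export
rwc <- function(WF, WD, WS) {
  if (any(WD <= 0) || any(WF < WD) || any(WS < WF)) {
    stop("need WS >= WF >= WD > 0", call. = FALSE)
  }
  if (any(WS == WD)) stop("WS = WD: RWC undefined", call. = FALSE)
  100 * (WF - WD) / (WS - WD)
}

#' Sodium/potassium concentration ratio
#' @param na_conc,k_conc concentrations (> 0).
#' @return `na_conc / k_conc`.
#' @export
na_k_ratio <- function(na_conc, k_conc) {
  if (any(k_conc <= 0) || any(na_conc <= 0)) {
    stop("concentrations must be > 0", call. = FALSE)
  }
  na_conc / k_conc
}

#' Log2 fold-change matrix with hierarchical gene grouping
#'
#' Genes are clustered on their log2(FC) profiles (Euclidean distance,
#' average linkage) and the tree is cut into `k_groups`; deterministic
#' given input order.
#'
#' @param expression_results output of [delta_delta_ct] (or any data.frame
#'   with `gene`, `condition`, `fold_change`).
#' @param k_groups number of groups (>= 1).
#' @return list with `log2fc` (genes x conditions matrix) and `groups`
#'   (named integer vector).
#' @export
heat_matrix <- function(expression_results, k_groups = 4L) {
  if (any(expression_results$fold_change <= 0)) {
    stop("fold changes must be positive", call. = FALSE)
  }
  genes <- unique(expression_results$gene)
  conds <- unique(expression_results$condition)
  m <- matrix(NA_real_, length(genes), length(conds),
              dimnames = list(genes, conds))
  for (i in seq_len(nrow(expression_results))) {
    m[expression_results$gene[i], expression_results$condition[i]] <-
      log2(expression_results$fold_change[i])
  }
  if (anyNA(m)) stop("incomplete gene x condition table", call. = FALSE)
  if (nrow(m) < 2 || k_groups >= nrow(m)) {
    groups <- setNames(rep(1L, nrow(m)), rownames(m))
    if (k_groups >= nrow(m)) groups <- setNames(seq_len(nrow(m)), rownames(m))
    return(list(log2fc = m, groups = groups))
  }
  hc <- hclust(dist(m, method = "euclidean"), method = "average")
  groups <- cutree(hc, k = k_groups)
  list(log2fc = m, groups = groups)
}
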