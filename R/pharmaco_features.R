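# Vectorized two-sided Welch t-test over matrix rows.
# Conventions: both groups constant with equal means -> t = 0, p = 1;
# both constant with unequal means -> p = 0.
.welch_rows <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(x[, idx1, drop = FALSE])
  m2 <- rowMeans(x[, idx2, drop = FALSE])
  v1 <- apply(x[, idx1, drop = FALSE], 1L, stats::var)
  v2 <- apply(x[, idx2, drop = FALSE], 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  zero <- se2 == 0
  eq <- zero & abs(m1 - m2) < .Machine$double.eps^0.5
  tstat[eq] <- 0; p[eq] <- 1
  tstat[zero & !eq] <- sign(m1 - m2)[zero & !eq] * Inf
  p[zero & !eq] <- 0
  data.frame(gene = rownames(x), log2FC = m1 - m2, t = tstat, p = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Trichotomize cell lines for one drug and metric
#'
#' Sensitive if the metric value is strictly below mean - 0.5 SD over the
#' lines assayed for the drug, resistant if strictly above mean + 0.5 SD,
#' partial otherwise (boundary values are partial). SD uses the n - 1
#' denominator; all-equal values give SD 0 and hence all-partial.
#'
#' @param response drug-response data.frame (columns cell_line, drug, and
#'   the metric).
#' @param drug drug name.
#' @param metric one of "IC50", "log10_IC50", "EC50", "log10_EC50".
#' @return named factor (levels sensitive/partial/resistant) over the
#'   assayed cell lines.
#' @export
trichotomize <- function(response, drug, metric = "log10_IC50") {
  sub <- response[response$drug == drug & is.finite(response[[metric]]), ]
  if (nrow(sub) < 3) stop("need >= 3 assayed cell lines for ", drug)
  v <- sub[[metric]]
  if (length(v) < 2) stop("SD undefined with fewer than 2 values")
  m <- mean(v); s <- stats::sd(v)
  cls <- rep("partial", length(v))
  cls[v < m - 0.5 * s] <- "sensitive"
  cls[v > m + 0.5 * s] <- "resistant"
  out <- factor(cls, levels = c("sensitive", "partial", "resistant"))
  names(out) <- sub$cell_line
  out
}

#' Resolve a final response class across sensitivity metrics
#'
#' The final class comes from a designated primary metric (log10_IC50 if
#' available, else log10_EC50, else IC50, else EC50); per-metric classes are
#' kept as diagnostics and a concordance flag records whether all available
#' metrics agree for a line.
#'
#' @param per_metric named list of per-metric class factors from
#'   [trichotomize()].
#' @return data.frame with cell_line, final, concordant, and one column per
#'   metric.
#' @export
resolve_class <- function(per_metric) {
  if (!length(per_metric)) stop("no metric classified")
  order_pref <- c("log10_IC50", "log10_EC50", "IC50", "EC50")
  avail <- intersect(order_pref, names(per_metric))
  if (!length(avail)) avail <- names(per_metric)
  primary <- avail[1L]
  lines <- unique(unlist(lapply(per_metric, names)))
  no_primary <- setdiff(lines, names(per_metric[[primary]]))
  if (length(no_primary)) {
    warning(length(no_primary), " cell line(s) lack the primary metric and are excluded")
    lines <- setdiff(lines, no_primary)
  }
  out <- data.frame(cell_line = lines, stringsAsFactors = FALSE)
  for (m in names(per_metric))
    out[[m]] <- as.character(per_metric[[m]][lines])
  out$final <- as.character(per_metric[[primary]][lines])
  known <- out[names(per_metric)]
  out$concordant <- apply(known, 1L, function(r) {
    r <- r[!is.na(r)]; length(unique(r)) == 1L
  })
  out
}

#' Classify all lines for a drug across its available metrics
#'
#' Convenience wrapper: trichotomizes every available metric, then resolves
#' the final class by the primary-metric rule.
#'
#' @inheritParams trichotomize
#' @return data.frame from [resolve_class()].
#' @export
classify_lines <- function(response, drug) {
  metrics <- intersect(c("IC50", "log10_IC50", "EC50", "log10_EC50"),
                       colnames(response))
  metrics <- metrics[vapply(metrics, function(m)
    any(is.finite(response[[m]][response$drug == drug])), logical(1))]
  per <- lapply(metrics, function(m) trichotomize(response, drug, m))
  names(per) <- metrics
  resolve_class(per)
}

#' Differential expression between sensitive and resistant lines for a drug
#'
#' Two-sided Welch t-test per gene; log2 fold change is mean(resistant) -
#' mean(sensitive) on the log2 scale; partial-response lines are excluded.
#' Genes constant and equal in both groups have p = 1 by convention.
#'
#' @param expr expression matrix (genes x cell lines).
#' @param classes data.frame from [classify_lines()] (or named vector of
#'   final classes).
#' @return data.frame (gene, log2FC, t, p), or NULL with a warning if either
#'   group has < 2 lines with expression.
#' @export
drug_de <- function(expr, classes) {
  validate_expression(expr)
  if (is.data.frame(classes)) {
    cls <- stats::setNames(classes$final, classes$cell_line)
  } else cls <- classes
  cls <- cls[names(cls) %in% colnames(expr)]
  res <- names(cls)[cls == "resistant"]
  sen <- names(cls)[cls == "sensitive"]
  if (length(res) < 2 || length(sen) < 2) {
    warning("fewer than 2 sensitive or resistant lines with expression; drug skipped")
    return(NULL)
  }
  .welch_rows(expr, match(res, colnames(expr)), match(sen, colnames(expr)))
}

#' Cross-database consensus drug response-featured genes
#'
#' For each drug assayed in both databases, keeps genes passing `p <
#' p_thresh` and `|log2FC| > lfc_thresh` in both with the same fold-change
#' sign, takes the union over drugs, and deduplicates by gene. A gene
#' supported with opposite directions by different drugs is dropped with a
#' warning.
#'
#' @param de_db1,de_db2 named lists (drug -> DE table from [drug_de()]);
#'   NULL entries (skipped drugs) are ignored.
#' @param p_thresh,lfc_thresh thresholds on raw p and absolute log2FC.
#' @return data.frame: gene, direction (up_in_resistant/down_in_resistant),
#'   drugs (";"-separated), lfc_db1, p_db1, lfc_db2, p_db2 (from the first
#'   supporting drug).
#' @export
consensus_featured_genes <- function(de_db1, de_db2, p_thresh = 0.05,
                                     lfc_thresh = 0.5) {
  shared <- intersect(names(de_db1)[!vapply(de_db1, is.null, logical(1))],
                      names(de_db2)[!vapply(de_db2, is.null, logical(1))])
  if (!length(shared)) stop("no drug analysed in both databases")
  hits <- list()
  for (d in shared) {
    a <- de_db1[[d]]; b <- de_db2[[d]]
    genes <- intersect(a$gene, b$gene)
    a <- a[match(genes, a$gene), ]; b <- b[match(genes, b$gene), ]
    pass <- a$p < p_thresh & abs(a$log2FC) > lfc_thresh &
      b$p < p_thresh & abs(b$log2FC) > lfc_thresh &
      sign(a$log2FC) == sign(b$log2FC)
    if (!any(pass)) next
    hits[[d]] <- data.frame(
      gene = genes[pass],
      direction = ifelse(a$log2FC[pass] > 0, "up_in_resistant",
                         "down_in_resistant"),
      drug = d, lfc_db1 = a$log2FC[pass], p_db1 = a$p[pass],
      lfc_db2 = b$log2FC[pass], p_db2 = b$p[pass],
      stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(gene = character(0), direction = character(0),
                      drugs = character(0), lfc_db1 = numeric(0),
                      p_db1 = numeric(0), lfc_db2 = numeric(0),
                      p_db2 = numeric(0)))
  all_hits <- do.call(rbind, hits)
  out <- do.call(rbind, lapply(split(all_hits, all_hits$gene), function(g) {
    if (length(unique(g$direction)) > 1L) return(NULL)
    data.frame(gene = g$gene[1L], direction = g$direction[1L],
               drugs = paste(g$drug, collapse = ";"),
               lfc_db1 = g$lfc_db1[1L], p_db1 = g$p_db1[1L],
               lfc_db2 = g$lfc_db2[1L], p_db2 = g$p_db2[1L],
               stringsAsFactors = FALSE)
  }))
  dropped <- length(unique(all_hits$gene)) - if (is.null(out)) 0L else nrow(out)
  if (dropped > 0)
    warning(dropped, " gene(s) dropped for conflicting direction across drugs")
  if (is.null(out))
    return(data.frame(gene = character(0), direction = character(0),
                      drugs = character(0), lfc_db1 = numeric(0),
                      p_db1 = numeric(0), lfc_db2 = numeric(0),
                      p_db2 = numeric(0)))
  rownames(out) <- NULL
  out[order(out$gene), ]
}
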