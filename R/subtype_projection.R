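.zrows <- function(expr) {
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) expr <- expr[sds > 0, , drop = FALSE]
  t(scale(t(expr)))
}

.cosine_dist_templates <- function(Z, sets, space) {
  denom_x <- sqrt(colSums(Z[space, , drop = FALSE]^2))
  d <- vapply(sets, function(S) {
    num <- colSums(Z[S, , drop = FALSE])
    dd <- 1 - num / (denom_x * sqrt(length(S)))
    dd[!is.finite(dd)] <- 1
    dd
  }, numeric(ncol(Z)))
  matrix(d, ncol = length(sets),
         dimnames = list(colnames(Z), names(sets)))
}

#' Nearest-template prediction of subtype membership
#'
#' Genes are z-standardized across the validation samples; each subtype's
#' template is the 0/1 indicator of its signature genes over the union of
#' all signature genes, and a sample is assigned to the template with the
#' smallest cosine distance (ties to the lowest subtype index). Per-sample
#' significance comes from `n_perm` random marker sets of identical sizes
#' drawn from all measured genes: p = (1 + #permuted d <= observed d) /
#' (n_perm + 1), followed by Benjamini-Hochberg FDR across samples.
#'
#' @param expr expression matrix of the cohort to classify.
#' @param signatures named list of signature gene vectors (pairwise
#'   disjoint).
#' @param n_perm permutations for the null distances.
#' @param fdr_max FDR below which a sample counts as classified.
#' @param seed integer seed.
#' @param min_coverage minimum measured fraction per signature.
#' @return data.frame: sample, subtype, distance, p, fdr, classified.
#' @export
ntp_classify <- function(expr, signatures, n_perm = 1000, fdr_max = 0.05,
                         seed = 1, min_coverage = 0.5) {
  validate_expression(expr)
  Z <- .zrows(expr)
  genes <- rownames(Z)
  sigs <- lapply(signatures, intersect, y = genes)
  cov <- vapply(seq_along(signatures), function(i)
    length(sigs[[i]]) / length(signatures[[i]]), numeric(1))
  low <- names(signatures)[cov < min_coverage]
  if (length(low))
    stop("signature coverage below ", min_coverage, " for subtype ",
         paste(low, collapse = ", "))
  space <- unique(unlist(sigs))
  d_obs <- .cosine_dist_templates(Z, sigs, space)
  pred <- apply(d_obs, 1L, which.min)  # ties break to the lowest index
  d_min <- d_obs[cbind(seq_len(nrow(d_obs)), pred)]
  set.seed(as.integer(seed))
  sizes <- lengths(sigs)
  exceed <- numeric(ncol(Z))
  for (b in seq_len(n_perm)) {
    draw <- sample(genes, sum(sizes))
    splits <- split(draw, rep(seq_along(sizes), sizes))
    names(splits) <- names(sigs)
    d_perm <- .cosine_dist_templates(Z, splits, unique(draw))
    # mirror the observed statistic: minimum over the random templates
    d_b <- apply(d_perm, 1L, min)
    exceed <- exceed + (d_b <= d_min)
  }
  p <- (1 + exceed) / (n_perm + 1)
  fdr <- stats::p.adjust(p, "BH")
  data.frame(sample = colnames(Z),
             subtype = as.integer(pred),
             distance = unname(d_min), p = unname(p), fdr = unname(fdr),
             classified = unname(fdr < fdr_max),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Weighted Kolmogorov-Smirnov enrichment score (weight exponent 1) of a
# gene set in a ranking by decreasing statistic; one-sided, max deviation.
.ks_es <- function(stat, set) {
  ord <- order(stat, decreasing = TRUE)
  genes <- names(stat)[ord]
  inset <- genes %in% set
  w <- abs(stat[ord])
  denom_in <- sum(w[inset])
  if (denom_in == 0) return(0)
  step <- ifelse(inset, w / denom_in, -1 / sum(!inset))
  max(cumsum(step))
}

.ovr_t <- function(expr, labels) {
  subtypes <- sort(unique(labels))
  out <- lapply(subtypes, function(k) {
    idx1 <- match(names(labels)[labels == k], colnames(expr))
    idx2 <- match(names(labels)[labels != k], colnames(expr))
    tab <- .welch_rows(expr, idx1, idx2)
    stats::setNames(tab$t, tab$gene)
  })
  names(out) <- as.character(subtypes)
  out
}

#' Submap-style cross-cohort subtype correspondence
#'
#' For each pair of subtypes (i in cohort A, j in cohort B), cohort-B genes
#' are ranked by the one-vs-rest Welch t statistic for subtype j and the
#' weighted KS enrichment score of A's subtype-i signature in that ranking
#' is compared with a null obtained by permuting cohort-B labels; the
#' reciprocal leg swaps the roles, enriching B's subtype-j markers (the top
#' genes by t in B, as many as A's signature) in the cohort-A ranking for
#' subtype i against label permutations of A. The two one-sided permutation
#' p-values are combined by Fisher's statistic, whose significance is itself
#' assessed against the permutations (the two legs are dependent, so the
#' chi-square reference would be anti-conservative), then Bonferroni-
#' corrected over all pairs; the smallest attainable corrected p is
#' `n_pairs / (n_perm + 1)`. Subtypes with fewer than 3 samples in a cohort
#' give NA rows or columns.
#'
#' @param expr_a,expr_b expression matrices.
#' @param labels_a,labels_b named subtype labels per sample.
#' @param signatures_a cohort-A signature list (names matching subtypes of
#'   A).
#' @param n_perm label permutations per cohort (> 0).
#' @param seed integer seed.
#' @return list with `p` (raw Fisher-combined), `p_adj` (Bonferroni) and
#'   `es` (observed enrichment of A-signatures in B rankings), all
#'   A-subtypes x B-subtypes matrices.
#' @export
submap_similarity <- function(expr_a, labels_a, expr_b, labels_b,
                              signatures_a, n_perm = 200, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  set.seed(as.integer(seed))
  labels_a <- labels_a[names(labels_a) %in% colnames(expr_a)]
  labels_b <- labels_b[names(labels_b) %in% colnames(expr_b)]
  sub_a <- names(signatures_a)
  sub_b <- as.character(sort(unique(labels_b)))
  ok_a <- sub_a[vapply(sub_a, function(k) sum(labels_a == k) >= 3, logical(1))]
  ok_b <- sub_b[vapply(sub_b, function(k) sum(labels_b == k) >= 3, logical(1))]
  t_b <- .ovr_t(expr_b, labels_b)
  t_a <- .ovr_t(expr_a, labels_a)
  sig_b <- lapply(ok_b, function(j) {
    m <- min(length(signatures_a[[1L]]), length(t_b[[j]]))
    names(sort(t_b[[j]], decreasing = TRUE))[seq_len(m)]
  })
  names(sig_b) <- ok_b
  es_fwd <- matrix(NA_real_, length(sub_a), length(sub_b),
                   dimnames = list(sub_a, sub_b))
  es_rev <- es_fwd
  for (i in intersect(sub_a, ok_a)) for (j in ok_b) {
    es_fwd[i, j] <- .ks_es(t_b[[j]], signatures_a[[i]])
    es_rev[i, j] <- .ks_es(t_a[[i]], sig_b[[j]])
  }
  # Both legs are calibrated against permutations of cohort-B labels (the
  # labels whose correspondence is being tested): the forward leg re-ranks
  # cohort B per permutation, the reciprocal leg re-derives B's marker sets
  # per permutation against the fixed cohort-A ranking.
  perm_fwd <- array(NA_real_, c(length(sub_a), length(sub_b), n_perm),
                    dimnames = c(dimnames(es_fwd), NULL))
  perm_rev <- perm_fwd
  for (b in seq_len(n_perm)) {
    perm_b <- labels_b
    names(perm_b) <- sample(names(labels_b))
    t_bp <- .ovr_t(expr_b, perm_b)
    sig_bp <- lapply(ok_b, function(j) {
      m <- min(length(signatures_a[[1L]]), length(t_bp[[j]]))
      names(sort(t_bp[[j]], decreasing = TRUE))[seq_len(m)]
    })
    names(sig_bp) <- ok_b
    for (i in intersect(sub_a, ok_a)) for (j in ok_b) {
      if (!is.null(t_bp[[j]])) {
        perm_fwd[i, j, b] <- .ks_es(t_bp[[j]], signatures_a[[i]])
        perm_rev[i, j, b] <- .ks_es(t_a[[i]], sig_bp[[j]])
      }
    }
  }
  # Per-leg p by pooled ranking (observed pooled with permutations); the
  # Fisher statistic combining the two dependent legs is itself calibrated
  # against the permutations rather than a chi-square reference.
  p <- es_fwd * NA
  pooled_p <- function(values) {
    # p for each value = fraction of pooled values at least as large
    n <- length(values)
    (n + 1 - rank(values, ties.method = "min")) / n
  }
  for (i in sub_a) for (j in sub_b) {
    if (is.na(es_fwd[i, j])) next
    pf <- pooled_p(c(es_fwd[i, j], perm_fwd[i, j, ]))
    pr <- pooled_p(c(es_rev[i, j], perm_rev[i, j, ]))
    x2 <- -2 * (log(pf) + log(pr))
    p[i, j] <- (1 + sum(x2[-1L] >= x2[1L])) / (n_perm + 1)
  }
  n_pairs <- sum(!is.na(p))
  p_adj <- p
  p_adj[] <- pmin(1, p * n_pairs)
  list(p = p, p_adj = p_adj, es = es_fwd)
}

#' Subtype proportions across cohorts with a homogeneity test
#'
#' @param assignment data.frame with columns sample, subtype, cohort.
#' @return list with `proportions` (cohort x subtype fractions), `counts`,
#'   `statistic` and `p` (Pearson chi-square test of homogeneity).
#' @export
subtype_proportions <- function(assignment) {
  counts <- table(assignment$cohort, assignment$subtype)
  if (nrow(counts) < 2) stop("need >= 2 cohorts")
  expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  if (any(expected < 1))
    warning("expected cell count < 1; chi-square approximation is weak")
  test <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  props <- sweep(counts, 1L, rowSums(counts), "/")
  list(proportions = props, counts = counts,
       statistic = unname(test$statistic), p = unname(test$p.value))
}
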