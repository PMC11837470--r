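#' Shift gene rows to a nonnegative range
#'
#' Subtracts each gene's minimum so every row has minimum exactly 0, the
#' input transform used before NMF.
#'
#' @param expr expression matrix restricted to the clustering genes.
#' @return nonnegative matrix of the same shape.
#' @export
nonneg_transform <- function(expr) {
  validate_expression(expr)
  if (nrow(expr) < 2) stop("need at least 2 genes for factorization")
  expr - apply(expr, 1L, min)
}

.kl_div <- function(V, WH) {
  WH <- pmax(WH, .Machine$double.xmin)
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

.h_labels <- function(H) apply(H, 2L, which.max)

#' Nonnegative matrix factorization by Kullback-Leibler multiplicative updates
#'
#' Brunet-style updates minimizing the generalized KL divergence
#' D(V || WH). Sample connectivity (the argmax over each column of H) is
#' checked every `check_interval` iterations; the run stops once it has been
#' unchanged for `stop_stable` consecutive checks, or at `max_iter`.
#' The divergence, recorded at each checkpoint, is non-increasing.
#'
#' @param V nonnegative matrix (genes x samples).
#' @param k factorization rank, `k < min(dim(V))`.
#' @param seed integer seed for the uniform random initialization.
#' @param max_iter iteration cap.
#' @param check_interval,stop_stable connectivity-stability stopping rule.
#' @return list with `W` (genes x k), `H` (k x samples), `divergence`
#'   (checkpoint trace) and `iterations`.
#' @useDynLib pharmacotype, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @export
nmf_factorize <- function(V, k, seed = 1, max_iter = 2000,
                          check_interval = 10, stop_stable = 40) {
  if (any(V < 0)) stop("V must be nonnegative")
  if (k >= min(dim(V))) stop("k must be < min(dim(V))")
  set.seed(as.integer(seed))
  n <- nrow(V); m <- ncol(V)
  W <- matrix(stats::runif(n * k), n, k)
  H <- matrix(stats::runif(k * m), k, m)
  fit <- .nmf_kl_cpp(unname(V), W, H, as.integer(max_iter),
                     as.integer(check_interval), as.integer(stop_stable))
  list(W = fit$W, H = fit$H, divergence = fit$divergence,
       iterations = fit$iterations)
}

#' Consensus clustering over NMF random restarts
#'
#' For each rank in `k_range`, runs `n_runs` NMF factorizations from random
#' starts; each run clusters samples by the argmax of their H column (ties
#' to the lowest index), and the consensus matrix is the mean co-clustering
#' indicator over runs. The cophenetic coefficient for a rank is the Pearson
#' correlation between 1 - consensus and the cophenetic distances of its
#' average-linkage tree; final labels cut that tree at the rank. The
#' selected rank maximizes the cophenetic coefficient; exact ties go to the
#' largest tied rank (see Details in the package vignette: a coarser rank
#' that always merges the same true groups is also perfectly ultrametric).
#'
#' @param V nonnegative matrix (genes x samples) from [nonneg_transform()].
#' @param k_range candidate ranks.
#' @param n_runs random restarts per rank (>= 2; `n_runs = 1` is allowed and
#'   gives a 0/1 consensus).
#' @param seed master seed; per-run seeds are derived by fixed offsets.
#' @param max_iter inner iteration cap per run.
#' @return list with per-rank entries (`consensus`, `cophenetic`, `labels`,
#'   `mean_divergence`) under `ranks`, plus `best_k` and `metrics`
#'   (data.frame rank/cophenetic/mean divergence).
#' @export
consensus_cluster <- function(V, k_range = 2:7, n_runs = 100, seed = 1,
                              max_iter = 2000) {
  m <- ncol(V)
  if (min(k_range) < 2 || max(k_range) > m - 1)
    stop("k_range must lie within [2, n_samples - 1]")
  samples <- colnames(V)
  ranks <- list()
  for (k in k_range) {
    consensus <- matrix(0, m, m)
    div <- 0
    for (r in seq_len(n_runs)) {
      fit <- nmf_factorize(V, k, seed = as.integer(seed) + 1000L * k + r,
                           max_iter = max_iter)
      lab <- .h_labels(fit$H)
      conn <- outer(lab, lab, "==") * 1
      consensus <- consensus + conn
      div <- div + fit$divergence[length(fit$divergence)]
    }
    consensus <- consensus / n_runs
    diag(consensus) <- 1
    dimnames(consensus) <- list(samples, samples)
    d <- stats::as.dist(1 - consensus)
    hc <- stats::hclust(d, method = "average")
    coph <- stats::cophenetic(hc)
    rho <- if (stats::sd(d) == 0 || stats::sd(coph) == 0) NA_real_ else
      stats::cor(d, coph)
    labels <- stats::cutree(hc, k = k)
    ranks[[as.character(k)]] <- list(consensus = consensus, cophenetic = rho,
                                     labels = labels, mean_divergence = div / n_runs)
  }
  rho_all <- vapply(ranks, `[[`, numeric(1), "cophenetic")
  cand <- rho_all
  cand[is.na(cand)] <- -Inf
  # Exact ties happen: a coarser rank that always merges the same true
  # groups yields an ultrametric consensus with rho = 1 just like the true
  # rank. A tie means both trees fit perfectly, so the finer (larger-k)
  # stable partition is the informative one; a strictly higher rho at a
  # smaller k still wins.
  tied <- which(cand >= max(cand) - 1e-12)
  best_k <- k_range[max(tied)]
  metrics <- data.frame(rank = k_range, cophenetic = unname(rho_all),
                        mean_divergence = vapply(ranks, `[[`, numeric(1),
                                                 "mean_divergence"))
  list(ranks = ranks, best_k = best_k, metrics = metrics)
}

#' Silhouette pruning of a consensus clustering
#'
#' Silhouette widths are computed with dissimilarity `1 - consensus`:
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with a(i) the mean dissimilarity
#' to the sample's own cluster and b(i) the smallest mean dissimilarity to
#' another cluster. Samples with negative width are flagged not retained.
#'
#' @param consensus consensus matrix (samples x samples).
#' @param labels integer cluster labels named by sample.
#' @return data.frame: sample, subtype, silhouette, retained.
#' @export
silhouette_filter <- function(consensus, labels) {
  k <- length(unique(labels))
  if (k < 2) stop("need at least 2 clusters")
  if (any(table(labels) < 2)) stop("every cluster must have >= 2 samples")
  d <- 1 - consensus
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i]); own <- setdiff(own, i)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(d[i, labels == cl]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  retained <- s >= 0
  if (any(table(labels[retained]) < 1) || length(unique(labels[retained])) < k)
    stop("silhouette pruning emptied a cluster")
  data.frame(sample = names(labels), subtype = as.integer(labels),
             silhouette = s, retained = retained, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Per-subtype up-regulated genes by one-vs-rest differential expression
#'
#' Welch t-test of each subtype against all other retained samples;
#' up-regulated means log2FC > `lfc_thresh` with Benjamini-Hochberg adjusted
#' p < `fdr_max`. Genes constant everywhere get p = 1.
#'
#' @param expr expression matrix over retained samples.
#' @param assignment data.frame from [silhouette_filter()] (only retained
#'   rows are used) or a named integer vector of labels.
#' @param lfc_thresh,fdr_max thresholds.
#' @return list with `up` (subtype -> character vector) and `tables`
#'   (subtype -> full DE table with `fdr`).
#' @export
subtype_de <- function(expr, assignment, lfc_thresh = 0.5, fdr_max = 0.05) {
  lab <- .assignment_labels(assignment)
  lab <- lab[names(lab) %in% colnames(expr)]
  if (any(table(lab) < 3)) stop("every subtype needs >= 3 retained samples")
  subtypes <- sort(unique(lab))
  tables <- list()
  up <- list()
  for (k in subtypes) {
    idx1 <- match(names(lab)[lab == k], colnames(expr))
    idx2 <- match(names(lab)[lab != k], colnames(expr))
    tab <- .welch_rows(expr, idx1, idx2)
    tab$fdr <- stats::p.adjust(tab$p, "BH")
    tables[[as.character(k)]] <- tab
    up[[as.character(k)]] <- tab$gene[tab$log2FC > lfc_thresh & tab$fdr < fdr_max]
  }
  list(up = up, tables = tables)
}

.assignment_labels <- function(assignment) {
  if (is.data.frame(assignment)) {
    a <- assignment[assignment$retained, ]
    stats::setNames(a$subtype, a$sample)
  } else assignment
}

.scale_free_fit <- function(k_conn, n_bins = 10) {
  k_conn <- k_conn[k_conn > 0]
  if (length(unique(k_conn)) < 3) return(c(r2 = NA_real_, slope = NA_real_))
  breaks <- seq(min(k_conn), max(k_conn), length.out = n_bins + 1)
  bin <- cut(k_conn, breaks, include.lowest = TRUE)
  pk <- tapply(k_conn, bin, length) / length(k_conn)
  km <- tapply(k_conn, bin, mean)
  ok <- !is.na(pk) & pk > 0 & !is.na(km) & km > 0
  if (sum(ok) < 3) return(c(r2 = NA_real_, slope = NA_real_))
  fit <- stats::lm(log10(pk[ok]) ~ log10(km[ok]))
  c(r2 = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2L]))
}

.module_eigengene <- function(expr_mod) {
  X <- t(scale(t(expr_mod)))          # standardize each gene across samples
  sv <- svd(X, nu = 0, nv = 1)
  e <- sv$v[, 1L]
  if (mean(stats::cor(t(X), e)) < 0) e <- -e
  stats::setNames(e, colnames(expr_mod))
}

#' Detect co-expression modules from topological overlap
#'
#' Builds an unsigned weighted network: adjacency `|cor|^beta` with the soft
#' power chosen as the smallest grid value whose scale-free fit R-squared
#' (log10 frequency vs log10 connectivity over 10 bins, negative slope)
#' reaches `r2_target`, else the best-fitting one. The topological overlap
#' matrix credits shared neighbors; genes are clustered by average linkage
#' on 1 - TOM with a static cut at 0.99 of the maximum merge height.
#' Clusters below `min_size` stay unassigned; modules whose eigengenes
#' correlate above `merge_r` are merged. Eigengenes are the first principal
#' component of the gene-standardized module submatrix, oriented so the mean
#' gene-eigengene correlation is nonnegative.
#'
#' @param expr expression matrix (genes x samples).
#' @param beta_grid candidate soft powers (default 1..10).
#' @param r2_target scale-free fit target.
#' @param min_size minimum module size.
#' @param merge_r eigengene correlation above which modules merge.
#' @return list with `modules` (named gene -> module id, NA if unassigned),
#'   `eigengenes` (samples x modules), `beta`, `fit` (per-power R2/slope).
#' @export
detect_modules <- function(expr, beta_grid = 1:10, r2_target = 0.85,
                           min_size = 30, merge_r = 0.8) {
  validate_expression(expr)
  if (ncol(expr) < 10) stop("need >= 10 samples")
  sds <- apply(expr, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " constant gene(s) dropped")
    expr <- expr[sds > 0, , drop = FALSE]
  }
  if (nrow(expr) < 2 * min_size) stop("need >= 2 * min_size non-constant genes")
  C <- abs(stats::cor(t(expr)))
  diag(C) <- 0
  fit <- t(vapply(beta_grid, function(b) .scale_free_fit(colSums(C^b)),
                  c(r2 = 0, slope = 0)))
  fit <- data.frame(beta = beta_grid, r2 = fit[, "r2"], slope = fit[, "slope"])
  ok <- !is.na(fit$r2) & fit$slope < 0
  beta <- if (any(ok & fit$r2 >= r2_target)) {
    min(fit$beta[ok & fit$r2 >= r2_target])
  } else if (any(ok)) fit$beta[ok][which.max(fit$r2[ok])] else
    fit$beta[which.max(fit$r2)]
  A <- C^beta
  kvec <- rowSums(A)
  L <- A %*% A
  kmin <- outer(kvec, kvec, pmin)
  TOM <- (L + A) / (kmin + 1 - A)
  diag(TOM) <- 1
  hc <- stats::hclust(stats::as.dist(1 - TOM), method = "average")
  cl <- stats::cutree(hc, h = 0.99 * max(hc$height))
  sizes <- table(cl)
  keep_cl <- names(sizes)[sizes >= min_size]
  modules <- rep(NA_character_, nrow(expr))
  names(modules) <- rownames(expr)
  for (i in seq_along(keep_cl))
    modules[cl == as.integer(keep_cl[i])] <- sprintf("M%d", i)
  if (!any(!is.na(modules)))
    return(list(modules = modules,
                eigengenes = matrix(numeric(0), ncol(expr), 0,
                                    dimnames = list(colnames(expr), NULL)),
                beta = beta, fit = fit))
  repeat {
    ids <- sort(unique(stats::na.omit(modules)))
    eig <- vapply(ids, function(m)
      .module_eigengene(expr[names(modules)[!is.na(modules) & modules == m], ,
                             drop = FALSE]), numeric(ncol(expr)))
    if (length(ids) < 2) break
    ec <- stats::cor(eig)
    diag(ec) <- 0
    mx <- which(ec == max(ec), arr.ind = TRUE)[1L, ]
    if (max(ec) <= merge_r) break
    modules[!is.na(modules) & modules == ids[mx[2L]]] <- ids[mx[1L]]
  }
  ids <- sort(unique(stats::na.omit(modules)))
  relabel <- stats::setNames(sprintf("M%d", seq_along(ids)), ids)
  modules[!is.na(modules)] <- relabel[modules[!is.na(modules)]]
  ids <- sort(unique(stats::na.omit(modules)))
  eig <- vapply(ids, function(m)
    .module_eigengene(expr[names(modules)[!is.na(modules) & modules == m], ,
                           drop = FALSE]), numeric(ncol(expr)))
  rownames(eig) <- colnames(expr)
  list(modules = modules, eigengenes = eig, beta = beta, fit = fit)
}

#' Select subtype-relevant modules by eigengene correlation
#'
#' Pearson correlation between each module eigengene and each subtype's
#' one-hot indicator over retained samples; a module serves a subtype when
#' r strictly exceeds `r_min` (a module may serve several subtypes).
#'
#' @param mods result of [detect_modules()].
#' @param assignment data.frame from [silhouette_filter()] or named labels.
#' @param r_min correlation threshold (strict).
#' @return list with `selected` (subtype -> module ids) and `correlation`
#'   (modules x subtypes matrix).
#' @export
module_trait_select <- function(mods, assignment, r_min = 0.5) {
  lab <- .assignment_labels(assignment)
  eig <- mods$eigengenes
  if (ncol(eig) < 1) stop("no modules to select from")
  common <- intersect(rownames(eig), names(lab))
  lab <- lab[common]
  eig <- eig[common, , drop = FALSE]
  subtypes <- sort(unique(lab))
  rmat <- vapply(subtypes, function(k)
    as.vector(stats::cor(eig, as.numeric(lab == k))), numeric(ncol(eig)))
  rmat <- matrix(rmat, ncol = length(subtypes),
                 dimnames = list(colnames(eig), as.character(subtypes)))
  selected <- lapply(as.character(subtypes), function(k) {
    hit <- rownames(rmat)[rmat[, k] > r_min]
    if (!length(hit)) warning("no module passes r > ", r_min,
                              " for subtype ", k)
    hit
  })
  names(selected) <- as.character(subtypes)
  list(selected = selected, correlation = rmat)
}

#' Derive per-subtype signature gene sets
#'
#' For each subtype, the signature is the union of its selected modules'
#' genes intersected with its up-regulated genes; genes landing in two or
#' more signatures are removed from all of them so signatures are pairwise
#' disjoint (well-posed nearest-template templates).
#'
#' @param selection result of [module_trait_select()].
#' @param mods result of [detect_modules()].
#' @param de result of [subtype_de()].
#' @return named list of character vectors (one per subtype).
#' @export
derive_signatures <- function(selection, mods, de) {
  subtypes <- names(selection$selected)
  sigs <- lapply(subtypes, function(k) {
    mod_genes <- names(mods$modules)[!is.na(mods$modules) &
                                       mods$modules %in% selection$selected[[k]]]
    intersect(mod_genes, de$up[[k]])
  })
  names(sigs) <- subtypes
  all_genes <- unlist(sigs)
  dup <- unique(all_genes[duplicated(all_genes)])
  sigs <- lapply(sigs, setdiff, y = dup)
  empty <- names(sigs)[vapply(sigs, length, 1L) == 0]
  if (length(empty))
    stop("empty signature for subtype ", paste(empty, collapse = ", "),
         "; consider relaxing module or DE thresholds")
  sigs
}
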