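#' Fit a cross-validated ridge model of drug response on cell lines
#'
#' Features default to the most-variable genes (top `n_features` by
#' variance). Features are z-standardized with training statistics; for each
#' lambda on the grid the closed-form ridge solution is computed and the
#' lambda minimizing the mean 10-fold cross-validated MSE (folds split by
#' `seed`) is kept, then the model is refit on all lines.
#'
#' @param expr_cells expression matrix (genes x cell lines).
#' @param response named numeric vector (e.g. log10 IC50) per cell line.
#' @param lambda_grid ridge penalties (default 13 log-spaced points over
#'   1e-2..1e4).
#' @param n_folds cross-validation folds.
#' @param seed integer seed for the fold split.
#' @param n_features number of most-variable genes used.
#' @param feature_genes optional explicit feature set (e.g. genes measured
#'   in the target cohorts); variance filtering applies within it.
#' @return ridge model list: features, center, scale, weights, intercept,
#'   lambda, cv (lambda x mean MSE).
#' @export
ridge_fit_cv <- function(expr_cells, response,
                         lambda_grid = 10^seq(-2, 4, length.out = 13),
                         n_folds = 10, seed = 1, n_features = 1000,
                         feature_genes = NULL) {
  validate_expression(expr_cells)
  lines <- intersect(colnames(expr_cells), names(response))
  if (length(lines) < 20) stop("need >= 20 training cell lines")
  if (n_folds > length(lines)) stop("n_folds exceeds the number of lines")
  pool <- if (is.null(feature_genes)) rownames(expr_cells) else
    intersect(feature_genes, rownames(expr_cells))
  vars <- apply(expr_cells[pool, lines, drop = FALSE], 1L, stats::var)
  pool <- pool[vars > 0]
  features <- pool[order(vars[vars > 0], decreasing = TRUE)][
    seq_len(min(n_features, length(pool)))]
  X <- t(expr_cells[features, lines, drop = FALSE])
  y <- response[lines]
  ctr <- colMeans(X); scl <- apply(X, 2L, stats::sd)
  Xz <- scale(X, center = ctr, scale = scl)
  set.seed(as.integer(seed))
  fold <- sample(rep(seq_len(n_folds), length.out = length(lines)))
  ridge_solve <- function(Xtr, ytr, lambda) {
    p <- ncol(Xtr)
    ym <- mean(ytr)
    b <- solve(crossprod(Xtr) + lambda * diag(p), crossprod(Xtr, ytr - ym))
    list(w = drop(b), b0 = ym)
  }
  mse <- vapply(lambda_grid, function(lam) {
    errs <- vapply(seq_len(n_folds), function(f) {
      tr <- fold != f
      fit <- ridge_solve(Xz[tr, , drop = FALSE], y[tr], lam)
      pred <- drop(Xz[!tr, , drop = FALSE] %*% fit$w) + fit$b0
      mean((pred - y[!tr])^2)
    }, numeric(1))
    mean(errs)
  }, numeric(1))
  lambda <- lambda_grid[which.min(mse)]
  fit <- ridge_solve(Xz, y, lambda)
  list(features = features, center = ctr, scale = scl, weights = fit$w,
       intercept = fit$b0, lambda = lambda,
       cv = data.frame(lambda = lambda_grid, mse = mse))
}

#' Predict drug response in a cohort from a ridge model
#'
#' Applies the training standardization; features missing from the cohort
#' are imputed at the training mean (z = 0) with a warning, provided at
#' least 80 percent of model features are measured.
#'
#' @param model ridge model from [ridge_fit_cv()].
#' @param expr_cohort cohort expression matrix.
#' @return named numeric vector of predicted response per sample.
#' @export
predict_response <- function(model, expr_cohort) {
  validate_expression(expr_cohort)
  have <- intersect(model$features, rownames(expr_cohort))
  coverage <- length(have) / length(model$features)
  if (coverage < 0.8)
    stop(sprintf("only %.0f%% of model features measured (need 80%%)",
                 100 * coverage))
  if (coverage < 1)
    warning(length(model$features) - length(have),
            " feature(s) imputed at the training mean")
  idx <- match(have, model$features)
  Z <- sweep(sweep(t(expr_cohort[have, , drop = FALSE]), 2L,
                   model$center[idx]), 2L, model$scale[idx], "/")
  drop(Z %*% model$weights[idx]) + model$intercept
}

#' Test predicted response differences across subtypes
#'
#' Kruskal-Wallis over subtype groups with pairwise Wilcoxon rank-sum
#' post-hoc tests (Benjamini-Hochberg adjusted). Groups with fewer than 3
#' samples are excluded with a warning.
#'
#' @param predictions named numeric vector per sample.
#' @param assignment data.frame from [silhouette_filter()] or named labels.
#' @return list: statistic, p, pairwise (matrix of adjusted p), group_medians.
#' @export
group_response_test <- function(predictions, assignment) {
  lab <- .assignment_labels(assignment)
  common <- intersect(names(predictions), names(lab))
  x <- predictions[common]; g <- lab[common]
  small <- names(table(g))[table(g) < 3]
  if (length(small)) {
    warning("excluding subtype(s) with < 3 samples: ",
            paste(small, collapse = ", "))
    keep <- !(g %in% as.integer(small) | as.character(g) %in% small)
    x <- x[keep]; g <- g[keep]
  }
  if (length(unique(g)) < 2) stop("need >= 2 subtypes with >= 3 samples")
  g <- factor(g)
  kw <- stats::kruskal.test(x, g)
  pw <- suppressWarnings(stats::pairwise.wilcox.test(x, g, p.adjust.method = "BH"))
  list(statistic = unname(kw$statistic), p = kw$p.value,
       pairwise = pw$p.value,
       group_medians = tapply(x, g, stats::median))
}

#' Correlate gene expression with (predicted) drug response
#'
#' Pearson correlation per gene across samples, ranked descending by r;
#' the top of the list nominates candidate resistance drivers.
#'
#' @param predictions named numeric response (predicted or measured) per
#'   sample.
#' @param expr expression matrix restricted to the genes of interest (for
#'   example one subtype's signature genes).
#' @param genes optional subset of genes to test.
#' @return data.frame (gene, r, p) ordered by decreasing r; constant genes
#'   excluded.
#' @export
gene_ic50_correlation <- function(predictions, expr, genes = NULL) {
  validate_expression(expr)
  common <- intersect(names(predictions), colnames(expr))
  if (length(common) < 10) stop("need >= 10 samples")
  if (is.null(genes)) genes <- rownames(expr)
  genes <- intersect(genes, rownames(expr))
  y <- predictions[common]
  out <- do.call(rbind, lapply(genes, function(g) {
    x <- expr[g, common]
    if (stats::sd(x) == 0) return(NULL)
    ct <- stats::cor.test(x, y)
    data.frame(gene = g, r = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out)) stop("all candidate genes are constant")
  rownames(out) <- NULL
  out[order(out$r, decreasing = TRUE), ]
}

#' Kaplan-Meier curves and k-sample log-rank test
#'
#' Product-limit estimates per group and the log-rank chi-square with
#' k - 1 degrees of freedom (hypergeometric variance).
#'
#' @param survival_tab data.frame with sample, time, event.
#' @param groups named group labels per sample.
#' @return list: fit (survfit), statistic, df, p.
#' @export
km_logrank <- function(survival_tab, groups) {
  common <- intersect(survival_tab$sample, names(groups))
  tab <- survival_tab[match(common, survival_tab$sample), ]
  g <- factor(groups[common])
  if (length(levels(g)) < 2) stop("need >= 2 groups")
  ev <- tapply(tab$event, g, sum)
  if (any(ev == 0)) warning("group(s) with zero events included: ",
                            paste(names(ev)[ev == 0], collapse = ", "))
  fit <- survival::survfit(survival::Surv(tab$time, tab$event) ~ g)
  sd_ <- survival::survdiff(survival::Surv(tab$time, tab$event) ~ g)
  df <- length(levels(g)) - 1L
  list(fit = fit, statistic = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Univariate Cox proportional hazards regression
#'
#' Partial-likelihood fit with Efron tie handling (Newton-Raphson,
#' convergence 1e-9, at most 50 iterations). Monotone-likelihood /
#' non-convergent fits raise an error.
#'
#' @param survival_tab data.frame with sample, time, event.
#' @param covariate named numeric vector per sample.
#' @return list: loghr, se, p (Wald), n_events.
#' @export
cox_univariate <- function(survival_tab, covariate) {
  common <- intersect(survival_tab$sample, names(covariate))
  tab <- survival_tab[match(common, survival_tab$sample), ]
  x <- covariate[common]
  if (stats::sd(x) == 0) stop("covariate is constant")
  if (sum(tab$event) < 10) stop("need >= 10 events")
  fit <- survival::coxph(survival::Surv(tab$time, tab$event) ~ x,
                         ties = "efron",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50))
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(diag(fit$var)))
  if (!is.finite(beta) || !is.finite(se) || abs(beta) > 15)
    stop("Cox fit did not converge (monotone likelihood?)")
  list(loghr = beta, se = se,
       p = 2 * stats::pnorm(abs(beta / se), lower.tail = FALSE),
       n_events = sum(tab$event))
}

#' Harrell's concordance index
#'
#' Counts all usable pairs (the member with the earlier time has an event;
#' tied event times are unusable); a pair is concordant when the
#' earlier-failing member has the higher risk, and tied risks score 0.5.
#'
#' @param risk named numeric risk scores.
#' @param survival_tab data.frame with sample, time, event.
#' @return C in `[0, 1]`, or NA if no usable pair exists.
#' @export
harrell_c <- function(risk, survival_tab) {
  common <- intersect(names(risk), survival_tab$sample)
  tab <- survival_tab[match(common, survival_tab$sample), ]
  r <- risk[common]; tt <- tab$time; ev <- tab$event
  n <- length(r)
  conc <- 0; ties <- 0; usable <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (tt[i] == tt[j]) next
    first <- if (tt[i] < tt[j]) i else j
    other <- if (first == i) j else i
    if (ev[first] != 1) next
    usable <- usable + 1
    if (r[first] > r[other]) conc <- conc + 1
    else if (r[first] == r[other]) ties <- ties + 1
  }
  if (usable == 0) return(NA_real_)
  (conc + 0.5 * ties) / usable
}

#' Benchmark coefficient-based prognostic gene signatures per subtype
#'
#' Each catalog model defines a linear risk score sum(coef * z(expr)) over
#' its measured genes (at least 60 percent coverage per cohort, else NA).
#' Harrell's C is computed within each subtype's samples in each cohort and
#' averaged over cohorts; the per-subtype winner maximizes the mean C.
#'
#' @param catalog data.frame: model_id, gene, coefficient.
#' @param cohorts list of lists with elements `expr` and `clinical`.
#' @param assignment data.frame with sample, subtype (covering cohort
#'   samples), or named labels.
#' @return list: report (long data.frame model/cohort/subtype/C), mean_c
#'   (models x subtypes), best (subtype -> model_id).
#' @export
benchmark_models <- function(catalog, cohorts, assignment) {
  stopifnot(all(c("model_id", "gene", "coefficient") %in% colnames(catalog)))
  lab <- .assignment_labels(assignment)
  models <- split(catalog, catalog$model_id)
  subtypes <- sort(unique(lab))
  rows <- list()
  for (mid in names(models)) {
    coefs <- stats::setNames(models[[mid]]$coefficient, models[[mid]]$gene)
    for (ci in seq_along(cohorts)) {
      expr <- cohorts[[ci]]$expr; clin <- cohorts[[ci]]$clinical
      have <- intersect(names(coefs), rownames(expr))
      if (length(have) / length(coefs) < 0.6) {
        warning("model ", mid, " below 60% gene coverage in cohort ", ci)
        for (k in subtypes)
          rows[[length(rows) + 1L]] <- data.frame(
            model = mid, cohort = ci, subtype = k, C = NA_real_)
        next
      }
      z <- t(scale(t(expr[have, , drop = FALSE])))
      z[!is.finite(z)] <- 0
      risk <- drop(crossprod(z, coefs[have]))
      names(risk) <- colnames(expr)
      for (k in subtypes) {
        s_k <- names(lab)[lab == k]
        s_k <- intersect(s_k, intersect(names(risk), clin$sample))
        C <- if (length(s_k) >= 3)
          harrell_c(risk[s_k], clin[clin$sample %in% s_k, ]) else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          model = mid, cohort = ci, subtype = k, C = C)
      }
    }
  }
  report <- do.call(rbind, rows)
  mean_c <- tapply(report$C, list(report$model, report$subtype),
                   function(v) mean(v, na.rm = TRUE))
  best <- apply(mean_c, 2L, function(v)
    if (all(is.na(v))) NA_character_ else rownames(mean_c)[which.max(v)])
  list(report = report, mean_c = mean_c, best = best)
}
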