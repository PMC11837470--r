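# Cell-line panel with a linear response surface for ridge tests.
make_ridge_fixture <- function(n = 60, p = 30, n_inform = 5, noise = 0.1,
                               seed = 3) {
  set.seed(seed)
  expr <- matrix(rnorm(p * n, 6, 1), p, n,
                 dimnames = list(sprintf("G%03d", 1:p), sprintf("CL%02d", 1:n)))
  beta <- c(runif(n_inform, 0.5, 1), rep(0, p - n_inform))
  y <- drop(crossprod(expr, beta)) + rnorm(n, 0, noise)
  names(y) <- colnames(expr)
  list(expr = expr, y = y, beta = beta)
}

test_that("ridge collapses to OLS as lambda vanishes and shrinks as it grows", {
  fx <- make_ridge_fixture(n = 50, p = 8)
  m_small <- ridge_fit_cv(fx$expr, fx$y, lambda_grid = 1e-8, n_folds = 5,
                          seed = 1, n_features = 8)
  X <- scale(t(fx$expr[m_small$features, ]))
  ols <- lm(fx$y ~ X)
  expect_equal(unname(m_small$weights[colnames(X)]),
               unname(coef(ols)[-1]), tolerance = 1e-6)

  m_big <- ridge_fit_cv(fx$expr, fx$y, lambda_grid = 1e9, n_folds = 5,
                        seed = 1, n_features = 8)
  expect_true(all(abs(m_big$weights) < 1e-3))
  expect_error(ridge_fit_cv(fx$expr[, 1:10], fx$y[1:10]), ">= 20")
})

test_that("cross-validated ridge recovers a linear response on held-out lines", {
  fx <- make_ridge_fixture(n = 80, p = 40, seed = 5)
  train <- 1:60; test <- 61:80
  m <- ridge_fit_cv(fx$expr[, train], fx$y[train], seed = 2, n_features = 40)
  pred <- predict_response(m, fx$expr[, test])
  expect_gte(cor(pred, fx$y[test]), 0.9)
  expect_true(is.finite(m$lambda) && m$lambda > 0)
  expect_equal(nrow(m$cv), 13L)  # default grid

  # all-mean sample predicts the intercept
  mean_sample <- matrix(m$center, ncol = 1,
                        dimnames = list(m$features, "MEANS"))
  expect_equal(unname(predict_response(m, mean_sample)), m$intercept,
               tolerance = 1e-9)

  # a cohort missing most features errors
  expect_error(predict_response(m, fx$expr[1:10, test]), "80%")
})

test_that("subtype response tests flag shifted groups and pass null groups", {
  set.seed(11)
  pred0 <- setNames(rep(rnorm(20), 3), paste0("s", 1:60))
  lab <- setNames(rep(1:3, each = 20), paste0("s", 1:60))
  # identical distributions duplicated across groups -> KW statistic 0
  out0 <- group_response_test(pred0, lab)
  expect_equal(out0$statistic, 0, tolerance = 1e-12)
  expect_equal(out0$p, 1)

  base <- rnorm(60)
  pred1 <- setNames(base + rep(c(0, 2, 4), each = 20) * sd(base), names(lab))
  out1 <- group_response_test(pred1, lab)
  expect_lt(out1$p, 0.01)

  lab_small <- lab; lab_small[lab_small == 3] <- NA
  lab_small <- c(lab_small[1:41], setNames(3L, "s60"))
  expect_warning(group_response_test(pred1[names(lab_small)],
                                     lab_small[!is.na(lab_small)]),
                 "< 3 samples")
  expect_error(group_response_test(pred1[1:20], lab[1:20]), ">= 2 subtypes")
})

test_that("gene-response correlation ranks a planted driver first", {
  fx <- make_ridge_fixture(n = 60, p = 30, n_inform = 1, noise = 0, seed = 7)
  # response is exactly the first gene (noiseless, single informative gene)
  ranked <- gene_ic50_correlation(fx$y, fx$expr)
  expect_equal(ranked$gene[1], "G001")
  expect_equal(ranked$r[1], 1, tolerance = 1e-9)
  expect_true(all(diff(ranked$r) <= 0))

  const <- fx$expr
  const["G002", ] <- 1
  ranked2 <- gene_ic50_correlation(fx$y, const)
  expect_false("G002" %in% ranked2$gene)
  expect_error(gene_ic50_correlation(fx$y[1:5], fx$expr[, 1:5]), ">= 10")
})

test_that("log-rank is zero for duplicated groups and powerful under HR 3", {
  surv <- data.frame(sample = paste0("s", 1:40),
                     time = rep(c(5, 10, 15, 20), 10),
                     event = rep(c(1, 0), 20), cohort = "A")
  groups <- setNames(rep(c("g1", "g2"), each = 20), surv$sample)
  # identical survival experience in both groups (duplicated times/events)
  surv$time <- rep(surv$time[1:20], 2)
  surv$event <- rep(surv$event[1:20], 2)
  out <- km_logrank(surv, groups)
  expect_equal(out$statistic, 0, tolerance = 1e-9)
  expect_equal(out$p, 1)

  hits <- logical(20)
  for (s in 1:20) {
    set.seed(s)
    t1 <- rexp(100, 1 / 300); t2 <- rexp(100, 3 / 300)
    cens <- runif(200) < 0.2
    tt <- c(t1, t2); tt[cens] <- tt[cens] * runif(sum(cens))
    sv <- data.frame(sample = paste0("x", 1:200), time = tt,
                     event = as.integer(!cens), cohort = "A")
    gr <- setNames(rep(c("a", "b"), each = 100), sv$sample)
    hits[s] <- km_logrank(sv, gr)$p < 0.001
  }
  expect_gte(mean(hits), 0.95)

  # KM reaches zero at the last event when nothing is censored
  sv2 <- data.frame(sample = paste0("y", 1:20), time = 1:20, event = 1,
                    cohort = "A")
  fit <- survival::survfit(survival::Surv(sv2$time, sv2$event) ~ 1)
  expect_equal(min(fit$surv), 0)
})

test_that("Cox regression recovers a planted log hazard ratio", {
  est <- numeric(10)
  for (s in 1:10) {
    set.seed(100 + s)
    x <- rnorm(300)
    tt <- rexp(300, exp(0.7 * x) / 500)
    sv <- data.frame(sample = paste0("p", 1:300), time = tt, event = 1,
                     cohort = "A")
    est[s] <- cox_univariate(sv, setNames(x, sv$sample))$loghr
  }
  expect_lt(abs(mean(est) - 0.7), 0.15)

  # independent covariate: small effect, valid Wald p
  set.seed(1)
  sv <- data.frame(sample = paste0("p", 1:200), time = rexp(200, 1 / 300),
                   event = 1, cohort = "A")
  out <- cox_univariate(sv, setNames(rnorm(200), sv$sample))
  expect_lt(abs(out$loghr), 0.3)
  expect_error(cox_univariate(sv, setNames(rep(1, 200), sv$sample)),
               "constant")
})

test_that("Harrell's C matches its definition and the survival package", {
  sv <- data.frame(sample = paste0("p", 1:50), time = sample(1:1000, 50),
                   event = 1, cohort = "A")
  risk <- setNames(-sv$time, sv$sample)    # perfect ranking
  expect_equal(harrell_c(risk, sv), 1)
  expect_equal(harrell_c(setNames(rep(1, 50), sv$sample), sv), 0.5)
  # complement identity for tie-free data
  set.seed(2)
  risk2 <- setNames(rnorm(50), sv$sample)
  expect_equal(harrell_c(risk2, sv) + harrell_c(-risk2, sv), 1)

  # cross-check against survival::concordance on censored data
  set.seed(3)
  sv$event <- rbinom(50, 1, 0.7)
  cidx <- harrell_c(risk2, sv)
  ref <- survival::concordance(survival::Surv(sv$time, sv$event) ~ risk2,
                               reverse = TRUE)$concordance
  expect_equal(cidx, unname(ref), tolerance = 1e-12)

  # random risk hovers near 0.5
  cs <- vapply(1:20, function(s) {
    set.seed(s)
    sv2 <- data.frame(sample = paste0("q", 1:500),
                      time = rexp(500, 1 / 300), event = 1, cohort = "A")
    harrell_c(setNames(rnorm(500), sv2$sample), sv2)
  }, numeric(1))
  expect_lt(abs(mean(cs) - 0.5), 0.05)
})

test_that("model benchmarking ranks the generating signature highest", {
  set.seed(21)
  p <- 20; n <- 150
  expr <- matrix(rnorm(p * n, 6, 1), p, n,
                 dimnames = list(sprintf("G%03d", 1:p), sprintf("s%03d", 1:n)))
  true_coef <- setNames(c(1, -1, 0.5, rep(0, p - 3)), rownames(expr))
  z <- t(scale(t(expr)))
  risk <- drop(crossprod(z, true_coef))
  tt <- rexp(n, exp(risk) / 400)
  clin <- data.frame(sample = colnames(expr), time = tt, event = 1,
                     cohort = "X")
  lab <- setNames(rep(1:2, length.out = n), colnames(expr))
  catalog <- rbind(
    data.frame(model_id = "true", gene = rownames(expr)[1:3],
               coefficient = true_coef[1:3]),
    data.frame(model_id = "rand1", gene = rownames(expr)[4:6],
               coefficient = c(0.8, -0.2, 0.1)),
    data.frame(model_id = "rand2", gene = rownames(expr)[7:9],
               coefficient = c(-0.5, 0.3, 0.9)))
  bench <- benchmark_models(catalog, list(list(expr = expr, clinical = clin)),
                            lab)
  expect_true(all(bench$best == "true"))
  rand_c <- bench$mean_c[c("rand1", "rand2"), ]
  expect_lt(max(abs(rand_c - 0.5)), 0.15)

  # low coverage gives NA with a warning
  cat2 <- data.frame(model_id = "m", gene = c("G001", "NOPE1", "NOPE2"),
                     coefficient = c(1, 1, 1))
  expect_warning(
    b2 <- benchmark_models(cat2, list(list(expr = expr, clinical = clin)),
                           lab),
    "coverage")
  expect_true(all(is.na(b2$report$C)))
})
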