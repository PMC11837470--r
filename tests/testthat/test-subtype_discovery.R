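test_that("nonneg_transform zeroes each gene's minimum", {
  m <- matrix(c(-1, 0, 2, 0, 1, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  out <- nonneg_transform(m)
  expect_equal(unname(out["a", ]), c(0, 1, 3))
  expect_equal(unname(out["b", ]), c(0, 1, 3))  # already nonnegative, min 0
  expect_true(all(apply(out, 1, min) == 0))
  expect_error(nonneg_transform(m[1, , drop = FALSE]), "2 genes")
})

test_that("KL-NMF converges on an exactly factorizable matrix", {
  set.seed(9)
  W0 <- matrix(runif(40, 0.5, 2), 20, 2)
  H0 <- matrix(runif(30, 0.5, 2), 2, 15)
  V <- W0 %*% H0
  dimnames(V) <- list(paste0("g", 1:20), paste0("s", 1:15))
  f <- nmf_factorize(V, 2, seed = 4, max_iter = 5000, stop_stable = 1e9)
  expect_lt(abs(f$divergence[length(f$divergence)]), 1e-6)
  expect_true(all(diff(f$divergence) <= 1e-8))   # monotone non-increasing
  expect_true(all(f$W >= 0) && all(f$H >= 0))

  # determinism under seed
  f2 <- nmf_factorize(V, 2, seed = 4, max_iter = 200)
  f3 <- nmf_factorize(V, 2, seed = 4, max_iter = 200)
  expect_identical(f2$W, f3$W)
  expect_identical(f2$H, f3$H)

  expect_error(nmf_factorize(V, 15, seed = 1), "k must be")
  expect_error(nmf_factorize(V - 10, 2), "nonnegative")
})

test_that("consensus matrices behave as co-clustering frequencies", {
  co <- simulate_patient_cohort(40, n_genes = 150,
                                truth = cohort_truth(marker_size = 30),
                                seed = 3)
  V <- nonneg_transform(co$expr[unlist(co$marker_genes), ])
  cc1 <- consensus_cluster(V, k_range = 3, n_runs = 1, seed = 2)
  cons1 <- cc1$ranks[["3"]]$consensus
  expect_true(all(cons1 %in% c(0, 1)))           # single run is 0/1
  cc <- consensus_cluster(V, k_range = 3, n_runs = 5, seed = 2)
  cons <- cc$ranks[["3"]]$consensus
  expect_true(all(cons >= 0 & cons <= 1))
  expect_equal(cons, t(cons))
  expect_true(all(diag(cons) == 1))
  expect_error(consensus_cluster(V, k_range = 1:3, n_runs = 2), "k_range")
})

test_that("a perfectly block-structured consensus gives rho 1 and block labels", {
  blocks <- rep(1:3, times = c(4, 5, 6))
  cons <- outer(blocks, blocks, "==") * 1
  dimnames(cons) <- list(paste0("s", 1:15), paste0("s", 1:15))
  d <- as.dist(1 - cons)
  hc <- hclust(d, "average")
  expect_equal(cor(d, cophenetic(hc)), 1.0)
  expect_equal(unname(cutree(hc, 3)[blocks == 1]), rep(cutree(hc, 3)[[1]], 4))

  sf <- silhouette_filter(cons, setNames(blocks, rownames(cons)))
  expect_true(all(sf$silhouette == 1))
  expect_true(all(sf$retained))
})

test_that("silhouette widths follow the hand-computed a/b formula", {
  # 6 samples, 2 clusters; sample 1 sits closer to the other cluster
  cons <- matrix(0.1, 6, 6)
  cons[1:3, 1:3] <- 0.9                 # cluster 1 core
  cons[4:6, 4:6] <- 0.9                 # cluster 2 core
  cons[1, 2:3] <- cons[2:3, 1] <- 0.2   # own cluster consensus 0.2 -> a = 0.8
  cons[1, 4:6] <- cons[4:6, 1] <- 0.9   # other cluster 0.9 -> b = 0.1
  diag(cons) <- 1
  dimnames(cons) <- list(paste0("s", 1:6), paste0("s", 1:6))
  lab <- setNames(c(1, 1, 1, 2, 2, 2), rownames(cons))
  sf <- silhouette_filter(cons, lab)
  expect_equal(sf$silhouette[1], (0.1 - 0.8) / 0.8)
  expect_false(sf$retained[1])
  expect_error(silhouette_filter(cons, setNames(rep(1, 6), rownames(cons))),
               "2 clusters")
})

test_that("one-vs-rest DE recovers planted markers exactly in noiseless mode", {
  co <- simulate_patient_cohort(45, n_genes = 150,
                                truth = cohort_truth(marker_size = 30,
                                                     shift = 2),
                                seed = 5, noiseless = TRUE)
  de <- subtype_de(co$expr, co$labels)
  for (k in 1:3) {
    expect_setequal(de$up[[as.character(k)]], co$marker_genes[[k]])
  }
  expect_error(subtype_de(co$expr, co$labels[1:5]), ">= 3")
})

test_that("label permutation yields at most chance-level up-DEG calls", {
  tot <- 0
  for (s in 1:10) {
    co <- simulate_patient_cohort(45, n_genes = 120,
                                  truth = cohort_truth(shift = 0,
                                                       marker_size = 30),
                                  seed = 40 + s)
    perm <- co$labels
    names(perm) <- sample(names(perm))
    de <- subtype_de(co$expr, perm)
    tot <- tot + sum(lengths(de$up))
  }
  expect_lte(tot / 10, 120 * 0.05 * 3)  # far below even the unadjusted bound
})

test_that("planted latent-factor modules are recovered", {
  set.seed(6)
  n <- 60; load <- 0.8
  f1 <- rnorm(n); f2 <- rnorm(n)
  X <- rbind(
    t(sapply(1:50, function(i) load * f1 + sqrt(1 - load^2) * rnorm(n))),
    t(sapply(1:50, function(i) load * f2 + sqrt(1 - load^2) * rnorm(n))),
    matrix(rnorm(40 * n), 40, n))
  dimnames(X) <- list(sprintf("g%03d", 1:140), sprintf("s%02d", 1:n))
  md <- detect_modules(X, min_size = 30)
  expect_equal(ncol(md$eigengenes), 2L)
  for (block in list(1:50, 51:100)) {
    assigned <- md$modules[block]
    main <- names(sort(table(assigned), decreasing = TRUE))[1]
    expect_gte(mean(assigned == main, na.rm = TRUE), 0.95)
    expect_gte(mean(!is.na(assigned)), 0.9)
  }
  # TOM-derived structure invariants via a null run: iid genes -> no module
  Xn <- matrix(rnorm(120 * 40), 120, 40,
               dimnames = list(sprintf("g%03d", 1:120), sprintf("s%02d", 1:40)))
  mdn <- detect_modules(Xn, min_size = 30)
  expect_equal(ncol(mdn$eigengenes), 0L)
})

test_that("TOM is symmetric and bounded in [0, 1]", {
  X <- make_expr(40, 20, seed = 13)
  C <- abs(cor(t(X))); diag(C) <- 0
  A <- C^6
  k <- rowSums(A)
  TOM <- (A %*% A + A) / (outer(k, k, pmin) + 1 - A)
  diag(TOM) <- 1
  expect_true(all(TOM >= 0 & TOM <= 1 + 1e-12))
  expect_equal(TOM, t(TOM), tolerance = 1e-12)
})

test_that("module-trait selection uses strict correlation threshold", {
  co <- simulate_patient_cohort(60, n_genes = 200, seed = 9)
  md <- detect_modules(co$expr, min_size = 30)
  sel <- module_trait_select(md, co$labels)
  # each planted marker module should serve its matching subtype
  for (k in 1:3) {
    mod_k <- unique(na.omit(md$modules[co$marker_genes[[k]]]))
    expect_true(any(mod_k %in% sel$selected[[as.character(k)]]))
  }
  # strictness: raising r_min to an attained correlation excludes the module
  r_attained <- max(sel$correlation[, "1"])
  sel2 <- suppressWarnings(module_trait_select(md, co$labels,
                                               r_min = r_attained))
  expect_false(any(sel2$selected[["1"]] %in%
                     rownames(sel$correlation)[sel$correlation[, "1"] ==
                                                 r_attained]))
})

test_that("signatures are module-and-DE intersections, pairwise disjoint", {
  fake_mods <- list(modules = c(A = "M1", B = "M1", C = "M1", D = "M2",
                                E = "M2", F = "M2"))
  fake_sel <- list(selected = list(`1` = "M1", `2` = "M2"))
  fake_de <- list(up = list(`1` = c("B", "C", "X"), `2` = c("D", "E")))
  sig <- derive_signatures(fake_sel, fake_mods, fake_de)
  expect_setequal(sig[["1"]], c("B", "C"))
  expect_setequal(sig[["2"]], c("D", "E"))

  # a gene claimed by two subtypes is removed from both
  fake_de2 <- list(up = list(`1` = c("B", "C", "D"), `2` = c("D", "E")))
  fake_mods2 <- list(modules = c(A = "M1", B = "M1", C = "M1", D = "M1",
                                 E = "M2", F = "M2"))
  fake_sel2 <- list(selected = list(`1` = "M1", `2` = c("M1", "M2")))
  sig2 <- derive_signatures(fake_sel2, fake_mods2, fake_de2)
  expect_false("D" %in% unlist(sig2))
  expect_length(intersect(sig2[["1"]], sig2[["2"]]), 0)

  fake_de3 <- list(up = list(`1` = "Z", `2` = c("D", "E")))
  expect_error(derive_signatures(fake_sel, fake_mods, fake_de3), "empty")
})
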