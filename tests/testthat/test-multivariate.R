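test_that("phase binning follows the 50-DIM convention", {
  expect_equal(bin_phases(c(1, 50)), c(1, 1))
  expect_equal(bin_phases(51), 2)
  expect_equal(bin_phases(c(101, 250, 251, 305)), c(3, 5, 6, 6))
  expect_warning(expect_equal(bin_phases(320), 6), "clamped")
  expect_error(bin_phases(0), "DIM")
})

test_that("phase matrix assembly is scoped, standardised and complete", {
  st <- tiny_study()
  res <- tiny_results()
  pm_b <- assemble_matrix(res, st$biomarkers, "blood")
  feats <- hrdcc:::phase_features(pm_b)
  expected <- paste0("blood_", c("granulocytes", "monocytes", "lymphocytes",
                                 "eos", "imm_gran", "cM", "intM", "ncM",
                                 "NK", "gdT", "CD4T", "CD8T", "B",
                                 "viability"))
  expect_setequal(feats, expected)
  X <- as.matrix(pm_b[feats])
  expect_true(all(abs(colMeans(X)) < 1e-9))
  expect_true(all(abs(apply(X, 2, sd) - 1) < 1e-9))

  # one row per complete visit; milk+blood visits always pair in the study
  pm_all <- assemble_matrix(res, st$biomarkers, "all")
  expect_equal(nrow(pm_all), nrow(st$samples) / 2)
  expect_false(any(grepl("MEC", names(pm_all))))
  expect_true(all(c("NEFA", "bilirubin", "haptoglobin") %in% names(pm_all)))

  # a visit missing one matrix is dropped
  res_miss <- dplyr::filter(res, !(sample_id == res$sample_id[1]))
  expect_message(pm_miss <- assemble_matrix(res_miss, st$biomarkers, "all"),
                 "dropped")
  expect_equal(nrow(pm_miss), nrow(pm_all) - 1)
})

test_that("PCA matches the correlation-eigendecomposition oracle", {
  st <- tiny_study()
  pm <- assemble_matrix(tiny_results(), st$biomarkers, "milk")
  pc <- fit_pca(pm)
  X <- as.matrix(pm[hrdcc:::phase_features(pm)])
  ev_oracle <- eigen(cor(X), symmetric = TRUE)$values
  expect_equal(pc$all_explained, 100 * ev_oracle / sum(ev_oracle),
               tolerance = 1e-8)
  expect_true(all(diff(pc$all_explained) <= 1e-12))
  expect_equal(sum(pc$all_explained), 100, tolerance = 1e-9)
  # scores are uncorrelated
  cv <- cov(pc$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
})

test_that("collinear data load entirely on the first component", {
  set.seed(50)
  t <- rnorm(40)
  X <- outer(t, c(1, -2, 0.5, 3, 1)) +
    matrix(rnorm(200, 0, 1e-8), 40)
  pm <- tibble::as_tibble(scale(X), .name_repair = ~ paste0("f", 1:5))
  pm$animal_id <- "a"; pm$dim <- seq_len(40); pm$phase <- bin_phases(pm$dim)
  attr(pm, "features") <- paste0("f", 1:5)
  class(pm) <- c("phase_matrix", class(pm))
  pc <- fit_pca(pm)
  expect_gt(pc$explained_variance[1], 99.99)
})

test_that("dense sPLS-DA matches the mixOmics PLS-DA oracle", {
  skip_if_not_installed("mixOmics")
  st <- tiny_study()
  pm <- assemble_matrix(tiny_results(), st$biomarkers, "milk")
  p <- length(hrdcc:::phase_features(pm))
  fit <- fit_splsda(pm, n_components = 2, keepX = p)
  X <- as.matrix(pm[hrdcc:::phase_features(pm)])
  oracle <- mixOmics::plsda(X, factor(pm$phase), ncomp = 2, scale = FALSE)
  for (h in 1:2) {
    expect_gte(abs(cor(fit$scores[, h], oracle$variates$X[, h])), 0.999)
  }
})

test_that("sparsity constraints and score orthogonality hold exactly", {
  st <- tiny_study()
  pm <- assemble_matrix(tiny_results(), st$biomarkers, "all")
  fit <- fit_splsda(pm, n_components = 2, keepX = 5)
  nz <- colSums(fit$loadings != 0)
  expect_equal(unname(nz), c(5, 5))
  expect_equal(sqrt(colSums(fit$loadings^2)), c(comp1 = 1, comp2 = 1),
               tolerance = 1e-9)
  expect_lt(abs(crossprod(fit$scores[, 1], fit$scores[, 2])), 1e-6)
  expect_error(fit_splsda(pm, keepX = 0), "keepX")
  expect_error(fit_splsda(pm, keepX = 1e4), "exceed")
})

test_that("planted informative features are selected and ranked first", {
  set.seed(60)
  n <- 120
  cls <- rep(1:2, each = n / 2)
  X <- matrix(rnorm(n * 20), n)
  X[, 7] <- X[, 7] + 3 * (cls == 1)
  X[, 13] <- X[, 13] - 3 * (cls == 1)
  pm <- tibble::as_tibble(scale(X), .name_repair = ~ paste0("f", 1:20))
  pm$animal_id <- "a"; pm$dim <- rep(1:60, 2); pm$phase <- cls
  attr(pm, "features") <- paste0("f", 1:20)
  class(pm) <- c("phase_matrix", class(pm))
  fit <- fit_splsda(pm, n_components = 2, keepX = 2, labels = cls)
  sel <- rownames(fit$loadings)[fit$loadings[, 1] != 0]
  expect_setequal(sel, c("f7", "f13"))
  expect_true(top_features(fit, 1)$feature %in% c("f7", "f13"))
  expect_equal(nrow(top_features(fit, 0)), 0)
  expect_warning(tf <- top_features(fit, 50), "truncat")
  expect_lte(nrow(tf), 4)
})

test_that("AUROC behaves at its fixed points and under permutation", {
  st <- tiny_study()
  pm <- assemble_matrix(tiny_results(), st$biomarkers, "milk")
  fit <- fit_splsda(pm, 2, 5)

  # identical scores for every sample give chance discrimination
  const_fit <- fit
  const_fit$coef[] <- 0
  expect_equal(auroc_one_vs_rest(const_fit, pm, 1), 0.5)

  # perfectly separated scores give 1: a one-feature model whose feature
  # is the phase-1 indicator
  pm_sep <- tibble::tibble(animal_id = pm$animal_id, dim = pm$dim,
                           phase = pm$phase,
                           f1 = as.numeric(pm$phase == 1))
  attr(pm_sep, "features") <- "f1"
  sep_fit <- structure(
    list(coef = matrix(c(1, -1), 1,
                       dimnames = list("f1", c("class1", "class2"))),
         y_center = c(class1 = 0, class2 = 0),
         features = "f1", classes = c(1, 2)),
    class = "hrdcc_splsda")
  expect_equal(auroc_one_vs_rest(sep_fit, pm_sep, 1), 1.0)

  # permuted labels: mean AUROC 0.5 +/- 0.02 (balanced 120-sample design
  # keeps the Monte-Carlo error of the mean well below the band)
  set.seed(61)
  n <- 120
  Xp <- matrix(rnorm(n * 8), n)
  pmp <- tibble::as_tibble(scale(Xp), .name_repair = ~ paste0("f", 1:8))
  pmp$animal_id <- "a"; pmp$dim <- rep(1:60, 2)
  pmp$phase <- rep(1:2, each = n / 2)
  attr(pmp, "features") <- paste0("f", 1:8)
  class(pmp) <- c("phase_matrix", class(pmp))
  fitp <- fit_splsda(pmp, 2, 5)
  perm <- vapply(1:200, function(i) {
    auroc_one_vs_rest(fitp, pmp, 1, labels = sample(pmp$phase))
  }, numeric(1))
  expect_lt(abs(mean(perm) - 0.5), 0.02)

  expect_error(auroc_one_vs_rest(fit, pm, 99), "not present")
  expect_error(auroc_one_vs_rest(fit, pm, 1, labels = rep(1, nrow(pm))),
               "single class")
})
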