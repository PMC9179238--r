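test_that("asinh transform is anchored, monotone and scatter-exempt", {
  ev <- synthesize_events(c(CD4T = 1), 1200, seed = 31)
  fsc <- ev$`FSC-A`
  cd4_raw <- ev$CD4
  tr <- asinh_transform(ev, cofactor = 150)
  expect_identical(tr$`FSC-A`, fsc)
  expect_equal(asinh_transform(tibble::tibble(CD4 = 0))$CD4, 0)
  expect_equal(asinh_transform(tibble::tibble(CD4 = 150), 150)$CD4,
               asinh(1), tolerance = 1e-12)
  expect_identical(order(tr$CD4), order(cd4_raw))
  expect_error(asinh_transform(ev, cofactor = -1), "cofactor")
})

test_that("auto_threshold finds the valley and falls back on quantiles", {
  set.seed(101)
  x <- c(rnorm(5000, 0), rnorm(5000, 6))
  # oracle: the mixture density minimum between the modes is at 3 (symmetry)
  thr <- auto_threshold(x)
  expect_lt(abs(thr - 3), 0.3)

  set.seed(102)
  u <- rnorm(20000)
  thr_u <- auto_threshold(u, params = list(fallback_quantile = 0.99))
  expect_lt(abs(thr_u - qnorm(0.99)), 0.1)

  expect_error(auto_threshold(rep(1, 1000)), "constant")
  expect_error(auto_threshold(rnorm(100)), "500")
})

test_that("nuisance exclusion recovers viability and flags hopeless samples", {
  ev0 <- synthesize_events(c(CD4T = 1), 20000,
                           nuisance_fractions = list(debris = 0, doublet = 0),
                           viability = 1, seed = 32)
  nz0 <- exclude_nuisance(asinh_transform(ev0))
  expect_equal(nz0$viability, 100, tolerance = 0.1)
  expect_gte(nrow(nz0$events), 0.99 * nrow(ev0))

  ev <- synthesize_events(c(CD4T = 1), 30000,
                          nuisance_fractions = list(debris = 0.05,
                                                    doublet = 0.03),
                          viability = 0.7, seed = 33)
  nz <- exclude_nuisance(asinh_transform(ev))
  expect_lt(abs(nz$viability - 70), 1.5)
  # a handful of nuisance events may survive in gate-overlap tails
  expect_gt(mean(nz$events$.label == "CD4T"), 0.995)

  # pure debris cannot be gated
  dbg <- asinh_transform(ev)
  dbg <- dbg[dbg$.label == "debris", ]
  attr(dbg, "sample_id") <- "pure_debris"
  expect_error(exclude_nuisance(dbg), "flagged")
  expect_error(exclude_nuisance(ev[0, ]), "empty")
})

test_that("quadrant and interval nodes partition events exactly", {
  tree <- gating_tree("blood")
  node <- tree$nodes$monoquad
  set.seed(34)
  n <- 40000
  grp <- sample(1:4, n, replace = TRUE)
  ev <- tibble::tibble(
    CD14 = ifelse(grp %in% c(1, 2), rnorm(n, 4.3, 0.3), rnorm(n, 0.6, 0.3)),
    CD16 = ifelse(grp %in% c(2, 3), rnorm(n, 4.2, 0.3), rnorm(n, 0.6, 0.3)))
  attr(ev, "transformed") <- TRUE
  kids <- gate_node(ev, node, "reference")
  expect_setequal(names(kids), c("cM", "intM", "ncM", "mono_dn"))
  tot <- sum(vapply(kids, nrow, 1L))
  expect_equal(tot, n) # every event in exactly one quadrant
  for (k in kids) expect_lt(abs(nrow(k) / n - 0.25), 0.01)

  # all-double-negative input lands entirely in the nn quadrant
  lo <- tibble::tibble(CD14 = rnorm(1000, 0.5, 0.2),
                       CD16 = rnorm(1000, 0.5, 0.2))
  attr(lo, "transformed") <- TRUE
  kids_lo <- gate_node(lo, node, "reference")
  expect_equal(nrow(kids_lo$mono_dn), 1000)

  # milk tree pools both CD16+ quadrants into ncMac
  mtree <- gating_tree("milk")
  kids_m <- gate_node(ev, mtree$nodes$monoquad, "reference")
  expect_equal(nrow(kids_m$ncMac), sum(grp %in% c(2, 3)), tolerance = 0.02)
  expect_error(gate_node(ev, list(rule = "nope", channels = "CD14",
                                  children = c(pos = "a", neg = "b"),
                                  threshold = 1), "reference"),
               "unknown")
})

test_that("full hierarchy recovers generator truth on a synthetic sample", {
  st <- tiny_study()
  blood_id <- st$samples$sample_id[st$samples$matrix == "blood"][1]
  ev <- asinh_transform(events_for_sample(st, blood_id, n_events = 30000))
  tree <- gating_tree("blood", tiny_config()$gates)
  res <- run_hrdcc(ev, tree, "reference", keep_assignments = TRUE)

  row <- st$samples[st$samples$sample_id == blood_id, ]
  state <- st$states[st$states$animal_id == row$animal_id &
                       st$states$dim == row$dim &
                       st$states$matrix == "blood", ]
  lymph_true <- sum(state[c("NK", "gdT", "CD4T", "CD8T", "B", "lymph_other")])
  truth_pct <- c(
    granulocytes = 100 * sum(state[c("neut", "eos", "imm_gran")]),
    lymphocytes = 100 * lymph_true,
    CD4T = 100 * state$CD4T / lymph_true,
    gdT = 100 * state$gdT / lymph_true)
  for (nd in names(truth_pct)) {
    expect_lt(abs(res$percent[res$node == nd] - truth_pct[[nd]]), 1.5)
  }
  # three main populations partition CD45+
  main <- res$percent[res$node %in% c("granulocytes", "monocytes",
                                      "lymphocytes")]
  expect_equal(sum(main), 100, tolerance = 0.01)

  # per-population F1 against truth labels
  a <- attr(res, "assignments")
  cellish <- !a$truth %in% c("debris", "doublet", "dead")
  f1 <- population_f1(a$truth[cellish], a$assigned[cellish])
  expect_true(all(f1$f1 >= 0.95))
})

test_that("pure-lymphocyte samples gate to 100% lymphocytes", {
  ev <- synthesize_events(c(CD4T = 0.5, CD8T = 0.3, B = 0.2), 20000,
                          nuisance_fractions = list(debris = 0, doublet = 0),
                          viability = 1, seed = 35)
  res <- run_hrdcc(asinh_transform(ev), gating_tree("blood"), "reference")
  expect_equal(res$percent[res$node == "lymphocytes"], 100, tolerance = 0.2)
  expect_lt(res$percent[res$node == "granulocytes"], 0.2)
  expect_lt(res$percent[res$node == "monocytes"], 0.2)
})

test_that("milk samples before 50 DIM yield null MEC but all other nodes", {
  st <- tiny_study()
  early <- st$samples$sample_id[st$samples$matrix == "milk" &
                                  st$samples$dim < 50][1]
  ev <- asinh_transform(events_for_sample(st, early, n_events = 12000))
  res <- run_hrdcc(ev, gating_tree("milk", tiny_config()$gates), "reference")
  expect_true(is.na(res$percent[res$node == "MEC"]))
  other <- res$percent[res$node != "MEC"]
  expect_true(all(is.finite(other)))
  # 9 reported milk subsets + 3 main populations + MEC + viability
  expect_equal(nrow(res), 14)

  ev$CD45 <- NULL
  expect_error(run_hrdcc(ev, gating_tree("milk"), "reference"), "CD45")
})

test_that("reference and auto modes agree on well-separated samples", {
  st <- tiny_study()
  sid <- st$samples$sample_id[st$samples$matrix == "blood"][2]
  ev <- asinh_transform(events_for_sample(st, sid, n_events = 30000))
  tree <- gating_tree("blood", tiny_config()$gates)
  ref <- run_hrdcc(ev, tree, "reference")
  aut <- run_hrdcc(ev, tree, "auto")
  d <- abs(ref$percent - aut$percent)
  expect_lt(max(d, na.rm = TRUE), 1)
})

test_that("collapsing signature separation destroys recoverability", {
  frac <- c(CD4T = 0.3, B = 0.7)
  run_f1 <- function(sep) {
    ev <- synthesize_events(frac, 20000,
                            nuisance_fractions = list(debris = 0,
                                                      doublet = 0),
                            viability = 1, separation = sep, seed = 36)
    res <- run_hrdcc(asinh_transform(ev), gating_tree("blood"),
                     "reference", keep_assignments = TRUE)
    a <- attr(res, "assignments")
    f1 <- population_f1(a$truth, a$assigned)
    mean(f1$f1)
  }
  expect_gt(run_f1(1), 0.95)
  expect_lt(run_f1(0), 0.6)
})

test_that("gate comparison is exact on identical inputs and validates keys", {
  res <- tiny_results()
  ref <- dplyr::filter(res, sample_id %in% unique(res$sample_id)[1:4])
  cmp <- compare_gating(ref, ref)
  expect_equal(cmp$r, 1)
  expect_equal(cmp$slope, 1)
  expect_equal(cmp$intercept, 0, tolerance = 1e-10)
  expect_equal(cmp$n_gates,
               sum(is.finite(ref$percent)))
  other <- dplyr::filter(res, sample_id %in% unique(res$sample_id)[2:5])
  expect_error(compare_gating(ref, other), "different samples")
})

test_that("denominator conventions never reorder siblings", {
  res <- tiny_results()
  subsets <- dplyr::filter(res, parent == "lymphocytes",
                           is.finite(percent))
  per_sample <- split(subsets, subsets$sample_id)
  for (s in per_sample) {
    expect_identical(order(s$percent), order(s$percent_cd45))
  }
})
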