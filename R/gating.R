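#' Arcsinh-transform marker channels
#'
#' Applies `asinh(x / cofactor)` to every non-scatter channel. Scatter
#' channels (FSC/SSC) are left on their linear scale.
#'
#' @param events Event matrix tibble.
#' @param cofactor Single cofactor or named vector per channel.
#' @return The transformed event matrix (attribute `transformed` set).
#' @export
asinh_transform <- function(events, cofactor = attr(events, "cofactor") %||% 150) {
  if (any(cofactor <= 0)) abort("cofactors must be > 0")
  if (isTRUE(attr(events, "transformed"))) return(events)
  chans <- setdiff(event_channels(events), c("FSC-A", "FSC-H", "SSC-A"))
  for (ch in chans) {
    cf <- if (length(cofactor) > 1) cofactor[[ch]] else cofactor
    if (is.null(cf) || cf <= 0) abort(sprintf("no valid cofactor for %s", ch))
    events[[ch]] <- asinh(events[[ch]] / cf)
  }
  attr(events, "transformed") <- TRUE
  events
}

#' Data-driven threshold between two intensity modes
#'
#' Kernel-density valley detection: the threshold is the density minimum
#' between the two highest well-separated modes (Silverman bandwidth).
#' If the distribution is unimodal the configured quantile is returned
#' instead. Deterministic given the values and parameters.
#'
#' @param values Numeric vector (>= 500 values for the valley method).
#' @param method `"density-valley"` or `"quantile-fallback"`.
#' @param params List: `fallback_quantile` (default 0.99), `min_sep_frac`
#'   (minimum mode separation as a fraction of the data range, default
#'   0.08), `bw` (bandwidth rule, default `"nrd0"`).
#' @return Numeric threshold.
#' @export
auto_threshold <- function(values, method = c("density-valley",
                                              "quantile-fallback"),
                           params = list()) {
  method <- match.arg(method)
  values <- values[is.finite(values)]
  if (length(unique(values)) < 2) abort("constant input: no threshold exists")
  q <- params$fallback_quantile %||% 0.99
  if (method == "quantile-fallback") return(unname(quantile(values, q)))
  if (length(values) < 500) {
    abort("density-valley thresholding needs >= 500 values")
  }
  cuts <- density_cuts(values, n_groups = 2,
                       min_sep_frac = params$min_sep_frac %||% 0.08,
                       bw = params$bw %||% "nrd0")
  if (is.null(cuts)) unname(quantile(values, q)) else cuts
}

# Valleys between the `n_groups` highest well-separated KDE modes.
# A candidate mode only counts if the density dips to below `depth_ratio`
# of the smaller peak between it and every already-accepted mode, which
# rejects spurious tail bumps of an essentially unimodal channel.
# Returns n_groups - 1 cut points, or NULL if too few modes are found.
density_cuts <- function(values, n_groups = 2, min_sep_frac = 0.08,
                         bw = "nrd0", depth_ratio = 0.6,
                         min_height_frac = 0.015, adjust = 2,
                         min_mass = 0.01) {
  d <- density(values, bw = bw, adjust = adjust, n = 512)
  y <- d$y
  loc_max <- which(diff(sign(diff(y))) == -2) + 1
  if (y[1] > y[2]) loc_max <- c(1, loc_max)
  if (y[512] > y[511]) loc_max <- c(loc_max, 512)
  # ignore stray-event spikes far below the dominant mode; the floor grows
  # on small parents where even single events make visible bumps
  floor_frac <- max(min_height_frac, 15 / length(values))
  loc_max <- loc_max[y[loc_max] >= floor_frac * max(y)]
  if (length(loc_max) < 2) return(NULL)
  min_sep <- min_sep_frac * diff(range(d$x))
  ord <- loc_max[order(y[loc_max], decreasing = TRUE)]
  keep <- integer()
  for (i in ord) {
    if (length(keep) == n_groups) break
    if (length(keep)) {
      if (any(abs(d$x[i] - d$x[keep]) < min_sep)) next
      deep <- vapply(keep, function(j) {
        seg <- seq(min(i, j), max(i, j))
        min(y[seg]) < depth_ratio * min(y[i], y[j])
      }, logical(1))
      if (!all(deep)) next
    }
    keep <- c(keep, i)
  }
  if (length(keep) < n_groups) return(NULL)
  keep <- sort(keep)
  cuts <- vapply(seq_len(n_groups - 1), function(k) {
    lo <- keep[k]; hi <- keep[k + 1]
    seg <- seq(lo, hi)
    d$x[seg[which.min(y[seg])]]
  }, numeric(1))
  # every resulting group must hold a non-trivial share of the events,
  # otherwise the "mode" was a tail sampling artifact
  shares <- diff(c(0, vapply(cuts, function(ct) mean(values <= ct),
                             numeric(1)), 1))
  if (any(shares < min_mass)) return(NULL)
  cuts
}

#' Remove debris, doublets and dead cells
#'
#' Debris: FSC-A and SSC-A jointly below the debris gate. Doublets:
#' FSC-A/FSC-H ratio above the doublet gate. Dead: viability-dye signal
#' above the live/dead threshold (fixed in reference mode, density-valley
#' in auto mode). Viability is reported as live singlets as a percentage of
#' non-debris singlets.
#'
#' @param events Transformed event matrix.
#' @param rules List with `debris_fsc`, `debris_ssc`, `doublet_ratio`,
#'   `viability` (fixed threshold) as in [reference_gates()].
#' @param mode `"reference"` (fixed viability threshold) or `"auto"`.
#' @return List with `events` (clean live singlets) and `viability`
#'   (percentage).
#' @export
exclude_nuisance <- function(events, rules = reference_gates(),
                             mode = c("reference", "auto")) {
  mode <- match.arg(mode)
  assert_cols(events, c("FSC-A", "FSC-H", "SSC-A", "Viability"),
              "event matrix")
  if (nrow(events) == 0) abort("empty sample: no events to gate")
  fsc <- events$`FSC-A`
  debris <- fsc < rules$debris_fsc & events$`SSC-A` < rules$debris_ssc
  singlet <- (fsc / events$`FSC-H`) <= rules$doublet_ratio
  keep1 <- !debris & singlet
  if (sum(keep1) < max(50, 0.01 * nrow(events))) {
    abort(sprintf("sample %s flagged: all but %d events removed as debris/doublets",
                  attr(events, "sample_id") %||% "?", sum(keep1)))
  }
  viab_vals <- events$Viability[keep1]
  thr <- if (mode == "reference" || sum(keep1) < 500) rules$viability else {
    density_cuts(viab_vals, n_groups = 2) %||% rules$viability
  }
  live <- keep1 & events$Viability < thr
  viability <- 100 * sum(live) / sum(keep1)
  if (!any(live)) {
    abort(sprintf("sample %s flagged: no live events",
                  attr(events, "sample_id") %||% "?"))
  }
  list(events = events[live, ], viability = viability,
       viability_threshold = thr)
}

#' Build the HRDCC gating tree
#'
#' The milk and blood trees share every node except the monocyte/macrophage
#' branch (blood: cM/intM/ncM; milk: cMac and ncMac, the latter pooling the
#' CD16+ quadrants per the CD14+/- CD16+ definition) and the milk-only MEC
#' branch (panCK+ among CD45- cells).
#'
#' @param matrix `"milk"` or `"blood"`.
#' @param gates Fixed reference thresholds, see [reference_gates()].
#' @return A list of class `gating_tree`.
#' @export
gating_tree <- function(matrix = c("milk", "blood"),
                        gates = reference_gates()) {
  matrix <- match.arg(matrix)
  n <- list()
  add <- function(name, parent, rule, channels, threshold, children,
                  fallback_quantile = 0.995) {
    n[[name]] <<- list(name = name, parent = parent, rule = rule,
                       channels = channels, threshold = threshold,
                       children = children,
                       fallback_quantile = fallback_quantile)
  }
  add("cd45", "root", "threshold-above", "CD45", gates$cd45,
      c(pos = "CD45pos", neg = "CD45neg"), fallback_quantile = 0.005)
  add("ssc", "CD45pos", "interval", "SSC-A", gates$ssc_cuts,
      c("lymphocytes", "monomac", "granulocytes"))
  add("eos", "granulocytes", "autofluorescence-high", "AF", gates$af,
      c(pos = "eos", neg = "gran_noneos"))
  add("imm", "gran_noneos", "threshold-below", "CD11b", gates$cd11b,
      c(pos = "imm_gran", neg = "neut"), fallback_quantile = 0.02)
  if (matrix == "blood") {
    add("monoquad", "monomac", "quadrant", c("CD14", "CD16"),
        c(gates$cd14, gates$cd16),
        c(pn = "cM", pp = "intM", np = "ncM", nn = "mono_dn"))
  } else {
    add("monoquad", "monomac", "quadrant", c("CD14", "CD16"),
        c(gates$cd14, gates$cd16),
        c(pn = "cMac", pp = "ncMac", np = "ncMac", nn = "mac_dn"))
  }
  add("nk", "lymphocytes", "threshold-above", "CD335", gates$cd335,
      c(pos = "NK", neg = "l_rest1"))
  add("gdt", "l_rest1", "threshold-above", "gdTCR", gates$gdtcr,
      c(pos = "gdT", neg = "l_rest2"))
  add("cd4", "l_rest2", "threshold-above", "CD4", gates$cd4,
      c(pos = "CD4T", neg = "l_rest3"))
  add("cd8", "l_rest3", "threshold-above", "CD8", gates$cd8,
      c(pos = "CD8T", neg = "l_rest4"))
  add("b", "l_rest4", "threshold-above", "CD21", gates$cd21,
      c(pos = "B", neg = "lymph_other"))
  if (matrix == "milk") {
    add("mec", "CD45neg", "threshold-above", "panCK", gates$panck,
        c(pos = "MEC", neg = "cd45neg_other"))
  }
  structure(list(matrix = matrix, nodes = n, gates = gates),
            class = "gating_tree")
}

#' @export
print.gating_tree <- function(x, ...) {
  cat("<gating_tree>", x$matrix, "-", length(x$nodes), "nodes\n")
  for (nd in x$nodes) {
    cat(sprintf("  %-9s <- %-12s %s on %s\n", nd$name, nd$parent, nd$rule,
                paste(nd$channels, collapse = "/")))
  }
  invisible(x)
}

# Resolve the threshold(s) a node uses for a given parent event subset.
# Auto mode places each cut at the density valley; when a channel is
# unimodal (or the parent too small) the template threshold anchors the
# gate, mirroring template-driven automated gating.
node_thresholds <- function(node, values_list, mode) {
  if (mode == "reference") return(node$threshold)
  out <- numeric(length(values_list))
  for (i in seq_along(values_list)) {
    v <- values_list[[i]]
    if (length(v) < 500 || length(unique(v)) < 2) {
      out[i] <- node$threshold[i]
    } else if (node$rule == "interval") {
      cuts <- density_cuts(v, n_groups = 3)
      return(if (is.null(cuts)) node$threshold else cuts)
    } else {
      cut <- density_cuts(v, n_groups = 2)
      out[i] <- if (is.null(cut)) node$threshold[i] else cut
    }
  }
  out
}

# core rule evaluation on a numeric matrix subset; returns a list of
# logical vectors (one per child) over the parent rows
apply_rule <- function(node, m, idx, thr) {
  ch <- node$channels
  switch(node$rule,
    "threshold-above" = ,
    "autofluorescence-high" = {
      v <- m[idx, ch[1]]
      list(pos = v > thr[1], neg = v <= thr[1])
    },
    "threshold-below" = {
      v <- m[idx, ch[1]]
      list(pos = v < thr[1], neg = v >= thr[1])
    },
    "interval" = {
      v <- m[idx, ch[1]]
      list(v <= thr[1], v > thr[1] & v <= thr[2], v > thr[2])
    },
    "quadrant" = {
      a <- m[idx, ch[1]] > thr[1]
      b <- m[idx, ch[2]] > thr[2]
      list(pn = a & !b, pp = a & b, np = !a & b, nn = !a & !b)
    },
    abort(sprintf("unknown gating rule: %s", node$rule))
  )
}

#' Apply one gating node to an event matrix
#'
#' Partitions the events per the node's rule. Quadrant nodes return four
#' subsets (possibly pooled when two quadrants map to the same child, as
#' for milk ncMac). Returns `NULL` for a node whose channel is absent and
#' tolerated (panCK before 50 DIM).
#'
#' @param events Transformed event matrix (the node's parent population).
#' @param node A node of a [gating_tree()].
#' @param mode `"reference"` or `"auto"`.
#' @return Named list of child event matrices.
#' @export
gate_node <- function(events, node, mode = c("reference", "auto")) {
  mode <- match.arg(mode)
  missing_ch <- setdiff(node$channels, names(events))
  if (length(missing_ch)) {
    if (identical(node$channels, "panCK")) return(NULL)
    abort(sprintf("missing channel(s): %s", paste(missing_ch, collapse = ", ")))
  }
  m <- as.matrix(events[node$channels])
  colnames(m) <- node$channels
  idx <- seq_len(nrow(events))
  thr <- node_thresholds(node, lapply(node$channels,
                                      function(ch) m[, ch]), mode)
  masks <- apply_rule(node, m, idx, thr)
  children <- unique(node$children)
  out <- setNames(vector("list", length(children)), children)
  for (child in children) {
    which_masks <- which(node$children == child)
    mask <- Reduce(`|`, masks[which_masks])
    out[[child]] <- events[mask, ]
  }
  out
}

#' Run the full HRDCC gating hierarchy on one sample
#'
#' Transforms the events if needed, excludes nuisance events, walks the
#' gating tree in the requested mode and reports population percentages
#' under the percent-of-parent convention, with percent-of-CD45+ emitted
#' alongside. The three main populations always sum to 100% of CD45+.
#'
#' @param events Event matrix (raw or transformed).
#' @param tree A [gating_tree()]; must match the sample matrix.
#' @param mode `"reference"` (fixed thresholds from the configuration's
#'   signature midpoints) or `"auto"` (density-valley placement).
#' @param keep_assignments Attach the per-event terminal assignment as an
#'   attribute (used for truth-label validation).
#' @return Tibble of class `hrdcc_result`: `sample_id`, `matrix`, `mode`,
#'   `node`, `parent`, `count`, `percent`, `percent_cd45`.
#' @export
run_hrdcc <- function(events, tree, mode = c("reference", "auto"),
                      keep_assignments = FALSE) {
  mode <- match.arg(mode)
  required <- setdiff(hrdcc_panel(), "panCK")
  missing_ch <- setdiff(required, event_channels(events))
  if (length(missing_ch)) {
    abort(sprintf("missing required channel(s): %s",
                  paste(missing_ch, collapse = ", ")))
  }
  sample_id <- attr(events, "sample_id") %||% "sample"
  events <- asinh_transform(events)
  nz <- exclude_nuisance(events, tree$gates, mode)
  ev <- nz$events
  n_all <- nrow(ev)

  # walk the tree keeping event index sets per population
  pops <- list(root = seq_len(n_all))
  m <- as.matrix(ev[setdiff(event_channels(ev), c("FSC-H"))])
  assignment <- rep(NA_character_, n_all)
  for (node in tree$nodes) {
    parent_idx <- pops[[node$parent]]
    if (is.null(parent_idx)) next
    missing_ch <- setdiff(node$channels, colnames(m))
    if (length(missing_ch)) {
      if (identical(node$channels, "panCK")) {
        pops[[node$children[["pos"]]]] <- NULL
        next
      }
      abort(sprintf("missing channel(s): %s",
                    paste(missing_ch, collapse = ", ")))
    }
    vals <- lapply(node$channels, function(ch) m[parent_idx, ch])
    thr <- node_thresholds(node, vals, mode)
    masks <- apply_rule(node, m, parent_idx, thr)
    for (child in unique(node$children)) {
      mask <- Reduce(`|`, masks[which(node$children == child)])
      pops[[child]] <- parent_idx[mask]
    }
  }
  terminals <- terminal_populations(tree$matrix)
  for (tp in c(terminals, "mono_dn", "mac_dn")) {
    if (!is.null(pops[[tp]])) assignment[pops[[tp]]] <- tp
  }

  cnt <- function(p) if (is.null(pops[[p]])) NA_integer_ else length(pops[[p]])
  n_cd45 <- cnt("CD45pos")
  mono_name <- if (tree$matrix == "blood") "monocytes" else "macrophages"
  rows <- list()
  push <- function(node, parent, count, denom) {
    pct <- if (is.na(count) || denom == 0) NA_real_ else 100 * count / denom
    pcd45 <- if (is.na(count) || n_cd45 == 0) NA_real_ else
      100 * count / n_cd45
    rows[[length(rows) + 1]] <<- tibble::tibble(
      node = node, parent = parent, count = count,
      percent = pct, percent_cd45 = pcd45)
  }
  push("granulocytes", "CD45pos", cnt("granulocytes"), n_cd45)
  push(mono_name, "CD45pos", cnt("monomac"), n_cd45)
  push("lymphocytes", "CD45pos", cnt("lymphocytes"), n_cd45)
  n_gran <- cnt("granulocytes")
  push("eos", "granulocytes", cnt("eos"), n_gran)
  push("imm_gran", "granulocytes", cnt("imm_gran"), n_gran)
  n_mono <- cnt("monomac")
  for (sub in setdiff(reported_subsets(tree$matrix),
                      c("eos", "imm_gran", "NK", "gdT", "CD4T", "CD8T", "B"))) {
    push(sub, mono_name, cnt(sub), n_mono)
  }
  n_lymph <- cnt("lymphocytes")
  for (sub in c("NK", "gdT", "CD4T", "CD8T", "B")) {
    push(sub, "lymphocytes", cnt(sub), n_lymph)
  }
  if (tree$matrix == "milk") {
    n_cd45neg <- cnt("CD45neg")
    mec_count <- cnt("MEC")
    push("MEC", "CD45neg", mec_count,
         if (is.na(mec_count)) 0L else n_cd45neg)
  }
  rows[[length(rows) + 1]] <- tibble::tibble(
    node = "viability", parent = "singlets", count = n_all,
    percent = nz$viability, percent_cd45 = NA_real_)
  out <- dplyr::bind_rows(rows)
  out <- tibble::add_column(out, sample_id = sample_id,
                            matrix = tree$matrix, mode = mode,
                            .before = 1)
  if (keep_assignments) {
    attr(out, "assignments") <- tibble::tibble(
      truth = if (".label" %in% names(ev)) ev$.label else NA_character_,
      assigned = assignment)
  }
  class(out) <- c("hrdcc_result", class(out))
  out
}

#' Gate every sample of a simulated study
#'
#' Regenerates each sample's events deterministically and runs the gating
#' hierarchy in one or both modes, streaming sample by sample so event-level
#' data never accumulate in memory.
#'
#' @param study An `hrdcc_study` from [simulate_study()].
#' @param mode `"reference"`, `"auto"` or `"both"`.
#' @param n_events Optional override of events per sample.
#' @param sample_ids Optional subset of samples to gate.
#' @return Long tibble of HRDCC results with `animal_id` and `dim` joined.
#' @export
run_study_hrdcc <- function(study, mode = c("both", "reference", "auto"),
                            n_events = NULL, sample_ids = NULL) {
  mode <- match.arg(mode)
  modes <- if (mode == "both") c("reference", "auto") else mode
  trees <- list(milk = gating_tree("milk", study$config$gates),
                blood = gating_tree("blood", study$config$gates))
  ids <- sample_ids %||% study$samples$sample_id
  res <- vector("list", length(ids) * length(modes))
  k <- 0
  for (sid in ids) {
    ev <- events_for_sample(study, sid, n_events = n_events)
    ev <- asinh_transform(ev)
    mat <- study$samples$matrix[study$samples$sample_id == sid]
    for (md in modes) {
      k <- k + 1
      res[[k]] <- run_hrdcc(ev, trees[[mat]], md)
    }
  }
  out <- dplyr::bind_rows(res)
  out <- dplyr::left_join(
    out, dplyr::select(study$samples, "sample_id", "animal_id", "dim"),
    by = "sample_id")
  class(out) <- c("hrdcc_result", class(out))
  out
}

#' Compare two gating result sets
#'
#' Pools all paired (sample x node) percentages and regresses one mode on
#' the other, the agreement analysis used to validate automated against
#' reference gating.
#'
#' @param results_a,results_b `hrdcc_result` tibbles over the same samples
#'   and nodes (e.g. reference and auto mode).
#' @return One-row tibble of class `gate_comparison`: `n_gates`, `r`,
#'   `slope`, `intercept`, `p_value`.
#' @export
compare_gating <- function(results_a, results_b) {
  key <- c("sample_id", "node")
  a <- dplyr::select(tibble::as_tibble(results_a), dplyr::all_of(key),
                     pct_a = "percent")
  b <- dplyr::select(tibble::as_tibble(results_b), dplyr::all_of(key),
                     pct_b = "percent")
  if (nrow(a) != nrow(b) ||
      nrow(dplyr::anti_join(a[key], b[key], by = key)) > 0 ||
      nrow(dplyr::anti_join(b[key], a[key], by = key)) > 0) {
    abort("result sets cover different samples or nodes")
  }
  j <- dplyr::inner_join(a, b, by = key)
  j <- j[is.finite(j$pct_a) & is.finite(j$pct_b), ]
  if (nrow(j) < 3) abort("need at least 3 paired gates")
  fit <- lm(pct_b ~ pct_a, data = j)
  # identical result sets give a perfect fit; that is a valid input here
  s <- suppressWarnings(summary(fit))
  out <- tibble::tibble(
    n_gates = nrow(j),
    r = cor(j$pct_a, j$pct_b),
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    p_value = unname(s$coefficients[2, 4])
  )
  class(out) <- c("gate_comparison", class(out))
  out
}

#' @export
glance.gate_comparison <- function(x, ...) tibble::as_tibble(x)

#' Per-population precision/recall/F1 against truth labels
#'
#' @param truth,assigned Character vectors of true and assigned terminal
#'   population labels (same length; events with `NA` assignment count as
#'   misses).
#' @return Tibble `population`, `precision`, `recall`, `f1`.
#' @export
population_f1 <- function(truth, assigned) {
  pops <- sort(unique(truth[!is.na(truth)]))
  purrr::map_dfr(pops, function(p) {
    tp <- sum(truth == p & assigned == p, na.rm = TRUE)
    fp <- sum(truth != p & assigned == p, na.rm = TRUE)
    fn <- sum(truth == p & (is.na(assigned) | assigned != p))
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    tibble::tibble(population = p, precision = prec, recall = rec,
                   f1 = if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec))
  })
}
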