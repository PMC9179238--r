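#' Lactation phase of a DIM
#'
#' Six 50-day bins: 1-50, 51-100, 101-150, 151-200, 201-250, 251-305.
#' DIMs above 305 clamp to phase 6 with a warning.
#'
#' @param dim Integer vector of days in milk (>= 1).
#' @return Integer phase labels in 1..6.
#' @export
bin_phases <- function(dim) {
  if (any(dim < 1)) abort("DIM must be >= 1")
  if (any(dim > 305)) warn("DIM > 305 clamped to phase 6")
  pmin(ceiling(dim / 50), 6L)
}

#' Assemble the samples-by-features phase matrix
#'
#' Joins milk and blood HRDCC percentages of the same visit with the
#' serum biomarkers, drops MEC (never a clustering feature) and rows with
#' missing values, standardises every feature to mean 0 / SD 1 and labels
#' each row with its 50-DIM lactation phase.
#'
#' @param results Long `hrdcc_result` tibble (a single mode; if both modes
#'   are present the reference mode is used).
#' @param biomarkers Long biomarker tibble (`animal_id`, `dim`, `analyte`,
#'   `value`); required for scopes `"all"` and `"lab"`.
#' @param scope `"all"`, `"milk"`, `"blood"` or `"lab"`.
#' @return Tibble of class `phase_matrix`: `animal_id`, `dim`, `phase`,
#'   then standardised feature columns (attribute `features`).
#' @export
assemble_matrix <- function(results, biomarkers = NULL,
                            scope = c("all", "milk", "blood", "lab")) {
  scope <- match.arg(scope)
  res <- tibble::as_tibble(results)
  if ("mode" %in% names(res)) {
    res <- dplyr::filter(res, .data$mode == "reference" |
                           !any(res$mode == "reference"))
  }
  res <- dplyr::filter(res, .data$node != "MEC")
  wide_for <- function(mat) {
    res |>
      dplyr::filter(.data$matrix == mat) |>
      dplyr::transmute(.data$animal_id, .data$dim,
                       feature = paste(mat, .data$node, sep = "_"),
                       value = .data$percent) |>
      tidyr::pivot_wider(names_from = "feature", values_from = "value")
  }
  parts <- list()
  if (scope %in% c("all", "milk")) parts$milk <- wide_for("milk")
  if (scope %in% c("all", "blood")) parts$blood <- wide_for("blood")
  if (scope %in% c("all", "lab")) {
    if (is.null(biomarkers)) abort("biomarkers required for this scope")
    parts$lab <- biomarkers |>
      tidyr::pivot_wider(names_from = "analyte", values_from = "value")
  }
  joined <- purrr::reduce(parts, function(a, b) {
    dplyr::full_join(a, b, by = c("animal_id", "dim"))
  })
  features <- setdiff(names(joined), c("animal_id", "dim"))
  complete <- stats::complete.cases(joined[features])
  if (any(!complete)) {
    rlang::inform(sprintf("dropped %d incomplete visit row(s)",
                          sum(!complete)))
  }
  joined <- joined[complete, ]
  X <- scale(as.matrix(joined[features]))
  if (any(!is.finite(X))) abort("constant feature column cannot be standardised")
  out <- tibble::as_tibble(joined[c("animal_id", "dim")])
  out$phase <- bin_phases(out$dim)
  out <- dplyr::bind_cols(out, tibble::as_tibble(X))
  attr(out, "features") <- features
  attr(out, "scope") <- scope
  attr(out, "center") <- attr(X, "scaled:center")
  attr(out, "scale") <- attr(X, "scaled:scale")
  class(out) <- c("phase_matrix", class(out))
  out
}

phase_features <- function(pm) {
  attr(pm, "features") %||%
    setdiff(names(pm), c("animal_id", "dim", "phase"))
}

#' Principal component analysis of a phase matrix
#'
#' Singular-value decomposition of the standardised feature matrix;
#' explained-variance percentages are non-increasing and sum to 100 over
#' all components.
#'
#' @param pm A [assemble_matrix()] phase matrix.
#' @param n_components Number of components to retain (default: all).
#' @return Object of class `hrdcc_pca` with `scores`, `loadings`,
#'   `explained_variance` and the sample metadata.
#' @export
fit_pca <- function(pm, n_components = NULL) {
  feats <- phase_features(pm)
  X <- as.matrix(pm[feats])
  if (any(apply(X, 2, sd) == 0)) abort("constant column in phase matrix")
  sv <- svd(X)
  ev <- sv$d^2 / sum(sv$d^2) * 100
  k <- n_components %||% length(sv$d)
  if (k > length(sv$d)) abort("n_components exceeds matrix rank")
  scores <- sv$u[, seq_len(k), drop = FALSE] %*%
    diag(sv$d[seq_len(k)], k, k)
  colnames(scores) <- paste0("PC", seq_len(k))
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  dimnames(loadings) <- list(feats, paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[seq_len(k)],
                 all_explained = ev,
                 meta = pm[c("animal_id", "dim", "phase")]),
            class = "hrdcc_pca")
}

#' @export
print.hrdcc_pca <- function(x, ...) {
  cat("<hrdcc_pca>", nrow(x$scores), "samples,",
      ncol(x$scores), "components;",
      "PC1", sprintf("%.1f%%", x$explained_variance[1]), "\n")
  invisible(x)
}

#' @export
tidy.hrdcc_pca <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "component",
                        values_to = "loading")
}

#' @export
glance.hrdcc_pca <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(x$explained_variance)),
                 explained_variance = x$explained_variance)
}

#' @export
autoplot.hrdcc_pca <- function(object, ...) {
  df <- dplyr::bind_cols(object$meta,
                         tibble::as_tibble(object$scores[, 1:2]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = factor(.data$phase))) +
    ggplot2::geom_point() +
    ggplot2::labs(colour = "phase",
                  x = sprintf("PC1 (%.1f%%)", object$explained_variance[1]),
                  y = sprintf("PC2 (%.1f%%)", object$explained_variance[2])) +
    ggplot2::theme_minimal()
}

#' Sparse PLS discriminant analysis
#'
#' NIPALS-style sparse PLS on a dummy-coded class matrix: per component the
#' X-loading is soft-thresholded to retain the `keepX` largest-magnitude
#' entries, normalised to unit length, and iterated to convergence
#' (tolerance 1e-6, at most 500 iterations); X and Y are then deflated by
#' regression on the component scores, which makes successive scores
#' mutually orthogonal.
#'
#' @param pm A [assemble_matrix()] phase matrix.
#' @param n_components Number of latent components (default 2).
#' @param keepX Number of features retained per component (default 5;
#'   `keepX = p` gives dense PLS-DA).
#' @param labels Class labels (default: the phase column).
#' @return Object of class `hrdcc_splsda`.
#' @export
fit_splsda <- function(pm, n_components = 2, keepX = 5, labels = NULL) {
  feats <- phase_features(pm)
  X <- as.matrix(pm[feats])
  y <- labels %||% pm$phase
  classes <- sort(unique(y))
  if (length(classes) < 2) abort("need at least 2 classes")
  if (keepX < 1) abort("keepX must be >= 1")
  p <- ncol(X)
  if (keepX > p) abort("keepX cannot exceed the number of features")
  n <- nrow(X)
  Y <- matrix(0, n, length(classes),
              dimnames = list(NULL, paste0("class", classes)))
  Y[cbind(seq_len(n), match(y, classes))] <- 1
  y_center <- colMeans(Y)
  Y <- sweep(Y, 2, y_center)
  X0ss <- sum(X^2)
  Xh <- X; Yh <- Y
  H <- n_components
  W <- matrix(0, p, H, dimnames = list(feats, paste0("comp", seq_len(H))))
  P <- matrix(0, p, H)
  Qm <- matrix(0, ncol(Y), H)
  Tm <- matrix(0, n, H, dimnames = list(NULL, paste0("comp", seq_len(H))))
  expl <- numeric(H)
  for (h in seq_len(H)) {
    u <- Yh[, which.max(apply(Yh, 2, var))]
    w_old <- rep(0, p)
    for (it in seq_len(500)) {
      w <- drop(crossprod(Xh, u))
      if (keepX < p) {
        lambda <- sort(abs(w), decreasing = TRUE)[keepX + 1]
        w <- sign(w) * pmax(abs(w) - lambda, 0)
      }
      nw <- sqrt(sum(w^2))
      if (nw == 0) abort("degenerate component: all loadings thresholded away")
      w <- w / nw
      tt <- drop(Xh %*% w)
      q <- drop(crossprod(Yh, tt)) / sum(tt^2)
      u <- drop(Yh %*% q) / sum(q^2)
      if (sqrt(sum((w - w_old)^2)) < 1e-6) break
      w_old <- w
    }
    pl <- drop(crossprod(Xh, tt)) / sum(tt^2)
    ss_before <- sum(Xh^2)
    Xh <- Xh - tcrossprod(tt, pl)
    Yh <- Yh - tcrossprod(tt, q)
    expl[h] <- 100 * (ss_before - sum(Xh^2)) / X0ss
    W[, h] <- w; P[, h] <- pl; Qm[, h] <- q; Tm[, h] <- tt
  }
  # regression coefficients for class-score prediction
  Wstar <- W %*% solve(crossprod(P, W))
  B <- Wstar %*% t(Qm)
  colnames(B) <- paste0("class", classes)
  structure(list(loadings = W, scores = Tm, y_loadings = Qm,
                 x_proj = P, coef = B, y_center = y_center,
                 explained_variance = expl, keepX = keepX,
                 n_components = H, classes = classes, features = feats,
                 meta = pm[c("animal_id", "dim", "phase")],
                 labels = y),
            class = "hrdcc_splsda")
}

#' @export
print.hrdcc_splsda <- function(x, ...) {
  cat("<hrdcc_splsda>", x$n_components, "components, keepX =", x$keepX,
      "\n  explained X-variance:",
      paste(sprintf("%.1f%%", x$explained_variance), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.hrdcc_splsda <- function(x, ...) {
  tibble::as_tibble(x$loadings, rownames = "feature") |>
    tidyr::pivot_longer(-"feature", names_to = "component",
                        values_to = "loading") |>
    dplyr::filter(.data$loading != 0)
}

#' @export
glance.hrdcc_splsda <- function(x, ...) {
  tibble::tibble(component = paste0("comp", seq_len(x$n_components)),
                 explained_variance = x$explained_variance,
                 keepX = x$keepX)
}

#' @export
autoplot.hrdcc_splsda <- function(object, ...) {
  df <- dplyr::bind_cols(object$meta,
                         tibble::as_tibble(object$scores[, 1:2]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comp1, y = .data$comp2,
                                   colour = factor(.data$phase))) +
    ggplot2::geom_point() +
    ggplot2::labs(colour = "phase",
                  x = sprintf("X-variate 1 (%.0f%%)",
                              object$explained_variance[1]),
                  y = sprintf("X-variate 2 (%.0f%%)",
                              object$explained_variance[2])) +
    ggplot2::theme_minimal()
}

#' Predicted class scores from a fitted sPLS-DA model
#'
#' Dummy-response regression prediction: each column is the model's score
#' for one class; the predicted class is the column-wise maximum.
#'
#' @param object A fitted `hrdcc_splsda`.
#' @param newdata Optional phase matrix with the same features; default the
#'   training matrix is unavailable, so scores are reconstructed from the
#'   stored components.
#' @param ... Unused.
#' @return Matrix of class scores (samples x classes).
#' @export
predict.hrdcc_splsda <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    scores <- object$scores %*% t(object$y_loadings)
  } else {
    X <- as.matrix(newdata[object$features])
    scores <- X %*% object$coef
  }
  sweep(scores, 2, object$y_center, `+`)
}

#' One-vs-rest AUROC for one lactation phase
#'
#' Mann-Whitney AUROC of the model's predicted score for `phase` against
#' all other samples, computed on the fitted (training) data.
#'
#' @param model A fitted `hrdcc_splsda`.
#' @param pm The phase matrix the model was fitted on.
#' @param phase Class label to score against the rest.
#' @param labels Optional label vector overriding `pm$phase`.
#' @return AUROC in `[0, 1]`.
#' @export
auroc_one_vs_rest <- function(model, pm, phase, labels = NULL) {
  y <- labels %||% pm$phase
  if (length(unique(y)) < 2) abort("labels contain a single class")
  if (!phase %in% y) abort(sprintf("phase %s not present in labels", phase))
  sc <- predict(model, pm)
  col <- match(paste0("class", phase), colnames(sc))
  s <- sc[, col]
  pos <- y == phase
  n1 <- sum(pos); n0 <- sum(!pos)
  r <- rank(s)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUROCs for every phase of a fitted model
#'
#' @inheritParams auroc_one_vs_rest
#' @return Tibble `phase`, `auroc`.
#' @export
phase_aurocs <- function(model, pm) {
  purrr::map_dfr(model$classes, function(ph) {
    tibble::tibble(phase = ph,
                   auroc = auroc_one_vs_rest(model, pm, ph))
  })
}

#' Top discriminating features of a sPLS-DA model
#'
#' Features ranked by absolute component-1 loading, ties broken by
#' component 2.
#'
#' @param model A fitted `hrdcc_splsda`.
#' @param k Number of features to return.
#' @return Tibble `rank`, `feature`, `loading1`, `loading2`.
#' @export
top_features <- function(model, k) {
  W <- model$loadings
  sel <- rowSums(W != 0) > 0
  l2 <- if (ncol(W) >= 2) abs(W[, 2]) else rep(0, nrow(W))
  tab <- tibble::tibble(feature = rownames(W),
                        loading1 = W[, 1],
                        loading2 = if (ncol(W) >= 2) W[, 2] else 0,
                        selected = sel)
  tab <- tab[tab$selected, ]
  ord <- order(-abs(tab$loading1), -abs(tab$loading2))
  tab <- tab[ord, c("feature", "loading1", "loading2")]
  if (k > nrow(tab)) {
    warn(sprintf("only %d selected features available; truncating", nrow(tab)))
    k <- nrow(tab)
  }
  out <- utils::head(tab, k)
  tibble::add_column(out, rank = seq_len(nrow(out)), .before = 1)
}

#' Within-phase dispersion in component space
#'
#' Mean Euclidean distance of each phase's samples to its centroid in the
#' model's score space (the early-lactation group is typically the most
#' dispersed).
#'
#' @param model A fitted `hrdcc_splsda` or `hrdcc_pca`.
#' @return Tibble `phase`, `dispersion`, `n`.
#' @export
phase_dispersion <- function(model) {
  sc <- model$scores[, 1:2, drop = FALSE]
  phase <- model$meta$phase
  purrr::map_dfr(sort(unique(phase)), function(ph) {
    m <- sc[phase == ph, , drop = FALSE]
    ctr <- colMeans(m)
    tibble::tibble(phase = ph,
                   dispersion = mean(sqrt(rowSums(sweep(m, 2, ctr)^2))),
                   n = nrow(m))
  })
}
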