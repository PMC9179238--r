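#' Detect haptoglobin-defined inflammation episodes
#'
#' Maximal runs of at least `min_consecutive` consecutive visits whose
#' haptoglobin exceeds the threshold. Runs separated by even a single
#' sub-threshold visit are distinct episodes.
#'
#' @param data Data frame with columns `dim` and `value` (haptoglobin),
#'   sorted by `dim`; an `animal_id` column is carried through if present.
#' @param threshold Episode threshold (> 0); the package convention is
#'   baseline + 3 baseline SDs, see [hapto_threshold()].
#' @param min_consecutive Minimum run length (default 2 visits).
#' @return Tibble `animal_id`, `start_dim`, `end_dim`, `peak_hapto`,
#'   `n_visits` (possibly empty).
#' @export
detect_episodes <- function(data, threshold, min_consecutive = 2) {
  assert_cols(data, c("dim", "value"), "haptoglobin series")
  if (threshold <= 0) abort("threshold must be > 0")
  if (is.unsorted(data$dim, strictly = FALSE)) {
    abort("series must be sorted by DIM")
  }
  above <- data$value > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_consecutive
  out <- purrr::map_dfr(which(keep), function(i) {
    idx <- seq(starts[i], ends[i])
    tibble::tibble(start_dim = data$dim[starts[i]],
                   end_dim = data$dim[ends[i]],
                   peak_hapto = max(data$value[idx]),
                   n_visits = length(idx))
  })
  if (nrow(out) == 0) {
    out <- tibble::tibble(start_dim = numeric(), end_dim = numeric(),
                          peak_hapto = numeric(), n_visits = integer())
  }
  aid <- if ("animal_id" %in% names(data)) data$animal_id[1] else NA_character_
  tibble::add_column(out, animal_id = rep(aid, nrow(out)), .before = 1)
}

#' In-episode versus out-of-episode contrast for a cell series
#'
#' Mean difference (in minus out) of a cell population series between
#' in-episode and out-of-episode visits, with a two-sided Wilcoxon
#' rank-sum test.
#'
#' @param data Data frame with `dim` and `value` (cell percentage).
#' @param episodes Episode tibble with `start_dim`, `end_dim`.
#' @param min_n Minimum visits required on each side (default 3).
#' @return One-row tibble `in_mean`, `out_mean`, `difference`, `p_value`,
#'   `n_in`, `n_out`, `reason` (`NA` on success; contrasts with too few
#'   visits return `NA` statistics and an explanatory reason).
#' @export
episode_contrast <- function(data, episodes, min_n = 3) {
  assert_cols(data, c("dim", "value"), "cell series")
  in_ep <- if (nrow(episodes) == 0) rep(FALSE, nrow(data)) else {
    purrr::map_lgl(data$dim,
                   ~ any(.x >= episodes$start_dim & .x <= episodes$end_dim))
  }
  n_in <- sum(in_ep); n_out <- sum(!in_ep)
  if (n_in < min_n || n_out < min_n) {
    return(tibble::tibble(in_mean = NA_real_, out_mean = NA_real_,
                          difference = NA_real_, p_value = NA_real_,
                          n_in = n_in, n_out = n_out,
                          reason = sprintf(
                            "insufficient visits (in = %d, out = %d)",
                            n_in, n_out)))
  }
  x <- data$value[in_ep]; y <- data$value[!in_ep]
  p <- if (length(unique(c(x, y))) < 2) 1 else {
    suppressWarnings(wilcox.test(x, y, exact = FALSE)$p.value)
  }
  tibble::tibble(in_mean = mean(x), out_mean = mean(y),
                 difference = mean(x) - mean(y), p_value = p,
                 n_in = n_in, n_out = n_out, reason = NA_character_)
}

#' Pearson correlation between two paired marker series
#'
#' Used for the immature-granulocyte null check: no association between
#' inflammation (haptoglobin) and CD11b-low granulocyte percentages.
#'
#' @param x,y Paired numeric vectors (n >= 10).
#' @return One-row tibble `r`, `conf_low`, `conf_high`, `p_value`, `n`
#'   (Fisher-z 95% interval).
#' @export
marker_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("series must be paired and equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) abort("need at least 10 paired observations")
  if (sd(x) == 0 || sd(y) == 0) abort("zero-variance input")
  ct <- cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate),
                 conf_low = ct$conf.int[1], conf_high = ct$conf.int[2],
                 p_value = ct$p.value, n = length(x))
}

#' Episode contrasts for every animal of a study
#'
#' Detects episodes per animal from the simulated haptoglobin series and
#' contrasts the milk gamma-delta T and CD4+ T percentages in versus out
#' of episodes.
#'
#' @param results Long `hrdcc_result` tibble (reference mode used).
#' @param biomarkers Long biomarker tibble from the study.
#' @param threshold Haptoglobin episode threshold.
#' @param min_consecutive Minimum in-episode run length.
#' @return List with `episodes` and `contrasts` tibbles.
#' @export
study_episode_analysis <- function(results, biomarkers, threshold,
                                   min_consecutive = 2) {
  res <- tibble::as_tibble(results)
  res <- dplyr::filter(res, .data$mode == res$mode[1])
  animals <- unique(res$animal_id)
  eps <- list(); cons <- list()
  for (a in animals) {
    hp <- biomarkers |>
      dplyr::filter(.data$animal_id == a, .data$analyte == "haptoglobin") |>
      dplyr::arrange(.data$dim) |>
      dplyr::transmute(animal_id = .data$animal_id, dim = .data$dim,
                       value = .data$value)
    ep <- detect_episodes(hp, threshold, min_consecutive)
    eps[[a]] <- ep
    for (pop in c("gdT", "CD4T", "imm_gran")) {
      series <- res |>
        dplyr::filter(.data$animal_id == a, .data$matrix == "milk",
                      .data$node == pop) |>
        dplyr::arrange(.data$dim) |>
        dplyr::transmute(dim = .data$dim, value = .data$percent)
      cc <- episode_contrast(series, ep)
      cc$animal_id <- a
      cc$population <- pop
      cons[[paste(a, pop)]] <- cc
    }
  }
  list(episodes = dplyr::bind_rows(eps),
       contrasts = dplyr::bind_rows(cons) |>
         dplyr::select("animal_id", "population", dplyr::everything()))
}
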