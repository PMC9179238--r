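# CSV + schema-sidecar output helper: every table declares its columns
write_output <- function(df, dir, name) {
  path <- file.path(dir, paste0(name, ".csv"))
  readr::write_csv(df, path, progress = FALSE)
  schema <- lapply(df, function(col) class(col)[1])
  jsonlite::write_json(schema, file.path(dir, paste0(name, ".schema.json")),
                       auto_unbox = TRUE, pretty = TRUE)
  path
}

pipeline_stages <- c("simulate", "gate", "trend", "episodes", "cluster")

#' Run the simulation/gating/analysis pipeline
#'
#' Executes the requested stages in order (`simulate`, `gate`, `trend`,
#' `episodes`, `cluster`; must be a contiguous prefix-or-middle run of that
#' order), writing every table as CSV with a JSON schema sidecar and a
#' run manifest last. With `keep_events = "none"` the simulate and gate
#' stages stream event matrices in memory (regenerated deterministically
#' per sample); with `"fcs"` events are written as FCS 3.1 files and the
#' gate stage reads them back from disk, so the stages can also be run in
#' separate calls.
#'
#' @param config A [study_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for the whole run.
#' @param stages Character vector of stages to execute.
#' @param mode Gating mode: `"both"`, `"reference"` or `"auto"`.
#' @param keep_events `"none"` (stream in memory) or `"fcs"`.
#' @return The run manifest (list), invisibly.
#' @export
run_pipeline <- function(config = study_config(), out_dir,
                         seed = 1,
                         stages = pipeline_stages,
                         mode = "both",
                         keep_events = c("none", "fcs")) {
  keep_events <- match.arg(keep_events)
  stages <- match.arg(stages, pipeline_stages, several.ok = TRUE)
  idx <- sort(match(stages, pipeline_stages))
  if (!identical(idx, seq(min(idx), max(idx)))) {
    abort("stages must be contiguous in simulate > gate > trend/episodes/cluster order")
  }
  stages <- pipeline_stages[idx]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  written <- character()
  study <- NULL
  results <- NULL
  biomarkers <- NULL

  if ("simulate" %in% stages) {
    study <- simulate_study(config, seed)
    written <- c(written,
                 write_output(study$samples[c("sample_id", "animal_id",
                                              "dim", "matrix")],
                              out_dir, "samples"),
                 write_output(study$biomarkers, out_dir, "biomarkers"),
                 write_output(study$states, out_dir, "truth_states"),
                 write_output(study$episodes, out_dir, "episodes_true"),
                 write_output(study$profiles, out_dir, "profiles"))
    if (keep_events == "fcs") {
      evdir <- file.path(out_dir, "events")
      dir.create(evdir, showWarnings = FALSE)
      for (sid in study$samples$sample_id) {
        ev <- events_for_sample(study, sid)
        write_fcs(ev, file.path(evdir, paste0(sid, ".fcs")))
      }
    }
    biomarkers <- study$biomarkers
  }

  if ("gate" %in% stages) {
    if (is.null(study)) {
      # file-based path: prior simulate run must have left FCS events
      samples_path <- file.path(out_dir, "samples.csv")
      evdir <- file.path(out_dir, "events")
      if (!file.exists(samples_path) || !dir.exists(evdir)) {
        abort("gate stage: missing upstream simulate outputs (samples.csv / events/)")
      }
      samples <- readr::read_csv(samples_path, show_col_types = FALSE,
                                 progress = FALSE)
      biomarkers <- readr::read_csv(file.path(out_dir, "biomarkers.csv"),
                                    show_col_types = FALSE, progress = FALSE)
      modes <- if (mode == "both") c("reference", "auto") else mode
      res <- list()
      for (i in seq_len(nrow(samples))) {
        sid <- samples$sample_id[i]
        fp <- file.path(evdir, paste0(sid, ".fcs"))
        ev <- tryCatch(read_fcs(fp), error = function(e) {
          abort(sprintf("gate stage failed on %s: %s", fp, conditionMessage(e)))
        })
        ev <- asinh_transform(ev, config$cofactor)
        tree <- gating_tree(samples$matrix[i], config$gates)
        for (md in modes) {
          res[[paste(sid, md)]] <- run_hrdcc(ev, tree, md)
        }
      }
      results <- dplyr::bind_rows(res) |>
        dplyr::left_join(samples[c("sample_id", "animal_id", "dim")],
                         by = "sample_id")
    } else {
      results <- run_study_hrdcc(study, mode)
    }
    out <- dplyr::mutate(tibble::as_tibble(results), denominator = "parent")
    written <- c(written, write_output(out, out_dir, "hrdcc"))
    if (length(unique(results$mode)) == 2) {
      ref <- dplyr::filter(results, .data$mode == "reference")
      aut <- dplyr::filter(results, .data$mode == "auto")
      written <- c(written,
                   write_output(compare_gating(ref, aut), out_dir,
                                "gate_comparison"))
    }
  }

  if (any(c("trend", "episodes", "cluster") %in% stages) && is.null(results)) {
    hp <- file.path(out_dir, "hrdcc.csv")
    if (!file.exists(hp)) abort("downstream stage: missing upstream hrdcc.csv")
    results <- readr::read_csv(hp, show_col_types = FALSE, progress = FALSE)
    biomarkers <- readr::read_csv(file.path(out_dir, "biomarkers.csv"),
                                  show_col_types = FALSE, progress = FALSE)
  }

  ref_results <- if (!is.null(results)) {
    dplyr::filter(tibble::as_tibble(results), .data$mode == "reference" |
                    !"reference" %in% unique(results$mode))
  }

  if ("trend" %in% stages) {
    keys <- ref_results |>
      dplyr::filter(is.finite(.data$percent)) |>
      dplyr::distinct(.data$animal_id, .data$matrix, .data$node)
    trends <- purrr::pmap_dfr(keys, function(animal_id, matrix, node) {
      series <- ref_results |>
        dplyr::filter(.data$animal_id == !!animal_id,
                      .data$matrix == !!matrix, .data$node == !!node,
                      is.finite(.data$percent)) |>
        dplyr::arrange(.data$dim) |>
        dplyr::transmute(dim = .data$dim, value = .data$percent)
      if (nrow(series) < 10) return(NULL)
      fit <- fit_trend(series, "spline4", Q = 1)
      dplyr::mutate(augment(fit), animal_id = animal_id, matrix = matrix,
                    node = node)
    })
    written <- c(written,
                 write_output(trends, out_dir, "trends"),
                 write_output(animal_summaries(ref_results), out_dir,
                              "animal_summary"))
  }

  if ("episodes" %in% stages) {
    thr <- hapto_threshold(config)
    ea <- study_episode_analysis(ref_results, biomarkers, thr)
    written <- c(written,
                 write_output(ea$episodes, out_dir, "episodes"),
                 write_output(ea$contrasts, out_dir, "episode_contrasts"))
  }

  if ("cluster" %in% stages) {
    pca_rows <- list(); spl_rows <- list(); auc_rows <- list()
    load_rows <- list()
    for (scope in c("all", "milk", "blood", "lab")) {
      pm <- assemble_matrix(ref_results, biomarkers, scope)
      pc <- fit_pca(pm, n_components = 2)
      spl <- fit_splsda(pm, n_components = 2,
                        keepX = min(5, length(phase_features(pm))))
      pca_rows[[scope]] <- dplyr::bind_cols(
        scope = scope, pc$meta, tibble::as_tibble(pc$scores))
      spl_rows[[scope]] <- dplyr::bind_cols(
        scope = scope, spl$meta, tibble::as_tibble(spl$scores))
      auc_rows[[scope]] <- dplyr::mutate(phase_aurocs(spl, pm),
                                         scope = scope, .before = 1)
      load_rows[[scope]] <- dplyr::mutate(tidy(spl), scope = scope,
                                          .before = 1)
    }
    written <- c(written,
                 write_output(dplyr::bind_rows(pca_rows), out_dir,
                              "pca_scores"),
                 write_output(dplyr::bind_rows(spl_rows), out_dir,
                              "splsda_scores"),
                 write_output(dplyr::bind_rows(auc_rows), out_dir, "auroc"),
                 write_output(dplyr::bind_rows(load_rows), out_dir,
                              "loadings"))
  }

  manifest <- list(
    tool = "hrdcc", version = as.character(packageVersion("hrdcc")),
    seed = seed, stages = stages, mode = mode, keep_events = keep_events,
    config_hash = rlang::hash(config),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(tools::md5sum(sort(written)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Build a study fixture on disk
#'
#' `tiny` writes a 2-animal, 10-visit, 5000-event study (fast enough for
#' end-to-end tests); `default` is the full 8-animal study.
#'
#' @param scale `"tiny"` or `"default"`.
#' @param out_dir Output directory.
#' @param seed Integer seed.
#' @return The configuration used, invisibly.
#' @export
make_fixture <- function(scale = c("tiny", "default"), out_dir, seed = 1) {
  scale <- match.arg(scale)
  config <- if (scale == "tiny") {
    study_config(n_animals = 2, n_events = 5000, max_visits = 10)
  } else {
    study_config()
  }
  run_pipeline(config, out_dir, seed = seed, stages = "simulate",
               keep_events = "fcs")
  invisible(config)
}
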