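#' Generate a sampling schedule for one lactation
#'
#' Visits fall twice a week (days 2 and 5 of each week) up to the cutoff DIM
#' and weekly afterwards, until the end of lactation. Each scheduled visit is
#' independently missed with probability `dropout_prob`.
#'
#' @param lactation_days Length of the lactation in days (>= cutoff + 1).
#' @param schedule List with `twice_weekly_until` (cutoff DIM) and
#'   `late_interval` (days between late visits).
#' @param dropout_prob Per-visit dropout probability.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is used.
#' @return Integer vector of strictly increasing sampling DIMs.
#' @export
generate_schedule <- function(lactation_days,
                              schedule = list(twice_weekly_until = 100,
                                              late_interval = 7),
                              dropout_prob = 0,
                              seed = NULL) {
  cutoff <- schedule$twice_weekly_until
  if (lactation_days < cutoff + 1) {
    abort("`lactation_days` must exceed the twice-weekly cutoff")
  }
  assert_prob(dropout_prob, "dropout_prob")
  early <- sort(c(seq(2, cutoff, by = 7), seq(5, cutoff, by = 7)))
  late <- seq(max(early) + schedule$late_interval, lactation_days,
              by = schedule$late_interval)
  visits <- c(early, late)
  draw <- function() visits[runif(length(visits)) >= dropout_prob]
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  as.integer(out)
}

#' Generate per-animal profiles
#'
#' Each cow gets a lactation length, a blood CD4+ baseline (mean and
#' per-visit SD, as a fraction of lymphocytes), logit-scale offsets for the
#' major milk/blood fractions, and a calving-window haptoglobin flag. The
#' named `cow1` and `cow6` profiles in the default configuration carry the
#' fixed blood CD4 parameters (34.7%, SD 2.9 and 19.7%, SD 2.6).
#'
#' @param config A [study_config()] object.
#' @param seed Optional integer seed.
#' @return Tibble with one row per animal.
#' @export
generate_animal_profiles <- function(config, seed = NULL) {
  if (config$animal_effect_sd < 0) abort("animal_effect_sd must be >= 0")
  if (config$n_animals < 1) abort("n_animals must be >= 1")
  gen <- function() {
    n <- config$n_animals
    ids <- paste0("cow", seq_len(n))
    rng <- config$lactation_days_range
    lact <- sample(seq(rng[1], rng[2]), n, replace = TRUE)
    bcfg <- config$blood_cd4_between
    cd4_mean <- clamp(rnorm(n, bcfg$mean, bcfg$sd), 0.10, 0.45)
    cd4_sd <- clamp(rnorm(n, 0.028, 0.004), 0.015, 0.05)
    for (nm in names(config$named_profiles)) {
      i <- match(nm, ids)
      if (!is.na(i)) {
        cd4_mean[i] <- config$named_profiles[[nm]]$blood_cd4_mean
        cd4_sd[i] <- config$named_profiles[[nm]]$blood_cd4_sd
      }
    }
    es <- config$animal_effect_sd
    tibble::tibble(
      animal_id = ids,
      lactation_days = as.integer(lact),
      blood_cd4_mean = cd4_mean,
      blood_cd4_sd = cd4_sd,
      off_milk_gran = rnorm(n, 0, es),
      off_milk_gdt = rnorm(n, 0, es),
      off_blood_gran = rnorm(n, 0, es),
      off_viability = rnorm(n, 0, es / 3),
      has_calving_elevation = runif(n) < config$episode_params$calving_prob
    )
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

# deterministic mean curves, exposed for tests of trend recovery
milk_gdt_curve <- function(dim, lp) {
  lp$gdt_start + (lp$gdt_end - lp$gdt_start) * dim / 305
}
milk_cd4_curve <- function(dim, lp) {
  lp$cd4_start + (lp$cd4_end - lp$cd4_start) * dim / 305
}
milk_viability_curve <- function(dim, vp) {
  pmin(vp$floor + vp$rise * (1 - exp(-dim / vp$tau)) + vp$late_slope * dim,
       vp$cap)
}
milk_nk_curve <- function(dim, lp) {
  lp$nk_start + (lp$nk_end - lp$nk_start) * dim / 305
}
milk_cmac_curve <- function(dim, ms) {
  ms$cmac_start + (ms$cmac_end - ms$cmac_start) * dim / 305
}

# renormalise subset columns so each row sums to `total` (default 1)
renorm_rows <- function(m, total = 1) {
  s <- rowSums(m)
  m * (total / s)
}

#' Generate true population trajectories for one animal
#'
#' Produces the latent per-visit state: terminal population fractions (of
#' all intact cells) plus viability. Milk gamma-delta T cells decline and
#' CD4+ T cells rise over lactation; milk granulocyte/lymphocyte fractions
#' are noisier before the level-out DIM than after; blood fractions are
#' stationary around the animal's baseline.
#'
#' @param profile One-row tibble from [generate_animal_profiles()].
#' @param schedule Integer vector of sampling DIMs.
#' @param trajectory_params As in `study_config()$trajectories`.
#' @param matrix `"milk"` or `"blood"`.
#' @param volatility Multiplier on every per-visit noise SD; 0 gives the
#'   deterministic mean curves.
#' @param seed Optional integer seed.
#' @return Tibble with one row per DIM and one column per terminal
#'   population (fractions summing to 1), plus `viability`.
#' @export
generate_trajectories <- function(profile, schedule, trajectory_params,
                                  matrix = c("milk", "blood"),
                                  volatility = 1, seed = NULL) {
  matrix <- match.arg(matrix)
  if (length(schedule) == 0) abort("schedule must be nonempty")
  tp <- trajectory_params[[matrix]]
  check_level1 <- if (matrix == "milk") {
    tp$level1$gran_mean + tp$level1$mac_mean
  } else {
    tp$level1$gran_mean + tp$level1$mono_mean
  }
  if (check_level1 >= 1 || check_level1 <= 0) {
    abort("level-1 population means must leave room for lymphocytes in (0,1)")
  }
  gen <- function() {
    d <- as.numeric(schedule)
    n <- length(d)
    v <- volatility
    if (matrix == "milk") {
      l1 <- tp$level1
      gran_sd <- ifelse(d < l1$level_out_dim, l1$gran_sd_early, l1$gran_sd_late)
      gran_mu <- plogis(qlogis(l1$gran_mean) + profile$off_milk_gran)
      gran <- clamp(rnorm(n, gran_mu, v * gran_sd), 0.05, 0.88)
      mac <- clamp(rnorm(n, l1$mac_mean, v * l1$mac_sd), 0.01, 0.40)
      over <- gran + mac > 0.96
      gran[over] <- gran[over] * 0.96 / (gran + mac)[over]
      mac[over] <- mac[over] * 0.96 / (gran + mac)[over]
      lymph <- 1 - gran - mac
      mec <- clamp(rnorm(n, tp$mec$mean, v * tp$mec$sd), 0.004, 0.15)
      cd45 <- 1 - mec
      lp <- tp$lymph
      gdt_mu <- plogis(qlogis(milk_gdt_curve(d, lp)) + profile$off_milk_gdt)
      cd4_mu <- plogis(qlogis(milk_cd4_curve(d, lp)) - profile$off_milk_gdt)
      sub <- cbind(
        NK = clamp(rnorm(n, milk_nk_curve(d, lp), v * lp$nk_sd), 0.002, 0.5),
        gdT = clamp(rnorm(n, gdt_mu, v * lp$gdt_sd), 0.01, 0.8),
        CD4T = clamp(rnorm(n, cd4_mu, v * lp$cd4_sd), 0.01, 0.8),
        CD8T = clamp(rnorm(n, lp$cd8_mean, v * lp$cd8_sd), 0.01, 0.8),
        B = clamp(rnorm(n, lp$b_mean, v * lp$b_sd), 0.002, 0.5)
      )
      other <- clamp(1 - rowSums(sub), 0.02, 0.9)
      sub <- renorm_rows(cbind(sub, lymph_other = other))
      gs <- tp$gran_sub
      eos <- clamp(rnorm(n, gs$eos_mean, v * gs$eos_sd), 0.001, 0.3)
      imm <- clamp(rnorm(n, gs$imm_mean, v * gs$imm_sd), 0.001, 0.3)
      neut <- 1 - eos - imm
      cmac <- clamp(rnorm(n, milk_cmac_curve(d, tp$mono_sub),
                          v * tp$mono_sub$cmac_sd),
                    0.2, 0.95)
      vp <- tp$viability
      viab <- clamp(milk_viability_curve(d, vp) + profile$off_viability / 10 +
                      rnorm(n, 0, v * vp$sd), 0.05, vp$cap)
      out <- tibble::tibble(
        animal_id = profile$animal_id, dim = as.integer(d), matrix = matrix,
        neut = cd45 * gran * neut, eos = cd45 * gran * eos,
        imm_gran = cd45 * gran * imm,
        cMac = cd45 * mac * cmac, ncMac = cd45 * mac * (1 - cmac),
        NK = cd45 * lymph * sub[, "NK"], gdT = cd45 * lymph * sub[, "gdT"],
        CD4T = cd45 * lymph * sub[, "CD4T"],
        CD8T = cd45 * lymph * sub[, "CD8T"], B = cd45 * lymph * sub[, "B"],
        lymph_other = cd45 * lymph * sub[, "lymph_other"],
        MEC = mec, viability = viab
      )
    } else {
      l1 <- tp$level1
      gran_mu <- plogis(qlogis(l1$gran_mean) + profile$off_blood_gran)
      gran <- clamp(rnorm(n, gran_mu, v * l1$gran_sd), 0.05, 0.7)
      mono <- clamp(rnorm(n, l1$mono_mean, v * l1$mono_sd), 0.01, 0.3)
      lymph <- 1 - gran - mono
      lp <- tp$lymph
      sub <- cbind(
        NK = clamp(rnorm(n, lp$nk_mean, v * lp$nk_sd), 0.002, 0.5),
        gdT = clamp(rnorm(n, lp$gdt_mean, v * lp$gdt_sd), 0.01, 0.8),
        CD4T = clamp(rnorm(n, profile$blood_cd4_mean,
                           v * profile$blood_cd4_sd), 0.01, 0.8),
        CD8T = clamp(rnorm(n, lp$cd8_mean, v * lp$cd8_sd), 0.01, 0.8),
        B = clamp(rnorm(n, lp$b_mean, v * lp$b_sd), 0.002, 0.6)
      )
      other <- clamp(1 - rowSums(sub), 0.02, 0.9)
      sub <- renorm_rows(cbind(sub, lymph_other = other))
      gs <- tp$gran_sub
      eos <- clamp(rnorm(n, gs$eos_mean, v * gs$eos_sd), 0.001, 0.3)
      imm <- clamp(rnorm(n, gs$imm_mean, v * gs$imm_sd), 0.001, 0.3)
      neut <- 1 - eos - imm
      ms <- tp$mono_sub
      cm <- clamp(rnorm(n, ms$cm_mean, v * ms$cm_sd), 0.4, 0.95)
      intm <- clamp(rnorm(n, ms$intm_mean, v * ms$intm_sd), 0.005, 0.3)
      ncm <- clamp(1 - cm - intm, 0.005, 0.5)
      msub <- renorm_rows(cbind(cM = cm, intM = intm, ncM = ncm))
      viab <- clamp(rnorm(n, tp$viability$mean, v * tp$viability$sd),
                    0.8, 0.998)
      out <- tibble::tibble(
        animal_id = profile$animal_id, dim = as.integer(d), matrix = matrix,
        neut = gran * neut, eos = gran * eos, imm_gran = gran * imm,
        cM = mono * msub[, "cM"], intM = mono * msub[, "intM"],
        ncM = mono * msub[, "ncM"],
        NK = lymph * sub[, "NK"], gdT = lymph * sub[, "gdT"],
        CD4T = lymph * sub[, "CD4T"], CD8T = lymph * sub[, "CD8T"],
        B = lymph * sub[, "B"], lymph_other = lymph * sub[, "lymph_other"],
        viability = viab
      )
    }
    # renormalise terminal fractions to sum to exactly 1
    pops <- terminal_populations(matrix)
    frac <- as.matrix(out[pops])
    out[pops] <- renorm_rows(frac)
    out
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Inject inflammation episodes into one animal's states
#'
#' Draws a Poisson number of episodes (merged if overlapping), and within
#' each episode shifts the milk gamma-delta T fraction down and the milk
#' CD4+ T fraction up by the configured deltas (as fractions of the
#' lymphocyte pool). The immature-granulocyte fraction is deliberately left
#' untouched so that it carries no inflammation signal.
#'
#' @param states Tibble of states (both matrices allowed) sorted by DIM
#'   within matrix; only milk rows are shifted.
#' @param episode_params As in `study_config()$episode_params`.
#' @param lactation_days Length of the lactation (bounds episode starts).
#' @param forced Optional tibble with `start_dim`, `end_dim` forcing given
#'   episodes instead of random draws.
#' @param seed Optional integer seed.
#' @return List with `states` (shifted) and `episodes` (tibble
#'   `animal_id`, `start_dim`, `end_dim`).
#' @export
inject_episodes <- function(states, episode_params, lactation_days = 300,
                            forced = NULL, seed = NULL) {
  if (is.unsorted(states$dim[states$matrix == states$matrix[1]])) {
    # per-matrix sort check
  }
  for (m in unique(states$matrix)) {
    if (is.unsorted(states$dim[states$matrix == m])) {
      abort("states must be sorted by DIM within matrix")
    }
  }
  ep <- episode_params
  gen <- function() {
    if (!is.null(forced)) {
      eps <- tibble::tibble(start_dim = forced$start_dim,
                            end_dim = forced$end_dim)
    } else {
      k <- rpois(1, ep$rate)
      if (k == 0) {
        eps <- tibble::tibble(start_dim = numeric(), end_dim = numeric())
      } else {
        start <- runif(k, 15, max(20, lactation_days - 30))
        dur <- runif(k, ep$duration_range[1], ep$duration_range[2])
        eps <- tibble::tibble(start_dim = start, end_dim = start + dur)
      }
    }
    # merge overlapping intervals
    if (nrow(eps) > 1) {
      eps <- dplyr::arrange(eps, .data$start_dim)
      merged <- eps[1, ]
      for (i in seq(2, nrow(eps))) {
        last <- nrow(merged)
        if (eps$start_dim[i] <= merged$end_dim[last]) {
          merged$end_dim[last] <- max(merged$end_dim[last], eps$end_dim[i])
        } else {
          merged <- dplyr::bind_rows(merged, eps[i, ])
        }
      }
      eps <- merged
    }
    eps
  }
  eps <- if (is.null(seed)) gen() else with_seed(seed, gen())
  in_episode <- function(d) {
    if (nrow(eps) == 0) rep(FALSE, length(d))
    else purrr::map_lgl(d, ~ any(.x >= eps$start_dim & .x <= eps$end_dim))
  }
  milk <- states$matrix == "milk"
  if (any(milk) && nrow(eps) > 0) {
    hit <- milk & in_episode(states$dim)
    if (any(hit)) {
      lymph_cols <- c("NK", "gdT", "CD4T", "CD8T", "B", "lymph_other")
      lt <- rowSums(states[hit, lymph_cols])
      gdt <- clamp(states$gdT[hit] + ep$gdt_shift * lt, 0.002 * lt, 0.95 * lt)
      cd4 <- clamp(states$CD4T[hit] + ep$cd4_shift * lt, 0.002 * lt, 0.95 * lt)
      states$gdT[hit] <- gdt
      states$CD4T[hit] <- cd4
      sub <- as.matrix(states[hit, lymph_cols])
      states[hit, lymph_cols] <- sub * (lt / rowSums(sub))
    }
  }
  eps$animal_id <- rep(states$animal_id[1], nrow(eps))
  list(states = states,
       episodes = dplyr::select(eps, "animal_id", dplyr::everything()))
}

#' Generate serum biomarker series for one animal
#'
#' NEFA, beta-HBA and bilirubin start elevated (negative energy balance in
#' early lactation) and decay exponentially to baseline; calcium dips
#' briefly after calving; GLDH decays slowly; haptoglobin sits at baseline
#' except during inflammation episodes and (for flagged cows) a decaying
#' calving window.
#'
#' @param profile One-row profile tibble.
#' @param schedule Sampling DIMs.
#' @param episodes Episode tibble (`start_dim`, `end_dim`), possibly empty.
#' @param biomarker_params As in `study_config()$biomarker_params`.
#' @param episode_params As in `study_config()$episode_params`.
#' @param seed Optional integer seed.
#' @return Long tibble `animal_id`, `dim`, `analyte`, `value` (all > 0).
#' @export
generate_biomarkers <- function(profile, schedule, episodes,
                                biomarker_params, episode_params,
                                seed = NULL) {
  if (length(schedule) == 0) abort("schedule must be nonempty")
  for (bm in names(biomarker_params)) {
    base <- biomarker_params[[bm]]$baseline
    if (is.null(base) || base < 0) abort("biomarker baselines must be >= 0")
  }
  gen <- function() {
    d <- as.numeric(schedule)
    n <- length(d)
    hp <- biomarker_params$haptoglobin
    ep <- episode_params
    in_ep <- if (nrow(episodes) == 0) rep(FALSE, n) else {
      purrr::map_lgl(d, ~ any(.x >= episodes$start_dim & .x <= episodes$end_dim))
    }
    calving <- if (isTRUE(profile$has_calving_elevation)) {
      ep$calving_amp * exp(-d / ep$calving_tau)
    } else 0
    hapto <- pmax(hp$baseline + ep$hapto_amplitude * in_ep + calving +
                    rnorm(n, 0, hp$sd), 0.05)
    rows <- list(tibble::tibble(animal_id = profile$animal_id,
                                dim = as.integer(d),
                                analyte = "haptoglobin", value = hapto))
    for (bm in setdiff(names(biomarker_params), "haptoglobin")) {
      p <- biomarker_params[[bm]]
      mu <- p$baseline + p$early_amp * exp(-d / p$decay_tau)
      val <- pmax(mu * exp(rnorm(n, 0, p$noise_cv)), 1e-6)
      rows[[bm]] <- tibble::tibble(animal_id = profile$animal_id,
                                   dim = as.integer(d),
                                   analyte = bm, value = val)
    }
    dplyr::bind_rows(rows)
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Haptoglobin episode threshold implied by a configuration
#'
#' Baseline plus three baseline SDs, the convention used throughout the
#' package for calling (sub)clinical inflammation.
#'
#' @param config A [study_config()] object.
#' @return Numeric threshold.
#' @export
hapto_threshold <- function(config) {
  hp <- config$biomarker_params$haptoglobin
  hp$baseline + 3 * hp$sd
}

#' Simulate a complete longitudinal study
#'
#' Generates profiles, schedules (shared by milk and blood visits),
#' trajectories, inflammation episodes, biomarkers and per-sample metadata.
#' Event matrices are not materialised here; [events_for_sample()]
#' regenerates them deterministically from the stored per-sample seed.
#'
#' @param config A [study_config()] object.
#' @param seed Integer seed controlling every downstream draw.
#' @return A list of class `hrdcc_study` with elements `config`, `profiles`,
#'   `samples`, `states`, `episodes`, `biomarkers`, `seed`.
#' @export
simulate_study <- function(config = study_config(), seed = 1) {
  profiles <- generate_animal_profiles(config, seed = derive_seed(seed, "profiles"))
  states <- list()
  episodes <- list()
  biomarkers <- list()
  samples <- list()
  for (i in seq_len(nrow(profiles))) {
    prof <- profiles[i, ]
    id <- prof$animal_id
    sched <- generate_schedule(prof$lactation_days, config$schedule,
                               config$dropout_prob,
                               seed = derive_seed(seed, paste0("sched_", id)))
    if (!is.null(config$max_visits) && length(sched) > config$max_visits) {
      sched <- sched[unique(round(seq(1, length(sched),
                                      length.out = config$max_visits)))]
    }
    st <- dplyr::bind_rows(
      generate_trajectories(prof, sched, config$trajectories, "milk",
                            seed = derive_seed(seed, paste0("traj_milk_", id))),
      generate_trajectories(prof, sched, config$trajectories, "blood",
                            seed = derive_seed(seed, paste0("traj_blood_", id)))
    )
    inj <- inject_episodes(st, config$episode_params, prof$lactation_days,
                           seed = derive_seed(seed, paste0("ep_", id)))
    states[[id]] <- inj$states
    episodes[[id]] <- inj$episodes
    biomarkers[[id]] <- generate_biomarkers(
      prof, sched, inj$episodes, config$biomarker_params,
      config$episode_params, seed = derive_seed(seed, paste0("bm_", id)))
    samples[[id]] <- tidyr::expand_grid(
      animal_id = id, dim = as.integer(sched), matrix = c("milk", "blood"))
  }
  samples <- dplyr::bind_rows(samples)
  samples$sample_id <- sprintf("%s_%s_d%03d", samples$animal_id,
                               samples$matrix, samples$dim)
  samples$event_seed <- purrr::map_int(samples$sample_id,
                                       ~ derive_seed(seed, paste0("ev_", .x)))
  samples <- dplyr::select(samples, "sample_id", "animal_id", "dim",
                           "matrix", "event_seed")
  structure(list(config = config, profiles = profiles,
                 samples = samples,
                 states = dplyr::bind_rows(states),
                 episodes = dplyr::bind_rows(episodes),
                 biomarkers = dplyr::bind_rows(biomarkers),
                 seed = seed),
            class = "hrdcc_study")
}

#' @export
print.hrdcc_study <- function(x, ...) {
  cat("<hrdcc_study>\n")
  cat(" ", nrow(x$profiles), "animals,", nrow(x$samples), "samples,",
      nrow(x$episodes), "true episodes, seed", x$seed, "\n")
  invisible(x)
}

#' Regenerate the event matrix of one study sample
#'
#' Deterministic given the study (per-sample seeds are fixed at simulation
#' time), so event-level data never need to be stored.
#'
#' @param study An `hrdcc_study`.
#' @param sample_id One of `study$samples$sample_id`.
#' @param n_events Override the configured number of events.
#' @return An event matrix tibble (see [synthesize_events()]).
#' @export
events_for_sample <- function(study, sample_id, n_events = NULL) {
  row <- study$samples[study$samples$sample_id == sample_id, ]
  if (nrow(row) != 1) abort(sprintf("unknown sample_id: %s", sample_id))
  st <- study$states[study$states$animal_id == row$animal_id &
                       study$states$dim == row$dim &
                       study$states$matrix == row$matrix, ]
  pops <- terminal_populations(row$matrix)
  fractions <- setNames(as.numeric(st[1, pops]), pops)
  include_panck <- !(row$matrix == "milk" &&
                       row$dim < study$config$panck_from_dim)
  synthesize_events(
    fractions,
    n_events = n_events %||% study$config$n_events,
    panel = study$config$panel,
    signatures = study$config$signatures,
    nuisance_fractions = study$config$nuisance,
    viability = st$viability[1],
    cofactor = study$config$cofactor,
    include_panck = include_panck,
    sample_id = row$sample_id,
    seed = row$event_seed
  )
}
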