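test_that("schedule density matches the twice-weekly/weekly design", {
  s <- generate_schedule(300, dropout_prob = 0)
  expect_false(is.unsorted(s, strictly = TRUE))
  # 2/week over 100 d + 1/week over 200 d is about 57 visits
  expect_gte(length(s), 55)
  expect_lte(length(s), 59)
  early <- s[s <= 100]
  late <- s[s > 100]
  expect_gt(length(early) / 100, 1.8 / 7)
  expect_equal(diff(late), rep(7, length(late) - 1))

  expect_length(generate_schedule(300, dropout_prob = 1, seed = 1), 0)
  expect_error(generate_schedule(80), "cutoff")
})

test_that("default dropout yields about 55 visits per animal", {
  cfg <- study_config()
  n <- vapply(1:40, function(i) {
    lact <- 291 + (i %% 15)
    length(generate_schedule(lact, cfg$schedule, cfg$dropout_prob, seed = i))
  }, numeric(1))
  expect_gt(mean(n), 52)
  expect_lt(mean(n), 58)
})

test_that("animal profiles carry the named cow CD4 baselines", {
  prof <- generate_animal_profiles(study_config(), seed = 7)
  expect_equal(nrow(prof), 8)
  expect_equal(prof$blood_cd4_mean[prof$animal_id == "cow1"], 0.347)
  expect_equal(prof$blood_cd4_sd[prof$animal_id == "cow1"], 0.029)
  expect_equal(prof$blood_cd4_mean[prof$animal_id == "cow6"], 0.197)
  expect_equal(prof$blood_cd4_sd[prof$animal_id == "cow6"], 0.026)

  cfg0 <- study_config()
  cfg0$animal_effect_sd <- 0
  p0 <- generate_animal_profiles(cfg0, seed = 7)
  expect_true(all(p0$off_milk_gran == 0))
  expect_true(all(p0$off_milk_gdt == 0))

  cfg_bad <- study_config()
  cfg_bad$animal_effect_sd <- -1
  expect_error(generate_animal_profiles(cfg_bad), "animal_effect_sd")
})

test_that("zero volatility reproduces the deterministic mean curves", {
  cfg <- study_config()
  prof <- generate_animal_profiles(cfg, seed = 1)[1, ]
  prof[c("off_milk_gran", "off_milk_gdt", "off_blood_gran",
         "off_viability")] <- 0
  sched <- generate_schedule(300, cfg$schedule, 0, seed = 1)
  st <- generate_trajectories(prof, sched, cfg$trajectories, "milk",
                              volatility = 0, seed = 1)
  lymph <- rowSums(st[c("NK", "gdT", "CD4T", "CD8T", "B", "lymph_other")])
  lp <- cfg$trajectories$milk$lymph
  expect_equal(st$gdT / lymph,
               hrdcc:::milk_gdt_curve(st$dim, lp), tolerance = 1e-9)
  expect_equal(st$viability,
               hrdcc:::milk_viability_curve(st$dim,
                                            cfg$trajectories$milk$viability),
               tolerance = 1e-9)
})

test_that("milk gdT declines and blood CD4 variation matches the profile", {
  cfg <- study_config()
  prof <- generate_animal_profiles(cfg, seed = 2)[1, ]
  early_m <- late_m <- sds <- numeric(20)
  for (i in 1:20) {
    sched <- generate_schedule(300, cfg$schedule, 0, seed = i)
    milk <- generate_trajectories(prof, sched, cfg$trajectories, "milk",
                                  seed = 100 + i)
    lymph <- rowSums(milk[c("NK", "gdT", "CD4T", "CD8T", "B", "lymph_other")])
    gdt <- milk$gdT / lymph
    early_m[i] <- mean(gdt[milk$dim <= 50])
    late_m[i] <- mean(gdt[milk$dim >= 251])
    blood <- generate_trajectories(prof, sched, cfg$trajectories, "blood",
                                   seed = 200 + i)
    lb <- rowSums(blood[c("NK", "gdT", "CD4T", "CD8T", "B", "lymph_other")])
    sds[i] <- sd(blood$CD4T / lb)
  }
  expect_true(all(early_m > late_m))
  # per-animal SD of blood CD4 close to the configured per-visit SD
  expect_lt(abs(mean(sds) - prof$blood_cd4_sd) / prof$blood_cd4_sd, 0.3)
})

test_that("milk level-1 noise is larger before the level-out DIM", {
  cfg <- study_config()
  prof <- generate_animal_profiles(cfg, seed = 3)[1, ]
  sds <- sapply(1:25, function(i) {
    sched <- generate_schedule(300, cfg$schedule, 0, seed = i)
    milk <- generate_trajectories(prof, sched, cfg$trajectories, "milk",
                                  seed = 300 + i)
    gran <- milk$neut + milk$eos + milk$imm_gran
    c(sd(gran[milk$dim < 150]), sd(gran[milk$dim >= 150]))
  })
  expect_gt(mean(sds[1, ]), mean(sds[2, ]))
})

test_that("terminal fractions always sum to one", {
  st <- tiny_study()
  for (m in c("milk", "blood")) {
    sub <- st$states[st$states$matrix == m, ]
    s <- rowSums(sub[hrdcc:::terminal_populations(m)])
    expect_true(all(abs(s - 1) < 1e-9))
  }
})

test_that("episode injection shifts gdT down, CD4 up, imm_gran untouched", {
  cfg <- study_config()
  prof <- generate_animal_profiles(cfg, seed = 4)[1, ]
  sched <- generate_schedule(300, cfg$schedule, 0, seed = 4)
  st <- generate_trajectories(prof, sched, cfg$trajectories, "milk",
                              seed = 4)
  forced <- tibble::tibble(start_dim = 75, end_dim = 96)
  inj <- inject_episodes(st, cfg$episode_params, 300, forced = forced)
  hit <- st$dim >= 75 & st$dim <= 96
  expect_true(all(inj$states$gdT[hit] < st$gdT[hit]))
  expect_true(all(inj$states$CD4T[hit] > st$CD4T[hit]))
  expect_equal(inj$states$imm_gran, st$imm_gran)
  expect_equal(inj$states$gdT[!hit], st$gdT[!hit])

  # zero rate leaves states untouched
  cfg0 <- cfg$episode_params; cfg0$rate <- 0
  inj0 <- inject_episodes(st, cfg0, 300, seed = 9)
  expect_equal(inj0$states, st)
  expect_equal(nrow(inj0$episodes), 0)

  # overlapping forced episodes are merged
  over <- tibble::tibble(start_dim = c(70, 80), end_dim = c(90, 110))
  injo <- inject_episodes(st, cfg$episode_params, 300, forced = over)
  expect_equal(nrow(injo$episodes), 1)
  expect_equal(injo$episodes$end_dim, 110)

  expect_error(inject_episodes(st[order(-st$dim), ], cfg$episode_params),
               "sorted")
})

test_that("biomarkers encode early-lactation elevation and episode haptoglobin", {
  cfg <- study_config()
  prof <- generate_animal_profiles(cfg, seed = 5)[1, ]
  prof$has_calving_elevation <- FALSE
  sched <- generate_schedule(300, cfg$schedule, 0, seed = 5)
  no_ep <- tibble::tibble(start_dim = numeric(), end_dim = numeric())
  nefa_contrast <- sapply(1:20, function(i) {
    bm <- generate_biomarkers(prof, sched, no_ep, cfg$biomarker_params,
                              cfg$episode_params, seed = i)
    nefa <- bm[bm$analyte == "NEFA", ]
    mean(nefa$value[nefa$dim <= 50]) - mean(nefa$value[nefa$dim >= 101 &
                                                         nefa$dim <= 150])
  })
  expect_true(all(nefa_contrast > 0))

  bm <- generate_biomarkers(prof, sched, no_ep, cfg$biomarker_params,
                            cfg$episode_params, seed = 6)
  expect_true(all(bm$value > 0))
  hp <- bm[bm$analyte == "haptoglobin", ]
  thr <- hapto_threshold(cfg)
  # without episodes or calving elevation, essentially nothing crosses
  expect_lt(mean(hp$value > thr), 0.02)

  ep <- tibble::tibble(start_dim = 75, end_dim = 96)
  bm_ep <- generate_biomarkers(prof, sched, ep, cfg$biomarker_params,
                               cfg$episode_params, seed = 6)
  hp_ep <- bm_ep[bm_ep$analyte == "haptoglobin", ]
  in_ep <- hp_ep$dim >= 75 & hp_ep$dim <= 96
  expect_true(all(hp_ep$value[in_ep] > thr))

  # infinitely fast decay leaves analytes flat at baseline
  flat_params <- cfg$biomarker_params
  flat_params$NEFA$decay_tau <- 1e-9
  flat_params$NEFA$noise_cv <- 0
  bm_flat <- generate_biomarkers(prof, sched, no_ep, flat_params,
                                 cfg$episode_params, seed = 7)
  expect_equal(unique(bm_flat$value[bm_flat$analyte == "NEFA"]), 0.30)

  bad <- cfg$biomarker_params; bad$NEFA$baseline <- -1
  expect_error(generate_biomarkers(prof, sched, no_ep, bad,
                                   cfg$episode_params), "baseline")
})

test_that("event synthesis respects fractions, nuisance classes and panCK", {
  frac <- c(A = 0.3, B = 0.7)
  sig <- dplyr::bind_rows(
    dplyr::mutate(default_signatures()[default_signatures()$population ==
                                         "CD4T", ], population = "A"),
    dplyr::mutate(default_signatures()[default_signatures()$population ==
                                         "B", ], population = "B"))
  ev <- synthesize_events(frac, 100000, signatures = sig,
                          nuisance_fractions = list(debris = 0, doublet = 0),
                          viability = 1, seed = 11)
  tab <- table(ev$.label)
  se <- sqrt(0.3 * 0.7 / 100000)
  expect_lt(abs(tab[["A"]] / 100000 - 0.3), 4 * se)

  # single population, no nuisance: all events share the label
  ev1 <- synthesize_events(c(CD4T = 1), 2000,
                           nuisance_fractions = list(debris = 0, doublet = 0),
                           viability = 1, seed = 2)
  expect_equal(unique(ev1$.label), "CD4T")

  # doublets sit near FSC-A = 2 x FSC-H, dead events high on the dye
  ev2 <- synthesize_events(c(CD4T = 1), 20000,
                           nuisance_fractions = list(debris = 0.1,
                                                     doublet = 0.1),
                           viability = 0.7, seed = 3)
  r <- ev2$`FSC-A` / ev2$`FSC-H`
  expect_gt(median(r[ev2$.label == "doublet"]), 1.8)
  expect_lt(median(r[ev2$.label == "CD4T"]), 1.2)
  expect_gt(median(asinh(ev2$Viability[ev2$.label == "dead"] / 150)), 3)
  expect_lt(median(ev2$`FSC-A`[ev2$.label == "debris"]), 20000)

  expect_error(synthesize_events(c(XX = 1), 1000), "signature")

  st <- tiny_study()
  early_milk <- st$samples$sample_id[st$samples$matrix == "milk" &
                                       st$samples$dim < 50][1]
  late_milk <- st$samples$sample_id[st$samples$matrix == "milk" &
                                      st$samples$dim >= 50][1]
  expect_false("panCK" %in% names(events_for_sample(st, early_milk)))
  expect_true("panCK" %in% names(events_for_sample(st, late_milk)))
})

test_that("same seed gives bit-identical studies and event matrices", {
  cfg <- tiny_config()
  a <- simulate_study(cfg, seed = 5)
  b <- simulate_study(cfg, seed = 5)
  expect_identical(a$states, b$states)
  expect_identical(a$samples, b$samples)
  expect_identical(a$biomarkers, b$biomarkers)
  sid <- a$samples$sample_id[3]
  expect_identical(events_for_sample(a, sid), events_for_sample(b, sid))
})

test_that("event proportions are calibrated to the requested fractions", {
  st <- default_study()
  ids <- st$samples$sample_id[seq(1, nrow(st$samples), length.out = 100)]
  errs <- purrr::map_dbl(ids, function(sid) {
    ev <- events_for_sample(st, sid)
    row <- st$samples[st$samples$sample_id == sid, ]
    state <- st$states[st$states$animal_id == row$animal_id &
                         st$states$dim == row$dim &
                         st$states$matrix == row$matrix, ]
    pops <- hrdcc:::terminal_populations(row$matrix)
    lab <- ev$.label[!ev$.label %in% c("debris", "doublet", "dead")]
    emp <- table(factor(lab, levels = pops)) / length(lab)
    mean(abs(emp - as.numeric(state[1, pops])))
  })
  # mean absolute error below half a percentage point
  expect_lt(mean(errs) * 100, 0.5)
})
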