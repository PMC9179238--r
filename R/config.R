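#' Default study configuration
#'
#' Builds the configuration object that drives the synthetic longitudinal
#' study: an eight-cow herd followed over a full lactation (291--305 days),
#' sampled twice weekly for the first 100 days in milk (DIM) and weekly
#' thereafter, in both milk and blood. The defaults encode the study
#' conditions the package is calibrated to:
#'
#' * milk gamma-delta T cells decline roughly linearly from ~40% to ~8% of
#'   lymphocytes over lactation while milk CD4+ T cells rise in mirror
#'   image; milk NK cells decline and nonclassical macrophages expand
#'   slowly over the same span;
#' * milk granulocyte/lymphocyte fractions fluctuate strongly before about
#'   150 DIM and settle afterwards; milk macrophages stay low and flat;
#' * milk cell viability is poor immediately post partum, recovers quickly
#'   and keeps creeping upwards late in lactation;
#' * blood populations are stationary around cow-specific baselines (the
#'   named `cow1` and `cow6` profiles carry blood CD4+ baselines of
#'   34.7% (SD 2.9) and 19.7% (SD 2.6) of lymphocytes);
#' * serum NEFA, beta-HBA and bilirubin are elevated in early lactation
#'   (negative energy balance) and decay exponentially to baseline;
#'   haptoglobin is flat except during inflammation episodes and an
#'   optional calving window.
#'
#' @param n_animals Number of cows in the herd.
#' @param n_events Events acquired per cytometry sample.
#' @param dropout_prob Probability that any scheduled visit is missed.
#' @param cofactor Arcsinh cofactor used for marker channels (raw intensities
#'   are `cofactor * sinh(z)` of the transformed-scale signatures).
#' @param episode_rate Expected number of inflammation episodes per
#'   lactation (Poisson).
#' @param max_visits Optional cap on visits per animal (evenly thinned
#'   across the lactation); used by the tiny test fixture.
#' @return A list of class `hrdcc_config`.
#' @export
study_config <- function(n_animals = 8,
                         n_events = 50000,
                         dropout_prob = 0.035,
                         cofactor = 150,
                         episode_rate = 0.6,
                         max_visits = NULL) {
  cfg <- list(
    n_animals = n_animals,
    lactation_days_range = c(291, 305),
    schedule = list(twice_weekly_until = 100, late_interval = 7),
    dropout_prob = dropout_prob,
    n_events = n_events,
    cofactor = cofactor,
    panel = hrdcc_panel(),
    signatures = default_signatures(),
    nuisance = list(debris = 0.05, doublet = 0.03),
    animal_effect_sd = 0.15,
    blood_cd4_between = list(mean = 0.27, sd = 0.045),
    named_profiles = list(
      cow1 = list(blood_cd4_mean = 0.347, blood_cd4_sd = 0.029),
      cow6 = list(blood_cd4_mean = 0.197, blood_cd4_sd = 0.026)
    ),
    trajectories = default_trajectories(),
    episode_params = list(
      rate = episode_rate, duration_range = c(14, 22),
      hapto_amplitude = 1.5, gdt_shift = -0.08, cd4_shift = 0.08,
      calving_prob = 0.25, calving_amp = 1.5, calving_tau = 7,
      calving_window = 12
    ),
    biomarker_params = list(
      haptoglobin = list(baseline = 1.0, sd = 0.15),
      calcium = list(baseline = 2.45, early_amp = -0.25, decay_tau = 10, noise_cv = 0.04),
      NEFA = list(baseline = 0.30, early_amp = 0.70, decay_tau = 30, noise_cv = 0.12),
      bHBA = list(baseline = 0.60, early_amp = 0.60, decay_tau = 35, noise_cv = 0.10),
      bilirubin = list(baseline = 2.5, early_amp = 4.0, decay_tau = 25, noise_cv = 0.15),
      GLDH = list(baseline = 15, early_amp = 10, decay_tau = 50, noise_cv = 0.20)
    ),
    gates = reference_gates(),
    panck_from_dim = 50,
    max_visits = max_visits
  )
  class(cfg) <- "hrdcc_config"
  validate_config(cfg)
}

#' @export
print.hrdcc_config <- function(x, ...) {
  cat("<hrdcc_config>\n")
  cat("  animals:", x$n_animals,
      " events/sample:", x$n_events,
      " dropout:", x$dropout_prob, "\n")
  cat("  panel:", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}

validate_config <- function(cfg) {
  assert_prob(cfg$dropout_prob, "dropout_prob")
  assert_prob(cfg$nuisance$debris, "nuisance$debris")
  assert_prob(cfg$nuisance$doublet, "nuisance$doublet")
  if (cfg$animal_effect_sd < 0) abort("animal_effect_sd must be >= 0")
  if (any(cfg$signatures$scale <= 0)) abort("signature scales must be > 0")
  if (cfg$n_events < 1) abort("n_events must be >= 1")
  for (bm in names(cfg$biomarker_params)) {
    if (cfg$biomarker_params[[bm]]$baseline < 0) {
      abort(sprintf("biomarker baseline for %s must be non-negative", bm))
    }
  }
  cfg
}

#' Cytometry panel channel names
#' @return Character vector of channel names.
#' @export
hrdcc_panel <- function() {
  c("FSC-A", "FSC-H", "SSC-A", "CD45", "CD14", "CD16", "CD11b", "CD335",
    "gdTCR", "CD4", "CD8", "CD21", "panCK", "Viability", "AF")
}

# terminal population labels per matrix (reported subsets + remainders)
terminal_populations <- function(matrix) {
  common <- c("neut", "eos", "imm_gran", "NK", "gdT", "CD4T", "CD8T", "B",
              "lymph_other")
  if (matrix == "blood") c(common, "cM", "intM", "ncM")
  else c(common, "cMac", "ncMac", "MEC")
}

# The 10 (blood) / 9 (milk) reported subpopulations
reported_subsets <- function(matrix) {
  base <- c("eos", "imm_gran", "NK", "gdT", "CD4T", "CD8T", "B")
  if (matrix == "blood") c(base, "cM", "intM", "ncM") else c(base, "cMac", "ncMac")
}

#' Per-population channel signatures
#'
#' Location/scale of every terminal population on every panel channel.
#' Marker channels are parameterised on the arcsinh-transformed scale
#' (positive ~4.2, negative ~0.6, SD 0.3); scatter channels are linear.
#'
#' @return A tibble with columns `population`, `channel`, `location`, `scale`.
#' @export
default_signatures <- function() {
  pops <- c("neut", "eos", "imm_gran", "cM", "intM", "ncM", "cMac", "ncMac",
            "NK", "gdT", "CD4T", "CD8T", "B", "lymph_other", "MEC")
  scatter <- list( # FSC-A loc/sd, SSC-A loc/sd
    neut = c(95000, 10000, 105000, 10000),
    eos = c(95000, 10000, 112000, 10000),
    imm_gran = c(95000, 10000, 105000, 10000),
    cM = c(85000, 9000, 45000, 6000),
    intM = c(85000, 9000, 45000, 6000),
    ncM = c(85000, 9000, 45000, 6000),
    cMac = c(85000, 9000, 45000, 6000),
    ncMac = c(85000, 9000, 45000, 6000),
    NK = c(60000, 7000, 15000, 3000),
    gdT = c(60000, 7000, 15000, 3000),
    CD4T = c(60000, 7000, 15000, 3000),
    CD8T = c(60000, 7000, 15000, 3000),
    B = c(60000, 7000, 15000, 3000),
    lymph_other = c(60000, 7000, 15000, 3000),
    MEC = c(110000, 12000, 40000, 8000)
  )
  neg <- 0.6
  pos <- list( # positive marker locations per population
    neut = c(CD45 = 4.2, CD11b = 4.4),
    eos = c(CD45 = 4.2, CD11b = 4.4, AF = 3.8),
    imm_gran = c(CD45 = 4.2, CD11b = 2.2),
    cM = c(CD45 = 4.2, CD14 = 4.3, CD11b = 3.5),
    intM = c(CD45 = 4.2, CD14 = 4.3, CD16 = 4.2, CD11b = 3.5),
    ncM = c(CD45 = 4.2, CD16 = 4.2, CD11b = 3.5),
    cMac = c(CD45 = 4.2, CD14 = 4.3, CD11b = 3.5),
    ncMac = c(CD45 = 4.2, CD14 = 1.5, CD16 = 4.2, CD11b = 3.5),
    NK = c(CD45 = 4.2, CD335 = 4.2),
    gdT = c(CD45 = 4.2, gdTCR = 4.3),
    CD4T = c(CD45 = 4.2, CD4 = 4.3),
    CD8T = c(CD45 = 4.2, CD8 = 4.3),
    B = c(CD45 = 4.2, CD21 = 4.2),
    lymph_other = c(CD45 = 4.2),
    MEC = c(panCK = 4.0)
  )
  markers <- setdiff(hrdcc_panel(), c("FSC-A", "FSC-H", "SSC-A"))
  rows <- purrr::map_dfr(pops, function(p) {
    sc <- scatter[[p]]
    loc <- setNames(rep(neg, length(markers)), markers)
    loc["AF"] <- 0.9
    loc["Viability"] <- 0.6 # live; dead events overridden at synthesis
    loc[names(pos[[p]])] <- pos[[p]]
    scl <- setNames(rep(0.30, length(markers)), markers)
    if (p == "ncMac") scl["CD14"] <- 1.0 # CD14 +/- straddle
    tibble::tibble(
      population = p,
      channel = c("FSC-A", "SSC-A", markers),
      location = c(sc[1], sc[3], unname(loc)),
      scale = c(sc[2], sc[4], unname(scl))
    )
  })
  rows
}

# signature of dead events: population signature with Viability pushed high
dead_viability <- function() c(location = 4.0, scale = 0.35)

# debris signature: low scatter, everything negative
debris_signature <- function() {
  list(fsc = c(8000, 3000), ssc = c(5000, 2000), marker = c(0.4, 0.3))
}

# Default trajectory parameterisation (fractions on the relevant parent).
default_trajectories <- function() {
  list(
    milk = list(
      level1 = list(gran_mean = 0.55, gran_sd_early = 0.10, gran_sd_late = 0.04,
                    mac_mean = 0.10, mac_sd = 0.02, level_out_dim = 150),
      mec = list(mean = 0.03, sd = 0.01),
      lymph = list(gdt_start = 0.40, gdt_end = 0.08,
                   cd4_start = 0.08, cd4_end = 0.40,
                   gdt_sd = 0.04, cd4_sd = 0.04,
                   nk_start = 0.07, nk_end = 0.015, nk_sd = 0.010,
                   cd8_mean = 0.28, cd8_sd = 0.030,
                   b_mean = 0.05, b_sd = 0.015),
      gran_sub = list(eos_mean = 0.02, eos_sd = 0.008,
                      imm_mean = 0.06, imm_sd = 0.015),
      mono_sub = list(cmac_start = 0.82, cmac_end = 0.50, cmac_sd = 0.05),
      viability = list(floor = 0.40, rise = 0.35, tau = 25,
                       late_slope = 8e-4, cap = 0.995, sd = 0.02)
    ),
    blood = list(
      level1 = list(gran_mean = 0.30, gran_sd = 0.03,
                    mono_mean = 0.08, mono_sd = 0.012),
      lymph = list(cd4_mean = 0.27, cd4_sd = 0.029,
                   gdt_mean = 0.15, gdt_sd = 0.02,
                   nk_mean = 0.08, nk_sd = 0.015,
                   cd8_mean = 0.13, cd8_sd = 0.02,
                   b_mean = 0.20, b_sd = 0.025),
      gran_sub = list(eos_mean = 0.05, eos_sd = 0.012,
                      imm_mean = 0.03, imm_sd = 0.010),
      mono_sub = list(cm_mean = 0.82, cm_sd = 0.04,
                      intm_mean = 0.06, intm_sd = 0.015),
      viability = list(mean = 0.97, sd = 0.01)
    )
  )
}

# Fixed reference-mode gate positions: midpoints of the positive/negative
# signature locations (scatter cuts between lineage scatter modes).
reference_gates <- function() {
  list(
    debris_fsc = 25000, debris_ssc = 11000,
    doublet_ratio = 1.5,
    viability = 2.3,
    cd45 = 2.4,
    ssc_cuts = c(28000, 75000),
    af = 2.35,
    cd11b = 3.3,
    cd14 = 2.45, cd16 = 2.40,
    cd335 = 2.4, gdtcr = 2.45, cd4 = 2.45, cd8 = 2.45, cd21 = 2.4,
    panck = 2.25
  )
}
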