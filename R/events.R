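#' Synthesize a flow cytometry event matrix
#'
#' Draws events from per-population location/scale clusters. Marker
#' channels are simulated on the arcsinh-transformed scale and emitted as
#' raw compensated intensities (`cofactor * sinh(z)`); scatter channels are
#' linear. Nuisance classes are included so downstream gating has something
#' to exclude: debris (low FSC/SSC), doublets (FSC-A about twice FSC-H) and
#' dead cells (high viability-dye signal). True class labels are kept in a
#' `.label` column.
#'
#' @param fractions Named numeric vector of terminal-population fractions
#'   (summing to 1) among intact cells.
#' @param n_events Total events to draw (>= 1000 for realistic samples; the
#'   hard floor here is 1).
#' @param panel Channel names (see [hrdcc_panel()]).
#' @param signatures Signature tibble as from [default_signatures()].
#' @param nuisance_fractions List with `debris` and `doublet` fractions.
#' @param viability Fraction of intact single cells that are alive.
#' @param cofactor Arcsinh cofactor for the raw marker scale.
#' @param separation Multiplier on the distance of every signature location
#'   from its channel mean; 0 collapses all populations onto one cluster.
#' @param include_panck Drop the panCK column when `FALSE` (milk samples
#'   before 50 DIM carry no panCK measurement).
#' @param sample_id Identifier stored as an attribute.
#' @param seed Optional integer seed.
#' @return Tibble of events x channels with a `.label` column; attributes
#'   `sample_id` and `cofactor`.
#' @export
synthesize_events <- function(fractions, n_events, panel = hrdcc_panel(),
                              signatures = default_signatures(),
                              nuisance_fractions = list(debris = 0.05,
                                                        doublet = 0.03),
                              viability = 0.97, cofactor = 150,
                              separation = 1, include_panck = TRUE,
                              sample_id = "sample", seed = NULL) {
  if (n_events < 1) abort("n_events must be >= 1")
  assert_prob(viability, "viability")
  bad <- setdiff(unique(signatures$channel), panel)
  if (length(bad)) {
    abort(sprintf("unknown channel(s) in signatures: %s",
                  paste(bad, collapse = ", ")))
  }
  pops <- names(fractions)
  missing_sig <- setdiff(pops, unique(signatures$population))
  if (length(missing_sig)) {
    abort(sprintf("no signature for population(s): %s",
                  paste(missing_sig, collapse = ", ")))
  }
  if (abs(sum(fractions) - 1) > 1e-6) abort("fractions must sum to 1")

  gen <- function() {
    f_debris <- nuisance_fractions$debris
    f_doublet <- nuisance_fractions$doublet
    cls <- sample(c("debris", "doublet", "cell"), n_events, replace = TRUE,
                  prob = c(f_debris, f_doublet, 1 - f_debris - f_doublet))
    n_cell <- sum(cls != "debris")
    # every non-debris event carries an underlying population
    pop <- rep(NA_character_, n_events)
    idx <- cls != "debris"
    pop[idx] <- sample(pops, sum(idx), replace = TRUE, prob = fractions)
    dead <- idx & (runif(n_events) > viability) & cls != "doublet"

    # location/scale lookup matrices [population x channel]
    sig_chans <- c("FSC-A", "SSC-A",
                   setdiff(panel, c("FSC-A", "FSC-H", "SSC-A")))
    L <- S <- matrix(NA_real_, length(pops), length(sig_chans),
                     dimnames = list(pops, sig_chans))
    for (p in pops) {
      sg <- signatures[signatures$population == p, ]
      L[p, sg$channel] <- sg$location
      S[p, sg$channel] <- sg$scale
    }
    if (any(is.na(L))) abort("signatures must cover every panel channel")
    if (separation != 1) {
      ctr <- colMeans(L)
      L <- sweep(L, 2, ctr) * separation
      L <- sweep(L, 2, ctr, `+`)
    }

    pi <- match(pop, pops)
    z <- matrix(rnorm(n_events * length(sig_chans)), n_events,
                dimnames = list(NULL, sig_chans))
    loc <- L[pi, , drop = FALSE]
    scl <- S[pi, , drop = FALSE]
    z <- z * scl + loc

    # debris overrides
    db <- debris_signature()
    ndb <- sum(cls == "debris")
    if (ndb > 0) {
      di <- which(cls == "debris")
      z[di, "FSC-A"] <- rnorm(ndb, db$fsc[1], db$fsc[2])
      z[di, "SSC-A"] <- rnorm(ndb, db$ssc[1], db$ssc[2])
      mk <- setdiff(sig_chans, c("FSC-A", "SSC-A"))
      z[di, mk] <- matrix(rnorm(ndb * length(mk), db$marker[1], db$marker[2]),
                          ndb)
    }
    dv <- dead_viability()
    if (any(dead)) {
      z[dead, "Viability"] <- rnorm(sum(dead), dv["location"], dv["scale"])
    }

    fsc_a <- pmax(z[, "FSC-A"], 100)
    ssc_a <- pmax(z[, "SSC-A"], 50)
    ratio <- rnorm(n_events, 1.05, 0.04)
    fsc_h <- fsc_a / ratio
    is_dbl <- cls == "doublet"
    if (any(is_dbl)) {
      fsc_a[is_dbl] <- fsc_a[is_dbl] * 2 * rnorm(sum(is_dbl), 1, 0.05)
      ssc_a[is_dbl] <- ssc_a[is_dbl] * 1.8
    }

    markers <- setdiff(sig_chans, c("FSC-A", "SSC-A"))
    raw <- cofactor * sinh(z[, markers, drop = FALSE])
    out <- tibble::as_tibble(raw)
    out$`FSC-A` <- fsc_a
    out$`FSC-H` <- pmax(fsc_h, 50)
    out$`SSC-A` <- ssc_a
    out <- out[, panel]
    if (!include_panck) out$panCK <- NULL
    lab <- pop
    lab[cls == "debris"] <- "debris"
    lab[is_dbl] <- "doublet"
    lab[dead] <- "dead"
    out$.label <- lab
    attr(out, "sample_id") <- sample_id
    attr(out, "cofactor") <- cofactor
    attr(out, "transformed") <- FALSE
    class(out) <- c("event_matrix", class(out))
    out
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' @export
print.event_matrix <- function(x, ...) {
  cat(sprintf("<event_matrix> %s: %d events x %d channels (%s scale)\n",
              attr(x, "sample_id") %||% "?", nrow(x),
              sum(names(x) != ".label"),
              if (isTRUE(attr(x, "transformed"))) "transformed" else "raw"))
  NextMethod()
}

# channel columns of an event matrix (excludes the truth label)
event_channels <- function(events) setdiff(names(events), ".label")
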