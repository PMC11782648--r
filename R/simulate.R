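# Synthetic sediment-microcosm generator with known ground truth.
#
# The simulator emulates anoxic estuarine microcosms amended with inorganic
# carbon (Ci), an organic carbon mix (Co), nitrate and sulfide, in which
# guilds couple electron donors (OM carbon at 4 e-/C, sulfide at 8 e-/S to
# sulfate or 2 e-/S to zero-valent sulfur) to acceptors (nitrate at 5 e-/N to
# N2, 4 e-/N to N2O, 8 e-/N to ammonium; sulfate at 8 e-/S). Every electron
# released by a donor in a step is consumed by an acceptor in the same step,
# so the electron ledger closes exactly and N and S atom totals are conserved.
# Ground truth (pre-noise pools, per-taxon isotope incorporation, true
# ledgers) is recorded alongside the noisy observations.

GUILDS <- c("CHEMOLITHOAUTOTROPH", "CONVENTIONAL_HD", "FSOHD_COMPLETE",
            "FSOHD_INCOMPLETE", "DNRA_HETEROTROPH", "SULFATE_REDUCER", "INERT")

ANALYTES <- c("NO3", "NO2", "N2O", "N2", "NH4",
              "sulfide", "S0", "S2O3", "SO3", "SO4", "OM_C")

guild_markers <- function(guild) {
  switch(guild,
         CHEMOLITHOAUTOTROPH = c("sqr", "soxB", "napA"),
         CONVENTIONAL_HD = c("nirS", "nosZ"),
         FSOHD_COMPLETE = c("sqr", "nirS", "nosZ"),
         FSOHD_INCOMPLETE = c("sqr", "nirS", "nosZ"),
         DNRA_HETEROTROPH = c("narG", "nrfA"),
         SULFATE_REDUCER = "dsrA",
         INERT = character(0))
}

#' Expected function flags per simulated guild
#'
#' The ground-truth mapping from simulator guild to the flags that the
#' treatment-comparison rules should raise, used by recovery tests.
#' @return named list of character vectors.
#' @export
guild_truth_flags <- function() {
  list(
    CHEMOLITHOAUTOTROPH = c("chemolithoautotroph",
                            "nitrate_reducer_sulfur_oxidizer",
                            "autotroph_sulfide_oxidizer"),
    CONVENTIONAL_HD = "heterotroph",
    FSOHD_COMPLETE = c("heterotroph", "sulfide_oxidizer",
                       "heterotroph_sulfide_oxidizer", "fsohd"),
    FSOHD_INCOMPLETE = c("heterotroph", "sulfide_oxidizer",
                         "heterotroph_sulfide_oxidizer", "fsohd"),
    DNRA_HETEROTROPH = "heterotroph",
    SULFATE_REDUCER = "heterotroph",
    INERT = character(0))
}

#' Generate a reproducible synthetic community
#'
#' Guild counts follow the requested proportions by largest-remainder
#' rounding; initial relative abundances are Dirichlet-distributed; GC
#' contents are uniform on a realistic bacterial range.
#'
#' @param n_taxa number of taxa (>= 1).
#' @param guild_mix named proportions over the guilds, summing to 1.
#' @param seed RNG seed.
#' @param gc_range range of GC contents.
#' @param dirichlet_alpha concentration parameter for initial abundances.
#' @return data frame of class `taxon_community` with columns `name`,
#'   `guild`, `gc`, `abundance`, `growth_yield` (uM biomass-C per uM e-),
#'   `uptake_om`, `uptake_sulfide` (uM donor per uM biomass-C per h) and
#'   `sulfide_inhibition_threshold` (uM, conventional HDs only).
#' @export
make_community <- function(n_taxa = 20,
                           guild_mix = c(CHEMOLITHOAUTOTROPH = 0.15,
                                         CONVENTIONAL_HD = 0.25,
                                         FSOHD_COMPLETE = 0.15,
                                         FSOHD_INCOMPLETE = 0.10,
                                         DNRA_HETEROTROPH = 0.10,
                                         SULFATE_REDUCER = 0.10,
                                         INERT = 0.15),
                           seed = 1, gc_range = c(0.35, 0.65),
                           dirichlet_alpha = 2) {
  if (n_taxa < 1) stop("n_taxa must be >= 1")
  if (abs(sum(guild_mix) - 1) > 1e-8) stop("guild mix proportions must sum to 1")
  bad <- setdiff(names(guild_mix), GUILDS)
  if (length(bad)) stop("unknown guild(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  # largest-remainder apportionment of taxa to guilds
  quota <- guild_mix * n_taxa
  counts <- floor(quota)
  rem <- n_taxa - sum(counts)
  if (rem > 0) {
    extra <- order(quota - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  guilds <- rep(names(guild_mix), counts)
  ab <- stats::rgamma(n_taxa, shape = dirichlet_alpha)
  ab <- ab / sum(ab)
  out <- data.frame(
    name = sprintf("taxon_%02d", seq_len(n_taxa)),
    guild = guilds,
    gc = stats::runif(n_taxa, gc_range[1], gc_range[2]),
    abundance = ab,
    growth_yield = 0.05,
    uptake_om = 0.2,
    uptake_sulfide = 0.1,
    sulfide_inhibition_threshold =
      ifelse(guilds == "CONVENTIONAL_HD", 1.25, NA_real_),
    stringsAsFactors = FALSE)
  class(out) <- c("taxon_community", "data.frame")
  out
}

#' Microcosm configuration
#'
#' Defaults are the standard amendment scheme: nitrate 300 uM N, sulfide
#' 50 uM S, sulfate 750 uM S, ammonium 100 uM N, organic carbon 5 mM C.
#' Amendments absent from the treatment key are zeroed. Label purities:
#' 0.985 for 13Ci, 0.99 for 13Co.
#'
#' @param treatment a [treatment_key()].
#' @param nitrate,sulfide,sulfate,ammonium,om_c initial concentrations
#'   (uM atom basis); nitrate/sulfide/om_c apply only when amended.
#' @param t_end incubation length, h.
#' @param dt_out output sampling interval, h.
#' @param dt internal Euler step, h (halved automatically on instability).
#' @param n_reps number of measured replicates.
#' @param noise_chem additive chemistry noise as a fraction of the analyte's
#'   initial concentration (element total for pools starting at 0); 0 = off.
#' @param noise_qpcr lognormal sigma for qPCR copy noise.
#' @param biomass_c0 initial community biomass, uM C.
#' @param seed RNG seed recorded in every output.
#' @return object of class `microcosm_config`.
#' @export
microcosm_config <- function(treatment = treatment_key(TRUE, TRUE, TRUE, TRUE),
                             nitrate = 300, sulfide = 50, sulfate = 750,
                             ammonium = 100, om_c = 5000,
                             t_end = 72, dt_out = 3, dt = 0.25, n_reps = 3,
                             noise_chem = 0.02, noise_qpcr = 0.15,
                             biomass_c0 = 100, seed = 1) {
  conc <- c(NO3 = if (treatment$n_present) nitrate else 0,
            NO2 = 0, N2O = 0, N2 = 0, NH4 = ammonium,
            sulfide = if (treatment$s_present) sulfide else 0,
            S0 = 0, S2O3 = 0, SO3 = 0, SO4 = sulfate,
            OM_C = if (treatment$co_present) om_c else 0)
  if (any(conc < 0)) stop("concentrations must be >= 0")
  if (dt <= 0 || dt_out <= 0 || t_end <= 0) stop("time settings must be > 0")
  structure(list(treatment = treatment, initial = conc,
                 t_end = t_end, dt_out = dt_out, dt = dt, n_reps = n_reps,
                 noise_chem = noise_chem, noise_qpcr = noise_qpcr,
                 biomass_c0 = biomass_c0,
                 label_purity = c("13Ci" = 0.985, "13Co" = 0.99),
                 seed = seed),
            class = "microcosm_config")
}

# One taxon's desired transactions for a step, before pool capping.
# Returns a list of processes; each process: pool deltas (uM), electrons,
# acceptor-side electrons (recomputed from acceptor stoichiometry), and
# carbon assimilation (amount + source).
guild_processes <- function(taxon, biomass, pools, treatment, dt) {
  pr <- list()
  add <- function(deltas, e_donor, e_acceptor, assim_c = 0, assim_src = NA,
                  donor = "om") {
    pr[[length(pr) + 1L]] <<- list(deltas = deltas, e_donor = e_donor,
                                   e_acceptor = e_acceptor,
                                   assim_c = assim_c, assim_src = assim_src,
                                   donor = donor)
  }
  om_process <- function(acceptor = c("N2", "N2O", "NH4")) {
    acceptor <- match.arg(acceptor)
    c_ox <- taxon$uptake_om * biomass * dt
    if (c_ox <= 0 || pools[["OM_C"]] <= 0 || pools[["NO3"]] <= 0) return()
    e <- 4 * c_ox
    epn <- c(N2 = 5, N2O = 4, NH4 = 8)[[acceptor]]
    n_use <- e / epn
    assim <- taxon$growth_yield * e
    d <- c(OM_C = -(c_ox + assim), NO3 = -n_use)
    d[acceptor] <- n_use
    add(d, e, n_use * epn, assim, "Co")
  }
  sulfide_process <- function(product = c("SO4", "S0"), e_per_s) {
    product <- match.arg(product)
    s_use <- taxon$uptake_sulfide * biomass * dt
    if (s_use <= 0 || pools[["sulfide"]] <= 0 || pools[["NO3"]] <= 0) return()
    e <- e_per_s * s_use
    n_use <- e / 5
    d <- c(sulfide = -s_use, NO3 = -n_use, N2 = n_use)
    d[product] <- s_use
    add(d, e, n_use * 5, donor = "sulfide")
  }
  switch(taxon$guild,
    CHEMOLITHOAUTOTROPH = {
      if (treatment$ci_present) {
        s_use <- taxon$uptake_sulfide * biomass * dt
        if (s_use > 0 && pools[["sulfide"]] > 0 && pools[["NO3"]] > 0) {
          e <- 8 * s_use
          n_use <- e / 5
          add(c(sulfide = -s_use, SO4 = s_use, NO3 = -n_use, N2 = n_use),
              e, n_use * 5, taxon$growth_yield * e, "Ci", donor = "sulfide")
        }
      }
    },
    CONVENTIONAL_HD = {
      inhibited <- pools[["sulfide"]] > taxon$sulfide_inhibition_threshold
      om_process(if (inhibited) "N2O" else "N2")
    },
    FSOHD_COMPLETE = {
      om_process("N2")
      sulfide_process("SO4", 8)
    },
    FSOHD_INCOMPLETE = {
      om_process("N2")
      sulfide_process("S0", 2)
    },
    DNRA_HETEROTROPH = om_process("NH4"),
    SULFATE_REDUCER = {
      c_ox <- taxon$uptake_om * biomass * dt
      if (c_ox > 0 && pools[["OM_C"]] > 0 && pools[["SO4"]] > 0) {
        e <- 4 * c_ox
        s_use <- e / 8
        assim <- taxon$growth_yield * e
        add(c(OM_C = -(c_ox + assim), SO4 = -s_use, sulfide = s_use),
            e, s_use * 8, assim, "Co")
      }
    },
    INERT = NULL)
  pr
}

#' Simulate an isotope-labelled microcosm incubation
#'
#' Explicit-Euler stepping of guild-specific stoichiometric rules (see the
#' module header in the source); pool over-draw is prevented by proportional
#' down-scaling of the demanding processes, with automatic step halving as a
#' second guard. Biomass nitrogen assimilation is off, so dissolved N and S
#' atom totals are conserved and the nitrogen ledger closes on dissolved
#' species alone. Measurement noise is added last; truth is recorded
#' pre-noise.
#'
#' @param community a [make_community()] result.
#' @param config a [microcosm_config()].
#' @return list with `series` (noisy observations: `analyte`, `replicate`,
#'   `time_h`, `concentration`), and `truth` (ground truth: `series`
#'   noise-free, per-`taxa` biomass / labelled carbon / APE, true `nitrogen`
#'   and `sulfur` ledgers, `d_om_c_consumed`, cumulative `electrons_donated`
#'   and `electrons_accepted`, initial and final pools, and the config).
#' @export
simulate_incubation <- function(community, config) {
  set.seed(config$seed)
  pools <- config$initial
  tr <- config$treatment
  biomass <- config$biomass_c0 * community$abundance / sum(community$abundance)
  labeled <- numeric(nrow(community))
  total_c <- biomass  # per-taxon biomass carbon, uM C
  e_donated <- e_accepted <- 0
  e_by_donor <- c(om = 0, sulfide = 0)
  step_closure_gap <- 0

  times_out <- seq(0, config$t_end, by = config$dt_out)
  truth_mat <- matrix(NA_real_, nrow = length(times_out), ncol = length(ANALYTES),
                      dimnames = list(NULL, ANALYTES))
  truth_mat[1, ] <- pools[ANALYTES]
  out_i <- 2L
  t_now <- 0
  purity <- config$label_purity

  advance <- function(dt) {
    # desired processes for every taxon at the current state
    procs <- list()
    for (i in seq_len(nrow(community))) {
      px <- guild_processes(community[i, ], biomass[i], pools, tr, dt)
      for (p in px) { p$taxon <- i; procs[[length(procs) + 1L]] <- p }
    }
    if (!length(procs)) return(TRUE)
    # proportional capping per consumed pool
    demand <- numeric(length(pools)); names(demand) <- names(pools)
    for (p in procs) {
      cons <- -pmin(p$deltas, 0)
      demand[names(cons)] <- demand[names(cons)] + cons
    }
    factor_pool <- ifelse(demand > 0, pmin(1, pools / demand), 1)
    # stage all updates locally; commit only if no pool is overdrawn
    new_pools <- pools
    new_biomass <- biomass; new_total_c <- total_c; new_labeled <- labeled
    d_edon <- d_eacc <- 0; gap <- 0
    d_edonor <- c(om = 0, sulfide = 0)
    for (p in procs) {
      used <- names(p$deltas)[p$deltas < 0]
      sc <- if (length(used)) min(factor_pool[used]) else 1
      if (sc <= 0) next
      new_pools[names(p$deltas)] <- new_pools[names(p$deltas)] + sc * p$deltas
      d_edon <- d_edon + sc * p$e_donor
      d_eacc <- d_eacc + sc * p$e_acceptor
      d_edonor[p$donor] <- d_edonor[p$donor] + sc * p$e_donor
      gap <- max(gap, abs(sc * (p$e_donor - p$e_acceptor)))
      i <- p$taxon
      grow <- sc * p$assim_c
      if (grow > 0) {
        new_biomass[i] <- new_biomass[i] + grow
        new_total_c[i] <- new_total_c[i] + grow
        if (!is.na(p$assim_src)) {
          if (tr$label == "13Ci" && p$assim_src == "Ci") {
            new_labeled[i] <- new_labeled[i] + purity[["13Ci"]] * grow
          } else if (tr$label == "13Co" && p$assim_src == "Co") {
            new_labeled[i] <- new_labeled[i] + purity[["13Co"]] * grow
          }
        }
      }
    }
    if (any(new_pools < -1e-9)) return(FALSE)
    pools <<- pmax(new_pools, 0)
    biomass <<- new_biomass; total_c <<- new_total_c; labeled <<- new_labeled
    e_donated <<- e_donated + d_edon
    e_accepted <<- e_accepted + d_eacc
    e_by_donor <<- e_by_donor + d_edonor
    step_closure_gap <<- max(step_closure_gap, gap)
    TRUE
  }

  while (t_now < config$t_end - 1e-9) {
    dt <- min(config$dt, config$t_end - t_now)
    ok <- advance(dt)
    h <- dt
    while (!ok) {
      h <- h / 2
      if (h < 1e-3) stop("step-size instability below the minimum step")
      ok <- advance(h)
    }
    t_now <- t_now + h
    while (out_i <= length(times_out) && times_out[out_i] <= t_now + 1e-9) {
      truth_mat[out_i, ] <- pools[ANALYTES]
      out_i <- out_i + 1L
    }
  }

  truth_series <- data.frame(
    analyte = rep(ANALYTES, each = length(times_out)),
    replicate = 1L,
    time_h = rep(times_out, times = length(ANALYTES)),
    concentration = as.vector(truth_mat))

  # measurement noise: additive Gaussian, sigma = noise_chem x the analyte's
  # initial concentration, falling back to the element's initial total for
  # pools that start at zero
  init <- config$initial
  elem_tot <- c(N = sum(init[c("NO3", "NO2", "N2O", "N2", "NH4")]),
                S = sum(init[c("sulfide", "S0", "S2O3", "SO3", "SO4")]),
                C = init[["OM_C"]])
  elem_of <- c(NO3 = "N", NO2 = "N", N2O = "N", N2 = "N", NH4 = "N",
               sulfide = "S", S0 = "S", S2O3 = "S", SO3 = "S", SO4 = "S",
               OM_C = "C")
  sigma <- vapply(ANALYTES, function(a) {
    base <- if (init[[a]] > 0) init[[a]] else elem_tot[[elem_of[[a]]]]
    config$noise_chem * base
  }, numeric(1))

  reps <- lapply(seq_len(config$n_reps), function(r) {
    df <- truth_series
    df$replicate <- r
    if (config$noise_chem > 0) {
      df$concentration <- pmax(0, df$concentration +
        stats::rnorm(nrow(df), 0, sigma[df$analyte]))
    }
    df
  })
  series <- do.call(rbind, reps)

  p0 <- config$initial; p1 <- pools
  nl <- nitrogen_ledger(p0[["NO3"]],
                        max(0, p0[["NO3"]] - p1[["NO3"]]),
                        max(0, p1[["NO2"]] - p0[["NO2"]]),
                        max(0, p1[["N2O"]] - p0[["N2O"]]),
                        max(0, p1[["NH4"]] - p0[["NH4"]]))
  sl <- sulfur_ledger(max(0, p0[["sulfide"]] - p1[["sulfide"]]),
                      max(0, p1[["S0"]] - p0[["S0"]]),
                      max(0, p1[["S2O3"]] - p0[["S2O3"]]),
                      max(0, p1[["SO3"]] - p0[["SO3"]]),
                      max(0, p1[["SO4"]] - p0[["SO4"]]))
  taxa <- data.frame(name = community$name, guild = community$guild,
                     gc = community$gc, biomass = biomass,
                     labeled_c = labeled,
                     ape = ifelse(total_c > 0, labeled / total_c, 0))
  list(series = series,
       truth = list(series = truth_series, taxa = taxa,
                    nitrogen = nl, sulfur = sl,
                    d_om_c_consumed = max(0, p0[["OM_C"]] - p1[["OM_C"]]),
                    electrons_donated = e_donated,
                    electrons_accepted = e_accepted,
                    electrons_by_donor = e_by_donor,
                    d_om_c_oxidized = e_by_donor[["om"]] / 4,
                    max_step_closure_gap = step_closure_gap,
                    pools_initial = p0, pools_final = p1,
                    config = config))
}

#' Simulate an isopycnic CsCl gradient for a labelled community state
#'
#' Each taxon's DNA bands at mean density
#' `rho = gc_intercept + gc_slope * GC + delta_rho_max * APE` with Gaussian
#' band width `band_sd`; fraction boundaries span `density_range` uniformly
#' (tail mass is lumped into the terminal fractions so total copies are
#' conserved). Guild marker genes ride along with the 16S copies. Fraction 1
#' is the densest (bottom-first collection).
#'
#' @param taxa data frame with columns `name`, `guild`, `gc`, `biomass`,
#'   `ape` (e.g. `truth$taxa` from [simulate_incubation()]).
#' @param n_fractions number of fractions (>= 3; default 14).
#' @param density_range gradient span, g/mL.
#' @param gc_intercept,gc_slope,delta_rho_max,band_sd density-model constants.
#' @param copies_per_biomass 16S copies per uM biomass C.
#' @param noise_qpcr lognormal sigma on per-fraction copies (0 = noise-free).
#' @param heavy_threshold g/mL cutoff for the heavy-fraction taxon table.
#' @param sample sample identifier for the profile.
#' @param seed RNG seed.
#' @return list: `profile` (a [fraction_profile()]), `heavy_taxa` (taxon
#'   relative abundances, %, in the pooled heavy fractions), `params`.
#' @export
simulate_gradient <- function(taxa, n_fractions = 14,
                              density_range = c(1.690, 1.760),
                              gc_intercept = 1.660, gc_slope = 0.098,
                              delta_rho_max = 0.036, band_sd = 0.006,
                              copies_per_biomass = 1e4, noise_qpcr = 0.15,
                              heavy_threshold = 1.725, sample = "sim",
                              seed = 1) {
  if (!nrow(taxa)) stop("empty community")
  if (n_fractions < 3) stop("need at least 3 fractions")
  set.seed(seed)
  bounds <- seq(density_range[1], density_range[2], length.out = n_fractions + 1)
  mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
  rho <- gc_intercept + gc_slope * taxa$gc + delta_rho_max * taxa$ape
  # taxon x fraction band mass, tails lumped into terminal fractions
  mass <- t(vapply(seq_len(nrow(taxa)), function(i) {
    cdf <- stats::pnorm(bounds, rho[i], band_sd)
    m <- diff(cdf)
    m[1] <- m[1] + cdf[1]
    m[length(m)] <- m[length(m)] + (1 - cdf[length(cdf)])
    m
  }, numeric(n_fractions)))
  copies16s <- taxa$biomass * copies_per_biomass

  markers <- unique(c("16S", unlist(lapply(taxa$guild, guild_markers))))
  rows <- list()
  for (mk in markers) {
    carry <- if (mk == "16S") rep(TRUE, nrow(taxa)) else
      vapply(taxa$guild, function(g) mk %in% guild_markers(g), logical(1))
    cp <- colSums(mass[carry, , drop = FALSE] * copies16s[carry])
    if (noise_qpcr > 0) {
      cp <- cp * stats::rlnorm(n_fractions, -noise_qpcr^2 / 2, noise_qpcr)
    }
    rows[[mk]] <- data.frame(fraction = rev(seq_len(n_fractions)),
                             density = mids, marker = mk, copies = cp)
  }
  profile <- fraction_profile(do.call(rbind, rows), sample = sample)

  heavy_bins <- mids >= heavy_threshold
  heavy <- as.vector(mass[, heavy_bins, drop = FALSE] %*%
                       rep(1, sum(heavy_bins))) * copies16s
  heavy_taxa <- data.frame(taxon = taxa$name, guild = taxa$guild,
                           rel_abundance_pct = 100 * heavy / sum(heavy))
  list(profile = profile, heavy_taxa = heavy_taxa,
       params = list(n_fractions = n_fractions, density_range = density_range,
                     gc_intercept = gc_intercept, gc_slope = gc_slope,
                     delta_rho_max = delta_rho_max, band_sd = band_sd,
                     heavy_threshold = heavy_threshold, seed = seed))
}

# Does this guild assimilate the treatment's 13C label into heavy DNA, and
# does sulfide give it an extra growth boost there?
guild_label_response <- function(guild, key) {
  labelled <- switch(guild,
    CHEMOLITHOAUTOTROPH = key$label == "13Ci" && key$n_present && key$s_present,
    CONVENTIONAL_HD = key$label == "13Co" && key$n_present,
    DNRA_HETEROTROPH = key$label == "13Co" && key$n_present,
    FSOHD_COMPLETE = key$label == "13Co" && key$n_present,
    FSOHD_INCOMPLETE = key$label == "13Co" && key$n_present,
    SULFATE_REDUCER = key$label == "13Co",
    INERT = FALSE)
  sbonus <- labelled && key$s_present &&
    guild %in% c("FSOHD_COMPLETE", "FSOHD_INCOMPLETE")
  (labelled + sbonus)  # 0, 1 or 2 effect units
}

#' Simulate heavy-fraction relative abundances over the treatment matrix
#'
#' Direct generator of the heavy-fraction taxon table across the
#' amendment-by-label treatment matrix with known ground truth: every taxon
#' carries a background share (the unlabelled high-GC tail that reaches the
#' heavy fractions regardless of labelling); a taxon that assimilates the
#' treatment's 13C source is enriched `label_fold`-fold per responding
#' condition (isotope-labelled growers dominate the heavy DNA severalfold,
#' so enrichment is multiplicative on abundance), with `effect_pp` percentage
#' points as an absolute floor so rare responders remain visible; facultative
#' sulfide-oxidizing heterotrophs respond a second unit when sulfide is
#' supplied. Lognormal replicate noise is applied last. Listed taxa
#' deliberately sum to less than 100% (rare taxa are untabulated, as in real
#' heavy-fraction community tables).
#'
#' @param community a [make_community()] result.
#' @param effect_pp minimum between-treatment effect per responding
#'   condition, percentage points.
#' @param label_fold multiplicative heavy-fraction enrichment per responding
#'   condition.
#' @param n_reps replicates per treatment.
#' @param noise_sd lognormal sigma of replicate noise.
#' @param background_total total background share (%) spread over the taxa.
#' @param treatments treatment code strings to generate.
#' @param seed RNG seed.
#' @return list: `table` (heavy abundance table: `taxon`, `treatment`,
#'   `replicate`, `rel_abundance_pct`), `truth` (taxon, guild, expected
#'   flags from [guild_truth_flags()]).
#' @export
simulate_heavy_abundance <- function(community, effect_pp = 2, label_fold = 2.5,
                                     n_reps = 3,
                                     noise_sd = 0.15, background_total = 25,
                                     treatments = c("12Ci+12Co+N+S",
                                                    "13Ci+12Co+N+S",
                                                    "12Ci+13Co+N+S",
                                                    "12Ci+12Co+N",
                                                    "12Ci+13Co+N",
                                                    "13Ci+12Co+N",
                                                    "13Ci+N+S", "12Ci+N+S",
                                                    "13Ci", "12Ci"),
                                     seed = 1) {
  set.seed(seed)
  base <- background_total * community$abundance / sum(community$abundance)
  rows <- list()
  for (code in treatments) {
    key <- parse_treatment_code(code)
    boost <- vapply(community$guild, guild_label_response, numeric(1), key = key)
    mu <- pmax(base * label_fold^boost, base + effect_pp * boost)
    for (r in seq_len(n_reps)) {
      obs <- mu * stats::rlnorm(length(mu), -noise_sd^2 / 2, noise_sd)
      # tabulated taxa can never exceed the whole community
      if (sum(obs) > 99) obs <- obs * 99 / sum(obs)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = community$name, treatment = code, replicate = r,
        rel_abundance_pct = obs)
    }
  }
  truth <- data.frame(taxon = community$name, guild = community$guild,
                      expected_flags = vapply(community$guild, function(g) {
                        paste(guild_truth_flags()[[g]], collapse = ";")
                      }, character(1)))
  list(table = do.call(rbind, rows), truth = truth)
}

#' Named microcosm and culture scenario presets
#'
#' The five SIP sediment microcosms (`+C+N+S`, `+C+N`, `+Ci+N+S`, `+Ci`,
#' `+Co`), the seven laboratory cultures (HD: conventional heterotrophic
#' denitrifier enrichment; CD: chemolithoautotrophic sulfur-oxidizing
#' denitrifier; ENR_U2 / ENR_C4: enrichments dominated by facultative
#' sulfide-oxidizing heterotrophic denitrifiers with incomplete / complete
#' sulfur oxidation; CE_H / CE_E / CE_L: HD:CD mixtures at 3:1, 1:1, 1:3)
#' in OM-rich (C/N = 3.52) and OM-limited (C/N = 0.70) variants, plus the
#' generic `OM_rich` / `OM_limited` medium configs.
#'
#' @param label optional isotope label applied to the SIP microcosm presets.
#' @param seed seed stored in each config.
#' @return named list; each entry has `config` (a [microcosm_config()]) and
#'   `community_mix` (guild proportions, or NULL for the sediment community).
#' @export
scenario_presets <- function(label = "12C", seed = 1) {
  sip <- function(ci, co, n, s) {
    lb <- label
    if (lb == "13Ci" && !ci) lb <- "12C"
    if (lb == "13Co" && !co) lb <- "12C"
    list(config = microcosm_config(treatment_key(ci, co, n, s, lb), seed = seed),
         community_mix = NULL)
  }
  cn_om <- function(cn) cn * 300  # uM C for the given C/N over 300 uM N
  culture <- function(mix, co = TRUE, s = TRUE, om_cn = 3.52) {
    list(config = microcosm_config(
           treatment_key(TRUE, co, TRUE, s, "12C"),
           om_c = cn_om(om_cn), seed = seed),
         community_mix = mix)
  }
  cultures <- list(
    HD = list(mix = c(CONVENTIONAL_HD = 1), co = TRUE),
    CD = list(mix = c(CHEMOLITHOAUTOTROPH = 1), co = FALSE),
    ENR_U2 = list(mix = c(FSOHD_INCOMPLETE = 1), co = TRUE),
    ENR_C4 = list(mix = c(FSOHD_COMPLETE = 1), co = TRUE),
    CE_H = list(mix = c(CONVENTIONAL_HD = 0.75, CHEMOLITHOAUTOTROPH = 0.25),
                co = TRUE),
    CE_E = list(mix = c(CONVENTIONAL_HD = 0.5, CHEMOLITHOAUTOTROPH = 0.5),
                co = TRUE),
    CE_L = list(mix = c(CONVENTIONAL_HD = 0.25, CHEMOLITHOAUTOTROPH = 0.75),
                co = TRUE))
  out <- list(
    "+C+N+S" = sip(TRUE, TRUE, TRUE, TRUE),
    "+C+N" = sip(TRUE, TRUE, TRUE, FALSE),
    "+Ci+N+S" = sip(TRUE, FALSE, TRUE, TRUE),
    "+Ci" = sip(TRUE, FALSE, FALSE, FALSE),
    "+Co" = sip(FALSE, TRUE, FALSE, FALSE))
  for (nm in names(cultures)) {
    cu <- cultures[[nm]]
    out[[paste0(nm, "_rich")]] <- culture(cu$mix, cu$co, TRUE, 3.52)
    out[[paste0(nm, "_limited")]] <- culture(cu$mix, cu$co, TRUE, 0.70)
  }
  out$OM_rich <- culture(NULL, TRUE, TRUE, 3.52)
  out$OM_limited <- culture(NULL, TRUE, TRUE, 0.70)
  out
}
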