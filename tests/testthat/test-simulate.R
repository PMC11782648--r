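pool_totals <- function(pools) {
  c(N = sum(pools[c("NO3", "NO2", "N2O", "N2", "NH4")]),
    S = sum(pools[c("sulfide", "S0", "S2O3", "SO3", "SO4")]))
}

test_that("make_community apportions guilds and normalizes abundances", {
  cm <- make_community(n_taxa = 20, seed = 3)
  expect_equal(nrow(cm), 20)
  expect_equal(sum(cm$abundance), 1)
  counts <- table(cm$guild)
  # largest-remainder: 20 taxa at the default mix gives exact integer quotas
  expect_equal(unname(counts[["CONVENTIONAL_HD"]]), 5)
  expect_equal(unname(counts[["FSOHD_COMPLETE"]]), 3)
  expect_equal(unname(counts[["FSOHD_INCOMPLETE"]]), 2)
  expect_equal(unname(counts[["INERT"]]), 3)
  expect_true(all(cm$gc >= 0.35 & cm$gc <= 0.65))
  # only conventional HDs carry the NosZ sulfide-inhibition threshold
  expect_true(all(is.na(cm$sulfide_inhibition_threshold) !=
                    (cm$guild == "CONVENTIONAL_HD")))
  expect_equal(cm$sulfide_inhibition_threshold[cm$guild == "CONVENTIONAL_HD"][1],
               1.25)
  # determinism
  expect_identical(make_community(seed = 3), cm)
  expect_false(identical(make_community(seed = 4)$abundance, cm$abundance))
  expect_error(make_community(guild_mix = c(INERT = 0.5)), "sum to 1")
  expect_error(make_community(guild_mix = c(XX = 1)), "unknown guild")
})

test_that("microcosm_config zeroes amendments absent from the treatment", {
  full <- microcosm_config(treatment_key(TRUE, TRUE, TRUE, TRUE))
  expect_equal(unname(full$initial[c("NO3", "sulfide", "OM_C", "NH4", "SO4")]),
               c(300, 50, 5000, 100, 750))
  bare <- microcosm_config(treatment_key(TRUE, FALSE, FALSE, FALSE))
  expect_equal(unname(bare$initial[c("NO3", "sulfide", "OM_C")]), c(0, 0, 0))
  expect_equal(unname(bare$initial[["SO4"]]), 750)  # porewater background stays
  expect_error(microcosm_config(nitrate = -1), ">= 0")
  expect_error(microcosm_config(dt = 0), "> 0")
})

test_that("incubations conserve N and S atoms and close the electron ledger", {
  for (nm in c("+C+N+S", "ENR_C4_rich", "CE_E_limited")) {
    sc <- scenario_presets()[[nm]]
    cm <- if (is.null(sc$community_mix)) make_community(seed = 5) else
      make_community(10, guild_mix = sc$community_mix, seed = 5)
    cfg <- sc$config; cfg$noise_chem <- 0
    sim <- simulate_incubation(cm, cfg)
    t0 <- pool_totals(sim$truth$pools_initial)
    t1 <- pool_totals(sim$truth$pools_final)
    expect_equal(t1[["N"]], t0[["N"]], tolerance = 1e-9, info = nm)
    expect_equal(t1[["S"]], t0[["S"]], tolerance = 1e-9, info = nm)
    expect_equal(sim$truth$electrons_donated, sim$truth$electrons_accepted,
                 tolerance = 1e-9, info = nm)
    expect_lt(sim$truth$max_step_closure_gap, 1e-9)
    # something actually happened
    expect_gt(sim$truth$electrons_donated, 0)
  }
})

test_that("truth ledgers equal a direct net_changes analysis of the noise-free series", {
  cm <- make_community(seed = 7)
  cfg <- microcosm_config(noise_chem = 0, seed = 7)
  sim <- simulate_incubation(cm, cfg)
  nc <- net_changes(sim$truth$series, 0, cfg$t_end)
  expect_equal(nc$nitrogen$d_no3_consumed, sim$truth$nitrogen$d_no3_consumed,
               tolerance = 1e-9)
  expect_equal(nc$sulfur$d_sulfide_consumed, sim$truth$sulfur$d_sulfide_consumed,
               tolerance = 1e-9)
  expect_equal(nc$d_om_c_consumed, sim$truth$d_om_c_consumed, tolerance = 1e-9)
  # noise off means observed replicates coincide with the truth
  expect_equal(
    sim$series$concentration[sim$series$replicate == 1],
    sim$truth$series$concentration)
})

test_that("donor electron shares reconstruct the balance statistics exactly", {
  # single-guild FSOHD culture: all electrons come from OM + sulfide and all
  # go to complete denitrification, so N'_com = P^S_den + P^OM_den exactly
  cm <- make_community(5, guild_mix = c(FSOHD_COMPLETE = 1), seed = 9)
  cfg <- microcosm_config(noise_chem = 0, seed = 9)
  sim <- simulate_incubation(cm, cfg)
  tr <- sim$truth
  ncom <- completion_extent(tr$nitrogen)
  ps <- sulfide_electron_share(tr$sulfur, tr$nitrogen$c_no3_initial)
  pom <- om_electron_share(tr$d_om_c_oxidized, tr$nitrogen$c_no3_initial)
  expect_equal(ps + pom, ncom, tolerance = 1e-9)
  expect_equal(ps, tr$electrons_by_donor[["sulfide"]] /
                 (tr$nitrogen$c_no3_initial * 5), tolerance = 1e-12)
  # complete oxidizer sends every consumed sulfide S to sulfate
  expect_equal(tr$sulfur$d_so4_produced, tr$sulfur$d_sulfide_consumed,
               tolerance = 1e-9)
  expect_equal(tr$sulfur$d_s0_produced, 0)
})

test_that("incomplete sulfur oxidizers stop at zero-valent sulfur", {
  cm <- make_community(5, guild_mix = c(FSOHD_INCOMPLETE = 1), seed = 9)
  sim <- simulate_incubation(cm, microcosm_config(noise_chem = 0, seed = 9))
  expect_equal(sim$truth$sulfur$d_s0_produced,
               sim$truth$sulfur$d_sulfide_consumed, tolerance = 1e-9)
  expect_equal(sim$truth$sulfur$d_so4_produced, 0)
})

test_that("sulfide above the NosZ threshold truncates conventional HDs at N2O", {
  cm <- make_community(5, guild_mix = c(CONVENTIONAL_HD = 1), seed = 2)
  base <- microcosm_config(treatment_key(TRUE, TRUE, TRUE, FALSE),
                           noise_chem = 0, seed = 2)
  with_s <- microcosm_config(treatment_key(TRUE, TRUE, TRUE, TRUE),
                             sulfide = 4.83, noise_chem = 0, seed = 2)
  sim0 <- simulate_incubation(cm, base)
  sim1 <- simulate_incubation(cm, with_s)
  # no sulfide: complete denitrification to N2, no N2O
  expect_equal(sim0$truth$nitrogen$d_n2o_produced, 0)
  expect_gt(sim0$truth$pools_final[["N2"]] - sim0$truth$pools_initial[["N2"]], 0)
  # 4.83 uM sulfide (> 1.25 threshold, HDs cannot remove it): all N2O
  expect_gt(sim1$truth$nitrogen$d_n2o_produced, 0)
  expect_equal(sim1$truth$pools_final[["N2"]], sim1$truth$pools_initial[["N2"]])
  expect_gt(n2o_emission_fraction(sim1$truth$nitrogen),
            n2o_emission_fraction(sim0$truth$nitrogen))
  # F-SOHDs remove the sulfide themselves and are not inhibited
  cmf <- make_community(5, guild_mix = c(FSOHD_COMPLETE = 1), seed = 2)
  simf <- simulate_incubation(cmf, with_s)
  expect_equal(simf$truth$nitrogen$d_n2o_produced, 0)
})

test_that("DNRA heterotrophs send nitrate to ammonium at 8 e- per N", {
  cm <- make_community(5, guild_mix = c(DNRA_HETEROTROPH = 1), seed = 2)
  sim <- simulate_incubation(cm, microcosm_config(noise_chem = 0, seed = 2))
  nl <- sim$truth$nitrogen
  expect_equal(nl$d_nh4_produced, nl$d_no3_consumed, tolerance = 1e-9)
  expect_equal(sim$truth$electrons_donated, nl$d_nh4_produced * 8,
               tolerance = 1e-6)
})

test_that("isotope labels land only in guilds that assimilate the labelled source", {
  cfg13co <- microcosm_config(treatment_key(TRUE, TRUE, TRUE, TRUE, "13Co"),
                              noise_chem = 0, seed = 6)
  cm <- make_community(seed = 6)
  sim <- simulate_incubation(cm, cfg13co)
  tx <- sim$truth$taxa
  het <- tx$guild %in% c("CONVENTIONAL_HD", "FSOHD_COMPLETE",
                         "FSOHD_INCOMPLETE", "DNRA_HETEROTROPH",
                         "SULFATE_REDUCER")
  expect_true(all(tx$ape[het] > 0))
  expect_true(all(tx$ape[!het] == 0))  # autotrophs + inert untouched by 13Co
  expect_true(all(tx$ape <= 0.99 + 1e-12))  # bounded by label purity

  cfg13ci <- microcosm_config(treatment_key(TRUE, TRUE, TRUE, TRUE, "13Ci"),
                              noise_chem = 0, seed = 6)
  sim2 <- simulate_incubation(cm, cfg13ci)
  tx2 <- sim2$truth$taxa
  expect_true(all(tx2$ape[tx2$guild == "CHEMOLITHOAUTOTROPH"] > 0))
  expect_true(all(tx2$ape[tx2$guild != "CHEMOLITHOAUTOTROPH"] == 0))
})

test_that("simulated incubations are seed-deterministic", {
  cm <- make_community(seed = 8)
  cfg <- microcosm_config(seed = 8)
  s1 <- simulate_incubation(cm, cfg)
  s2 <- simulate_incubation(cm, cfg)
  expect_identical(s1$series, s2$series)
  cfg2 <- microcosm_config(seed = 9)
  s3 <- simulate_incubation(cm, cfg2)
  expect_false(identical(s1$series$concentration, s3$series$concentration))
})

test_that("simulated gradients conserve copies and shift with APE", {
  taxa <- data.frame(name = "t1", guild = "FSOHD_COMPLETE", gc = 0.5,
                     biomass = 100, ape = 0)
  profiles <- lapply(c(0, 0.25, 0.5, 0.99), function(a) {
    taxa$ape <- a
    simulate_gradient(taxa, noise_qpcr = 0, seed = 1)$profile
  })
  unl <- profiles[[1]]
  # copy conservation: tail lumping keeps the full 16S copy count in-gradient
  tot <- sum(unl$fractions$copies[unl$fractions$marker == "16S"])
  expect_equal(tot, 100 * 1e4, tolerance = 1e-6)
  shifts <- vapply(profiles, labeling_shift, numeric(1),
                   unlabeled = unl, marker = "16S")
  expect_equal(shifts[1], 0)
  expect_true(all(diff(shifts) > 0))
  # weighted-mean shift tracks delta_rho_max * APE to within a fraction width
  expect_true(all(abs(shifts - 0.036 * c(0, 0.25, 0.5, 0.99)) <= 0.005))
  # fraction 1 is the densest
  f16 <- unl$fractions[unl$fractions$marker == "16S", ]
  expect_equal(f16$density[f16$fraction == 1], max(f16$density))
})

test_that("marker genes ride along with their guilds only", {
  taxa <- data.frame(name = c("a", "cd"), guild = c("FSOHD_COMPLETE",
                                                    "CHEMOLITHOAUTOTROPH"),
                     gc = c(0.45, 0.60), biomass = c(50, 50), ape = c(0.5, 0))
  g <- simulate_gradient(taxa, noise_qpcr = 0, seed = 1)
  fr <- g$profile$fractions
  expect_true(all(c("16S", "sqr", "nirS", "nosZ", "soxB", "napA") %in% fr$marker))
  # nirS comes only from the labelled FSOHD taxon, so its weighted density
  # exceeds soxB's (unlabelled autotroph, despite higher GC by only 0.015 rho)
  wmean <- function(mk) {
    s <- fr[fr$marker == mk, ]; stats::weighted.mean(s$density, s$copies)
  }
  expect_gt(wmean("nirS"), wmean("soxB"))
  expect_equal(sum(fr$copies[fr$marker == "nosZ"]), 50 * 1e4, tolerance = 1e-6)
})

test_that("heavy-abundance generator: ground truth, determinism, validity", {
  cm <- make_community(seed = 10)
  ha <- simulate_heavy_abundance(cm, seed = 10)
  expect_invisible(validate_heavy_table(ha$table))
  expect_identical(ha$table, simulate_heavy_abundance(cm, seed = 10)$table)
  expect_equal(sort(unique(ha$table$taxon)), sort(cm$name))
  expect_equal(nrow(ha$truth), nrow(cm))
  # expected flags reproduce the guild truth map
  fs <- ha$truth$expected_flags[ha$truth$guild == "FSOHD_COMPLETE"][1]
  expect_identical(fs, paste(guild_truth_flags()$FSOHD_COMPLETE, collapse = ";"))
  # noise-free means: responding guilds enriched in their responding condition
  ha0 <- simulate_heavy_abundance(cm, noise_sd = 0, seed = 10)
  t13 <- ha0$table[ha0$table$treatment == "12Ci+13Co+N+S" &
                     ha0$table$replicate == 1, ]
  t12 <- ha0$table[ha0$table$treatment == "12Ci+12Co+N+S" &
                     ha0$table$replicate == 1, ]
  fsohd_taxa <- cm$name[cm$guild == "FSOHD_COMPLETE"]
  inert_taxa <- cm$name[cm$guild == "INERT"]
  for (tx in fsohd_taxa) {
    expect_gt(t13$rel_abundance_pct[t13$taxon == tx],
              t12$rel_abundance_pct[t12$taxon == tx])
  }
  for (tx in inert_taxa) {
    expect_equal(t13$rel_abundance_pct[t13$taxon == tx],
                 t12$rel_abundance_pct[t12$taxon == tx])
  }
})

test_that("end-to-end: classification of a simulated community recovers guilds", {
  cm <- make_community(seed = 20)
  ha <- simulate_heavy_abundance(cm, seed = 20)
  calls <- classify_community(ha$table)
  tb <- calls_table(calls)
  truth_map <- guild_truth_flags()
  flags <- setdiff(names(tb), "taxon")
  hits <- 0; total <- 0
  for (i in seq_len(nrow(cm))) {
    expected <- truth_map[[cm$guild[i]]]
    got <- tb[tb$taxon == cm$name[i], flags]
    for (fl in flags) {
      total <- total + 1
      ok <- isTRUE(got[[fl]]) == (fl %in% expected)
      hits <- hits + ok
    }
  }
  expect_gt(hits / total, 0.9)
})

test_that("scenario presets encode the study design", {
  pr <- scenario_presets()
  expect_true(all(c("+C+N+S", "+C+N", "+Ci+N+S", "+Ci", "+Co",
                    "HD_rich", "HD_limited", "CD_rich", "ENR_U2_rich",
                    "ENR_C4_limited", "CE_H_rich", "CE_E_rich", "CE_L_limited",
                    "OM_rich", "OM_limited") %in% names(pr)))
  # OM-rich C/N = 3.52, OM-limited 0.70, over 300 uM N
  expect_equal(unname(pr$OM_rich$config$initial[["OM_C"]]), 3.52 * 300)
  expect_equal(unname(pr$OM_limited$config$initial[["OM_C"]]), 0.70 * 300)
  # sulfide present only in +S treatments
  expect_equal(unname(pr[["+C+N"]]$config$initial[["sulfide"]]), 0)
  expect_gt(unname(pr[["+C+N+S"]]$config$initial[["sulfide"]]), 0)
  # CD culture has no organic carbon
  expect_equal(unname(pr$CD_rich$config$initial[["OM_C"]]), 0)
  # mixtures sum to 1
  expect_equal(sum(pr$CE_H_rich$community_mix), 1)
  # a 13Ci label is dropped for microcosms without inorganic carbon
  pr13 <- scenario_presets(label = "13Ci")
  expect_identical(pr13[["+Co"]]$config$treatment$label, "12C")
  expect_identical(pr13[["+Ci+N+S"]]$config$treatment$label, "13Ci")
})
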