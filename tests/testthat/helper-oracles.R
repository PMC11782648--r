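# Independent oracles kept deliberately separate from the package's own code
# paths: oxidation states are looked up from a hand-written table, and the
# balance statistics are rebuilt species-by-species from electron counts
# rather than via the packaged closed forms.

# hand-tabulated oxidation states of the ledger species' key atoms
ORACLE_N_STATE <- c(NO3 = 5, NO2 = 3, N2O = 1, N2 = 0, NH4 = -3)
ORACLE_S_STATE <- c(sulfide = -2, S0 = 0, S2O3 = 2, SO3 = 4, SO4 = 6)

# completion extent, rebuilt as: electrons actually consumed per N product
# (5 - product N state), with the N2 pool inferred by difference
oracle_completion_extent <- function(ci, d_no3, d_no2, d_n2o, d_nh4) {
  d_n2 <- d_no3 - d_no2 - d_n2o - d_nh4
  prods <- c(NO2 = d_no2, N2O = d_n2o, N2 = d_n2, NH4 = d_nh4)
  e <- sum(prods * (ORACLE_N_STATE[["NO3"]] - ORACLE_N_STATE[names(prods)]))
  e / (ci * (ORACLE_N_STATE[["NO3"]] - ORACLE_N_STATE[["N2"]]))
}

# sulfide electron share, rebuilt as electrons released per S product
# (product state minus sulfide's -2)
oracle_sulfide_share <- function(ci, d_s0, d_s2o3, d_so3, d_so4) {
  prods <- c(S0 = d_s0, S2O3 = d_s2o3, SO3 = d_so3, SO4 = d_so4)
  e <- sum(prods * (ORACLE_S_STATE[names(prods)] - ORACLE_S_STATE[["sulfide"]]))
  e / (ci * 5)
}

# a random nitrogen ledger satisfying every stated ledger invariant:
# fields >= 0, dNO2 + dN2O + dNH4 <= dNO3 <= c_no3_initial
random_valid_ledger <- function() {
  ci <- stats::runif(1, 50, 500)
  d_no3 <- stats::runif(1, 0, ci)
  w <- stats::rgamma(4, shape = 1)
  parts <- d_no3 * w / sum(w)  # NO2, N2O, NH4, remainder-to-N2
  nitrogen_ledger(ci, d_no3, parts[1], parts[2], parts[3])
}

# mean oxidation state from composition + charge, recoded locally
oracle_ox_state <- function(comp, charge, element) {
  fixed <- c(H = 1, O = -2)
  others <- setdiff(names(comp), element)
  (charge - sum(fixed[others] * comp[others])) / comp[[element]]
}

# two-point time series builder for net_changes tests
two_point_series <- function(analyte, c0, c1, t0 = 0, t1 = 63, replicate = 1) {
  data.frame(analyte = analyte, replicate = replicate,
             time_h = c(t0, t1), concentration = c(c0, c1))
}
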