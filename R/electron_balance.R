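# Stoichiometric electron-flow statistics for anoxic incubations.
#
# All nitrogen and sulfur concentrations are on an ATOM basis (uM of N or S
# atoms): a molecule-basis N2O or thiosulfate measurement must be multiplied
# by its atom multiplicity before it enters a ledger. The reader in R/io.R
# performs that conversion from an explicit unit_basis column.

#' Per-atom electron coefficients used by the balance statistics
#'
#' Electrons consumed per N atom reduced from nitrate to each terminal
#' product, and released per S atom oxidized from sulfide to each product.
#' @return list with `nitrogen` and `sulfur` named numeric vectors.
#' @export
electron_coefficients <- function() {
  list(
    nitrogen = c(NO2 = 2, N2O = 4, N2 = 5, NH4 = 8),
    sulfur   = c(S0 = 2, S2O3 = 4, SO3 = 6, SO4 = 8)
  )
}

#' Nitrogen net-change ledger
#'
#' Net changes over an incubation window, uM of N atoms: initial nitrate,
#' nitrate consumed, and nitrite / nitrous oxide / ammonium produced.
#' Violations of the nesting constraint
#' `dNO2 + dN2O + dNH4 <= dNO3 <= c_no3_initial` are flagged, never altered.
#'
#' @param c_no3_initial initial nitrate, uM N.
#' @param d_no3_consumed,d_no2_produced,d_n2o_produced,d_nh4_produced net
#'   changes, uM N, all >= 0.
#' @return object of class `nitrogen_ledger` (list incl. `flags`).
#' @export
nitrogen_ledger <- function(c_no3_initial, d_no3_consumed, d_no2_produced = 0,
                            d_n2o_produced = 0, d_nh4_produced = 0) {
  vals <- c(c_no3_initial, d_no3_consumed, d_no2_produced,
            d_n2o_produced, d_nh4_produced)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("nitrogen ledger fields must be finite and >= 0")
  }
  flags <- character(0)
  tol <- 1e-9 * max(1, c_no3_initial)
  if (d_no2_produced + d_n2o_produced + d_nh4_produced > d_no3_consumed + tol) {
    flags <- c(flags, "products_exceed_no3_consumed")
  }
  if (d_no3_consumed > c_no3_initial + tol) {
    flags <- c(flags, "no3_consumed_exceeds_initial")
  }
  structure(list(c_no3_initial = c_no3_initial, d_no3_consumed = d_no3_consumed,
                 d_no2_produced = d_no2_produced, d_n2o_produced = d_n2o_produced,
                 d_nh4_produced = d_nh4_produced, flags = flags),
            class = "nitrogen_ledger")
}

#' Sulfur net-change ledger
#'
#' Net changes over an incubation window, uM of S atoms. An apparent S mass
#' imbalance (products exceeding sulfide consumed) is flagged, not corrected.
#'
#' @param d_sulfide_consumed sulfide consumed, uM S.
#' @param d_s0_produced,d_s2o3_produced,d_so3_produced,d_so4_produced net
#'   production of zero-valent sulfur, thiosulfate (atom basis), sulfite and
#'   sulfate, uM S.
#' @param tol_frac tolerance fraction for the mass-balance flag.
#' @return object of class `sulfur_ledger`.
#' @export
sulfur_ledger <- function(d_sulfide_consumed, d_s0_produced = 0,
                          d_s2o3_produced = 0, d_so3_produced = 0,
                          d_so4_produced = 0, tol_frac = 0.05) {
  vals <- c(d_sulfide_consumed, d_s0_produced, d_s2o3_produced,
            d_so3_produced, d_so4_produced)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("sulfur ledger fields must be finite and >= 0")
  }
  flags <- character(0)
  prod <- d_s0_produced + d_s2o3_produced + d_so3_produced + d_so4_produced
  if (prod > d_sulfide_consumed * (1 + tol_frac) + 1e-9) {
    flags <- c(flags, "s_products_exceed_sulfide_consumed")
  }
  structure(list(d_sulfide_consumed = d_sulfide_consumed,
                 d_s0_produced = d_s0_produced, d_s2o3_produced = d_s2o3_produced,
                 d_so3_produced = d_so3_produced, d_so4_produced = d_so4_produced,
                 flags = flags),
            class = "sulfur_ledger")
}

#' Completion extent of denitrification
#'
#' Electron-weighted fraction of the theoretical electron demand for full
#' nitrate-to-dinitrogen reduction actually realized:
#' \deqn{N'_{com} = \frac{(\Delta NO_3 - \Delta NO_2 - \Delta N_2O - \Delta NH_4)
#'   \times 5 + \Delta NO_2 \times 2 + \Delta N_2O \times 4 + \Delta NH_4
#'   \times 8}{C^i_{NO_3} \times 5}}
#' All terms are uM N atoms. Because dissimilatory nitrate reduction to
#' ammonium consumes 8 e-/N (more than the 5 e-/N of complete
#' denitrification), the value can exceed 1 when DNRA dominates; values are
#' reported raw (callers flag overrange via [balance_result()]).
#'
#' @param ledger a [nitrogen_ledger()].
#' @return dimensionless fraction.
#' @export
completion_extent <- function(ledger) {
  if (ledger$c_no3_initial <= 0) stop("c_no3_initial must be > 0")
  with(ledger,
       ((d_no3_consumed - d_no2_produced - d_n2o_produced - d_nh4_produced) * 5 +
          d_no2_produced * 2 + d_n2o_produced * 4 + d_nh4_produced * 8) /
         (c_no3_initial * 5))
}

#' Proportion of denitrification electrons contributed by sulfide
#'
#' \deqn{P^S_{den} = \frac{\Delta S^0 \times 2 + \Delta S_2O_3^{2-} \times 4 +
#'   \Delta SO_3^{2-} \times 6 + \Delta SO_4^{2-} \times 8}{C^i_{NO_3} \times 5}}
#' with every sulfur term the net amount produced on an S-atom basis.
#'
#' @param s_ledger a [sulfur_ledger()].
#' @param c_no3_initial initial nitrate, uM N.
#' @return dimensionless fraction.
#' @export
sulfide_electron_share <- function(s_ledger, c_no3_initial) {
  if (c_no3_initial <= 0) stop("c_no3_initial must be > 0")
  with(s_ledger,
       (d_s0_produced * 2 + d_s2o3_produced * 4 + d_so3_produced * 6 +
          d_so4_produced * 8) / (c_no3_initial * 5))
}

#' Proportion of denitrification electrons contributed by organic matter
#'
#' `generic4` mode uses the field convention of 4 e- per OM carbon oxidized to
#' CO2; `per_compound` mode weights by each compound's own electron content
#' (see [om_electron_content()]).
#'
#' @param d_om_c_consumed organic carbon consumed, uM C (for `per_compound`,
#'   a named vector of uM C per compound, names resolvable in `lib`).
#' @param c_no3_initial initial nitrate, uM N.
#' @param mode `"generic4"` or `"per_compound"`.
#' @param lib species library for `per_compound` lookups.
#' @return dimensionless fraction.
#' @export
om_electron_share <- function(d_om_c_consumed, c_no3_initial,
                              mode = c("generic4", "per_compound"),
                              lib = species_library()) {
  mode <- match.arg(mode)
  if (c_no3_initial <= 0) stop("c_no3_initial must be > 0")
  if (any(d_om_c_consumed < 0)) stop("d_om_c_consumed must be >= 0")
  electrons <- if (mode == "generic4") {
    sum(d_om_c_consumed) * 4
  } else {
    if (is.null(names(d_om_c_consumed))) {
      stop("per_compound mode needs a named vector of uM C per compound")
    }
    sum(vapply(seq_along(d_om_c_consumed), function(i) {
      d_om_c_consumed[i] *
        om_electron_content(names(d_om_c_consumed)[i], "per_compound", lib)
    }, numeric(1)))
  }
  electrons / (c_no3_initial * 5)
}

#' N2O emission as a percentage of initial nitrate nitrogen
#'
#' @param ledger a [nitrogen_ledger()].
#' @return percentage, `100 * dN2O / c_no3_initial` (N-atom basis).
#' @export
n2o_emission_fraction <- function(ledger) {
  if (ledger$c_no3_initial <= 0) stop("c_no3_initial must be > 0")
  100 * ledger$d_n2o_produced / ledger$c_no3_initial
}

#' Aggregate balance statistics with data-quality flags
#'
#' @param n_ledger a [nitrogen_ledger()].
#' @param s_ledger a [sulfur_ledger()] (optional).
#' @param d_om_c_consumed OM carbon consumed, uM C (optional).
#' @param om_mode passed to [om_electron_share()].
#' @param lib species library.
#' @return list of class `balance_result`: `n_com`, `p_s_den`, `p_om_den`,
#'   `n2o_pct`, `flags`. Values outside \[0, 1\] are reported raw with an
#'   `"overrange"` flag.
#' @export
balance_result <- function(n_ledger, s_ledger = NULL, d_om_c_consumed = NULL,
                           om_mode = "generic4", lib = species_library()) {
  n_com <- completion_extent(n_ledger)
  p_s <- if (is.null(s_ledger)) NA_real_ else
    sulfide_electron_share(s_ledger, n_ledger$c_no3_initial)
  p_om <- if (is.null(d_om_c_consumed)) NA_real_ else
    om_electron_share(d_om_c_consumed, n_ledger$c_no3_initial, om_mode, lib)
  flags <- c(n_ledger$flags, if (!is.null(s_ledger)) s_ledger$flags)
  vals <- c(n_com = n_com, p_s_den = p_s, p_om_den = p_om)
  over <- names(vals)[!is.na(vals) & (vals < 0 | vals > 1)]
  if (length(over)) flags <- c(flags, paste0("overrange:", over))
  structure(list(n_com = n_com, p_s_den = p_s, p_om_den = p_om,
                 n2o_pct = n2o_emission_fraction(n_ledger),
                 flags = unique(flags)),
            class = "balance_result")
}

#' Net concentration changes over an incubation window
#'
#' Endpoint-difference convention: consumption of donors/acceptors (NO3,
#' sulfide, OM_C) is `max(0, c(t0) - c(t1))`; production of the remaining
#' analytes is `max(0, c(t1) - c(t0))`. Linear interpolation between sampled
#' times; replicates averaged with the SEM retained; negative net changes are
#' clamped to zero and flagged.
#'
#' @param series data frame with columns `analyte`, `replicate`, `time_h`,
#'   `concentration` (uM, atom basis). Analytes from
#'   `NO3, NO2, N2O, N2, NH4, sulfide, S0, S2O3, SO3, SO4, OM_C`.
#' @param t_start,t_end window, h; must be covered by every analyte series.
#' @return list with `nitrogen` ([nitrogen_ledger()]), `sulfur`
#'   ([sulfur_ledger()]), `d_om_c_consumed`, `sem` (named vector), `flags`.
#' @export
net_changes <- function(series, t_start, t_end) {
  need <- c("analyte", "replicate", "time_h", "concentration")
  miss <- setdiff(need, names(series))
  if (length(miss)) stop("series missing columns: ", paste(miss, collapse = ", "))
  if (t_end <= t_start) stop("t_end must exceed t_start")
  consumed <- c("NO3", "sulfide", "OM_C")
  flags <- character(0)

  conc_at <- function(df, t) {
    if (t < min(df$time_h) || t > max(df$time_h)) {
      stop("time ", t, " h outside series range for analyte ", df$analyte[1])
    }
    stats::approx(df$time_h, df$concentration, xout = t, ties = "ordered")$y
  }

  per_rep <- list()
  for (an in unique(series$analyte)) {
    sub <- series[series$analyte == an, ]
    deltas <- vapply(split(sub, sub$replicate), function(df) {
      df <- df[order(df$time_h), ]
      raw <- if (an %in% consumed) conc_at(df, t_start) - conc_at(df, t_end)
             else conc_at(df, t_end) - conc_at(df, t_start)
      raw
    }, numeric(1))
    if (any(deltas < 0)) flags <- c(flags, paste0("negative_net_change:", an))
    per_rep[[an]] <- pmax(0, deltas)
  }
  mn <- vapply(per_rep, mean, numeric(1))
  sem <- vapply(per_rep, function(x) {
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  }, numeric(1))

  get <- function(an) if (an %in% names(mn)) mn[[an]] else 0
  no3_sub <- series[series$analyte == "NO3", ]
  c_init <- if (nrow(no3_sub)) {
    mean(vapply(split(no3_sub, no3_sub$replicate), function(df) {
      df <- df[order(df$time_h), ]
      conc_at(df, t_start)
    }, numeric(1)))
  } else NA_real_

  nl <- nitrogen_ledger(c_init, get("NO3"), get("NO2"), get("N2O"), get("NH4"))
  sl <- sulfur_ledger(get("sulfide"), get("S0"), get("S2O3"),
                      get("SO3"), get("SO4"))
  list(nitrogen = nl, sulfur = sl, d_om_c_consumed = get("OM_C"),
       sem = sem, flags = unique(c(flags, nl$flags, sl$flags)))
}
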