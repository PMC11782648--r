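# Readers/writers for the package's TSV dialects, plus the reproducible
# pipeline runner. TSV is canonical: UTF-8, "." decimal, fixed column order
# per dialect. Readers validate schemas hard (unit ambiguity is an error,
# never guessed); writers emit columns in the dialect order so that
# write(read(x)) round-trips content-identically.

ATOM_MULTIPLICITY <- c(NO3 = 1, NO2 = 1, N2O = 2, N2 = 2, NH4 = 1,
                       sulfide = 1, S0 = 1, S2O3 = 2, SO3 = 1, SO4 = 1,
                       OM_C = 1)

require_columns <- function(tab, need, what) {
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
}

#' Read an incubation time-series TSV
#'
#' Columns: `sample`, `treatment`, `replicate`, `time_h`, `analyte`,
#' `concentration`, `unit_basis` (`atom` or `molecule`), `below_detection`
#' (0/1). Molecule-basis rows are converted to the ledger's atom basis by the
#' analyte's atom multiplicity (N2O and N2 carry 2 N, thiosulfate 2 S);
#' below-detection rows are stored as 0 with the flag retained.
#'
#' @param path file path.
#' @return data frame on atom basis with `unit_basis` normalized to "atom".
#' @export
read_timeseries_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(tab, c("sample", "treatment", "replicate", "time_h",
                         "analyte", "concentration", "unit_basis",
                         "below_detection"), "time-series table")
  bad_unit <- setdiff(unique(tab$unit_basis), c("atom", "molecule"))
  if (length(bad_unit)) {
    stop("ambiguous unit_basis value(s): ", paste(bad_unit, collapse = ", "),
         " (must be 'atom' or 'molecule')")
  }
  bad_an <- setdiff(unique(tab$analyte), names(ATOM_MULTIPLICITY))
  if (length(bad_an)) stop("unknown analyte(s): ", paste(bad_an, collapse = ", "))
  mol <- tab$unit_basis == "molecule"
  tab$concentration[mol] <- tab$concentration[mol] *
    ATOM_MULTIPLICITY[tab$analyte[mol]]
  tab$unit_basis <- "atom"
  tab$concentration[tab$below_detection == 1] <- 0
  tab[order(tab$sample, tab$analyte, tab$replicate, tab$time_h), ]
}

#' Write an incubation time-series TSV
#' @param tab time-series data frame (atom basis).
#' @param path output path.
#' @export
write_timeseries_tsv <- function(tab, path) {
  cols <- c("sample", "treatment", "replicate", "time_h", "analyte",
            "concentration", "unit_basis", "below_detection")
  if (!"sample" %in% names(tab)) tab$sample <- "sim"
  if (!"treatment" %in% names(tab)) tab$treatment <- NA
  if (!"unit_basis" %in% names(tab)) tab$unit_basis <- "atom"
  if (!"below_detection" %in% names(tab)) tab$below_detection <- 0L
  utils::write.table(tab[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a gradient fraction TSV
#'
#' Columns: `sample`, `treatment`, `replicate`, `fraction`, exactly one of
#' `ri` / `density_g_ml` per row (never both, never neither), `marker`,
#' `copies_per_ul`. Refractive indices are converted with `cal`.
#'
#' @param path file path.
#' @param cal a [density_calibration()] for `ri` rows.
#' @return data frame with a resolved `density` column.
#' @export
read_fraction_tsv <- function(path, cal = density_calibration()) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(tab, c("sample", "treatment", "replicate", "fraction",
                         "marker", "copies_per_ul"), "fraction table")
  has_ri <- "ri" %in% names(tab)
  has_d <- "density_g_ml" %in% names(tab)
  if (!has_ri && !has_d) {
    stop("fraction table needs an 'ri' or a 'density_g_ml' column")
  }
  ri <- if (has_ri) tab$ri else rep(NA_real_, nrow(tab))
  dd <- if (has_d) tab$density_g_ml else rep(NA_real_, nrow(tab))
  both <- !is.na(ri) & !is.na(dd)
  neither <- is.na(ri) & is.na(dd)
  if (any(both) || any(neither)) {
    stop("each row must supply exactly one of ri / density_g_ml (rows: ",
         paste(utils::head(which(both | neither), 5), collapse = ", "), ")")
  }
  tab$density <- dd
  if (any(is.na(dd))) {
    tab$density[is.na(dd)] <- density_from_refractive_index(ri[is.na(dd)], cal)
  }
  tab
}

#' Write a gradient fraction TSV
#' @param tab fraction table with `density` column.
#' @param path output path.
#' @export
write_fraction_tsv <- function(tab, path) {
  tab$density_g_ml <- tab$density
  cols <- c("sample", "treatment", "replicate", "fraction", "density_g_ml",
            "marker", "copies_per_ul")
  if (!"copies_per_ul" %in% names(tab) && "copies" %in% names(tab)) {
    tab$copies_per_ul <- tab$copies
  }
  for (c0 in c("sample", "treatment", "replicate")) {
    if (!c0 %in% names(tab)) tab[[c0]] <- NA
  }
  utils::write.table(tab[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Read a heavy-fraction abundance TSV
#'
#' Columns: `taxon`, `treatment_code`, `replicate`, `rel_abundance_pct`.
#' Treatment codes are parsed strictly (see [parse_treatment_code()]).
#'
#' @param path file path.
#' @return validated heavy abundance table (column `treatment`).
#' @export
read_heavy_abundance_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  require_columns(tab, c("taxon", "treatment_code", "replicate",
                         "rel_abundance_pct"), "heavy abundance table")
  names(tab)[names(tab) == "treatment_code"] <- "treatment"
  validate_heavy_table(tab)
  tab
}

#' Write a heavy-fraction abundance TSV
#' @param tab heavy abundance table.
#' @param path output path.
#' @export
write_heavy_abundance_tsv <- function(tab, path) {
  out <- data.frame(taxon = tab$taxon, treatment_code = tab$treatment,
                    replicate = tab$replicate,
                    rel_abundance_pct = tab$rel_abundance_pct)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(config)), f)
  unname(tools::md5sum(f))
}

#' Run the full synthetic pipeline: simulate, gradient, classify, electrons, thermo
#'
#' Chains the stages over a seeded synthetic community, persisting every
#' intermediate as TSV under `out_dir` and recording a run manifest (tool
#' version, config hash, seeds, file digests, thresholds, timestamps). Given
#' the same config the data files are digest-identical across runs.
#'
#' @param config list with optional elements `seed`, `n_taxa`, `effect_pp`,
#'   `thresholds` (a [decision_thresholds()]), `heavy_threshold` (g/mL),
#'   `alpha`, `t_window` (c(t0, t1) h), `treatment` (a [treatment_key()]).
#' @param out_dir output directory (created if needed).
#' @return list with the stage results and the `manifest`; the manifest is
#'   also written to `manifest.json`.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("sipflux_run_")) {
  cfg <- utils::modifyList(list(
    seed = 1, n_taxa = 20, effect_pp = 2,
    thresholds = decision_thresholds(), heavy_threshold = 1.725,
    alpha = 0.05, t_window = c(0, 63),
    treatment = treatment_key(TRUE, TRUE, TRUE, TRUE, "13Co")), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(tool = "sipflux",
                   version = as.character(utils::packageVersion("sipflux")),
                   config_hash = config_hash(cfg),
                   seed = cfg$seed,
                   thresholds = unclass(cfg$thresholds),
                   heavy_threshold = cfg$heavy_threshold,
                   alpha = cfg$alpha,
                   started = format(Sys.time(), tz = "UTC"),
                   status = "running", files = list())

  community <- make_community(n_taxa = cfg$n_taxa, seed = cfg$seed)
  sim <- simulate_incubation(community,
                             microcosm_config(cfg$treatment, seed = cfg$seed))
  ts_path <- file.path(out_dir, "timeseries.tsv")
  ts <- sim$series
  ts$sample <- "microcosm"; ts$treatment <- treatment_code(cfg$treatment)
  write_timeseries_tsv(ts, ts_path)

  grad <- simulate_gradient(sim$truth$taxa, heavy_threshold = cfg$heavy_threshold,
                            seed = cfg$seed)
  fr_path <- file.path(out_dir, "fractions.tsv")
  fr <- grad$profile$fractions
  fr$sample <- "microcosm"; fr$treatment <- treatment_code(cfg$treatment)
  fr$replicate <- 1L; fr$copies_per_ul <- fr$copies
  write_fraction_tsv(fr, fr_path)

  heavy <- simulate_heavy_abundance(community, effect_pp = cfg$effect_pp,
                                    seed = cfg$seed)
  hv_path <- file.path(out_dir, "heavy_abundance.tsv")
  write_heavy_abundance_tsv(heavy$table, hv_path)

  calls <- classify_community(heavy$table, cfg$thresholds)
  calls_path <- file.path(out_dir, "calls.tsv")
  utils::write.table(calls_table(calls), calls_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  ev <- do.call(rbind, lapply(calls, function(cl) cl$evidence))
  utils::write.table(ev, file.path(out_dir, "evidence.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  nc <- net_changes(sim$series, cfg$t_window[1], cfg$t_window[2])
  bal <- balance_result(nc$nitrogen, nc$sulfur, nc$d_om_c_consumed)
  bal_path <- file.path(out_dir, "balance.tsv")
  utils::write.table(
    data.frame(statistic = c("n_com", "p_s_den", "p_om_den", "n2o_pct"),
               value = c(bal$n_com, bal$p_s_den, bal$p_om_den, bal$n2o_pct),
               flags = paste(bal$flags, collapse = ";")),
    bal_path, sep = "\t", quote = FALSE, row.names = FALSE)

  lib <- species_library()
  energies <- lapply(reaction_presets(), delta_g_standard, lib = lib)
  th_path <- file.path(out_dir, "reaction_energies.tsv")
  utils::write.table(
    data.frame(reaction = names(energies),
               dG0_kJ = vapply(energies, `[[`, numeric(1), "dG0"),
               dG0_per_nitrate_kJ = vapply(energies, `[[`, numeric(1),
                                           "dG0_per_nitrate")),
    th_path, sep = "\t", quote = FALSE, row.names = FALSE)

  paths <- c(timeseries = ts_path, fractions = fr_path,
             heavy_abundance = hv_path, calls = calls_path, balance = bal_path,
             reaction_energies = th_path)
  manifest$files <- as.list(stats::setNames(unname(tools::md5sum(paths)),
                                            names(paths)))
  manifest$status <- "complete"
  manifest$finished <- format(Sys.time(), tz = "UTC")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  list(out_dir = out_dir, community = community, incubation = sim,
       gradient = grad, heavy = heavy, calls = calls, balance = bal,
       energies = energies, manifest = manifest)
}
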