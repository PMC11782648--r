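# build a heavy table from a named list treatment -> per-replicate abundances
heavy_table <- function(taxon, values, n_reps = 3) {
  do.call(rbind, lapply(names(values), function(tr) {
    v <- rep_len(values[[tr]], n_reps)
    data.frame(taxon = taxon, treatment = tr, replicate = seq_len(n_reps),
               rel_abundance_pct = v)
  }))
}

ALL_TREATMENTS <- c("12Ci+12Co+N+S", "12Ci+12Co+N", "13Ci+12Co+N+S",
                    "13Ci+12Co+N", "12Ci+13Co+N+S", "12Ci+13Co+N",
                    "13Ci+N+S", "12Ci+N+S", "13Ci", "12Ci")

test_that("treatment-code grammar round-trips and rejects malformed codes", {
  for (code in ALL_TREATMENTS) {
    expect_identical(treatment_code(parse_treatment_code(code)), code)
  }
  k <- parse_treatment_code("12Ci+13Co+N+S")
  expect_true(k$ci_present && k$co_present && k$n_present && k$s_present)
  expect_identical(k$label, "13Co")
  expect_identical(parse_treatment_code("12Ci")$label, "12C")

  expect_error(parse_treatment_code("13Ci+13Co"), "two labels")
  expect_error(parse_treatment_code("12C+N"), "malformed")
  expect_error(parse_treatment_code("12Ci+12Ci"), "malformed")
  expect_error(parse_treatment_code(""), "malformed")
  expect_error(treatment_key(label = "13Ci"), "requires ci_present")
})

test_that("heavy-table validation catches schema and composition errors", {
  tab <- heavy_table("t1", list("12Ci" = c(5, 6, 7)))
  expect_invisible(validate_heavy_table(tab))
  expect_error(validate_heavy_table(tab[, -4]), "missing columns")
  bad <- tab; bad$rel_abundance_pct[1] <- 101
  expect_error(validate_heavy_table(bad), "\\[0, 100\\]")
  bad2 <- tab; bad2$treatment <- "14C"
  expect_error(validate_heavy_table(bad2), "malformed")
  over <- rbind(tab, heavy_table("t2", list("12Ci" = c(96, 96, 96))))
  expect_error(validate_heavy_table(over), "sum above 100")
})

test_that("abundance deltas: difference, fold, replicate support, zero baseline", {
  tab <- heavy_table("t1", list(A = c(10, 12, 11), B = c(5, 6, 4)))
  names(tab)[2] <- "treatment"  # keep codes arbitrary for this unit
  tab$treatment <- ifelse(tab$treatment == "A", "12Ci+N+S", "12Ci")
  d <- abundance_delta(tab, "t1", "12Ci+N+S", "12Ci")
  expect_equal(d$delta_pp, 11 - 5)
  expect_equal(d$fold, 11 / 5)
  expect_equal(d$support, 1)
  expect_identical(d$flags, character(0))

  z <- heavy_table("t1", list("12Ci+N+S" = c(1, 1, 1), "12Ci" = c(0, 0, 0)))
  dz <- abundance_delta(z, "t1", "12Ci+N+S", "12Ci")
  expect_true("zero-baseline" %in% dz$flags)
  expect_equal(dz$fold, 1 / 0.01)

  tie <- heavy_table("t1", list("12Ci+N+S" = c(5, 5, 5), "12Ci" = c(5, 5, 5)))
  expect_equal(abundance_delta(tie, "t1", "12Ci+N+S", "12Ci")$support, 0.5)

  expect_error(abundance_delta(tab, "t1", "13Ci", "12Ci"), "absent for taxon")
})

test_that("decision thresholds validate their domains", {
  th <- decision_thresholds()
  expect_equal(th$min_delta_pp, 0.5)
  expect_equal(th$min_fold, 1.2)
  expect_equal(th$min_replicate_support, 2 / 3)
  expect_error(decision_thresholds(min_delta_pp = -1), ">= 0")
  expect_error(decision_thresholds(min_fold = 0.9), ">= 1")
  expect_error(decision_thresholds(min_replicate_support = 0.5), "\\(0.5, 1\\]")
})

test_that("a textbook F-SOHD passes heterotroph + sulfide-oxidizer rules only", {
  # responds to 13Co labelling (heterotroph) and gains further heavy
  # abundance when sulfide is added under 13Co (heterotrophic S oxidizer);
  # no response to 13Ci
  vals <- list("12Ci+12Co+N+S" = 2, "12Ci+12Co+N" = 2,
               "13Ci+12Co+N+S" = 2, "13Ci+12Co+N" = 2,
               "12Ci+13Co+N+S" = 16, "12Ci+13Co+N" = 8,
               "13Ci+N+S" = 2, "12Ci+N+S" = 2, "13Ci" = 2, "12Ci" = 2)
  cl <- classify_taxon(heavy_table("fsohd1", vals), "fsohd1")
  expect_true(cl$flags[["heterotroph"]])
  expect_true(cl$flags[["heterotroph_sulfide_oxidizer"]])
  expect_true(cl$flags[["sulfide_oxidizer"]])
  expect_true(cl$flags[["fsohd"]])
  expect_false(cl$flags[["chemolithoautotroph"]])
  expect_false(cl$flags[["autotroph_sulfide_oxidizer"]])
  expect_false(cl$flags[["nitrate_reducer_sulfur_oxidizer"]])
  # every flag decision is backed by evidence rows
  expect_true(all(c("treatA", "treatB", "delta_pp", "fold", "support",
                    "passed") %in% names(cl$evidence)))
})

test_that("a chemolithoautotrophic sulfur-oxidizing denitrifier is separated", {
  vals <- list("12Ci+12Co+N+S" = 2, "12Ci+12Co+N" = 2,
               "13Ci+12Co+N+S" = 14, "13Ci+12Co+N" = 6,
               "12Ci+13Co+N+S" = 2, "12Ci+13Co+N" = 2,
               "13Ci+N+S" = 12, "12Ci+N+S" = 2, "13Ci" = 3, "12Ci" = 3)
  cl <- classify_taxon(heavy_table("cd1", vals), "cd1")
  expect_true(cl$flags[["chemolithoautotroph"]])
  expect_true(cl$flags[["autotroph_sulfide_oxidizer"]])
  expect_true(cl$flags[["nitrate_reducer_sulfur_oxidizer"]])
  expect_false(cl$flags[["heterotroph"]])
  expect_false(cl$flags[["heterotroph_sulfide_oxidizer"]])
  expect_false(cl$flags[["fsohd"]])
})

test_that("a conventional heterotrophic denitrifier is not called a sulfide oxidizer", {
  vals <- list("12Ci+12Co+N+S" = 2, "12Ci+12Co+N" = 2,
               "13Ci+12Co+N+S" = 2, "13Ci+12Co+N" = 2,
               "12Ci+13Co+N+S" = 10, "12Ci+13Co+N" = 10,
               "13Ci+N+S" = 2, "12Ci+N+S" = 2, "13Ci" = 2, "12Ci" = 2)
  cl <- classify_taxon(heavy_table("hd1", vals), "hd1")
  expect_true(cl$flags[["heterotroph"]])
  expect_false(cl$flags[["heterotroph_sulfide_oxidizer"]])
  expect_false(cl$flags[["fsohd"]])
})

test_that("missing treatments give NA (not evaluable), never FALSE", {
  vals <- list("12Ci+13Co+N+S" = 16, "12Ci+13Co+N" = 8,
               "12Ci+12Co+N+S" = 2, "12Ci+12Co+N" = 2)
  cl <- classify_taxon(heavy_table("t1", vals), "t1")
  expect_true(cl$flags[["heterotroph"]])
  expect_true(cl$flags[["heterotroph_sulfide_oxidizer"]])
  expect_true(is.na(cl$flags[["chemolithoautotroph"]]))
  expect_true(is.na(cl$flags[["nitrate_reducer_sulfur_oxidizer"]]))
  expect_true(cl$flags[["fsohd"]])  # both conjuncts evaluable and TRUE
  # fsohd is NA when a conjunct is not evaluable
  cl2 <- classify_taxon(heavy_table("t1", vals["12Ci+13Co+N+S"]), "t1")
  expect_true(is.na(cl2$flags[["fsohd"]]))
})

test_that("rule label-mode options switch the comparisons used", {
  # taxon responding in the unlabelled +Ci contrast only
  vals <- list("12Ci+N+S" = 10, "12Ci" = 2, "13Ci+N+S" = 2, "13Ci" = 2)
  tab <- heavy_table("t1", vals)
  cl_13 <- classify_taxon(tab, "t1", rule3_label = "13Ci")
  cl_12 <- classify_taxon(tab, "t1", rule3_label = "12Ci")
  expect_false(cl_13$flags[["nitrate_reducer_sulfur_oxidizer"]])
  expect_true(cl_12$flags[["nitrate_reducer_sulfur_oxidizer"]])

  vals4 <- list("12Ci+12Co+N+S" = 9, "12Ci+12Co+N" = 2,
                "12Ci+13Co+N+S" = 2, "12Ci+13Co+N" = 2)
  tab4 <- heavy_table("t1", vals4)
  expect_false(classify_taxon(tab4, "t1")$flags[["sulfide_oxidizer"]])
  expect_true(
    classify_taxon(tab4, "t1", rule4_label = "12C")$flags[["sulfide_oxidizer"]])
})

test_that("sub-threshold responses are rejected by each threshold axis", {
  base <- list("12Ci+13Co+N+S" = c(10.3, 10.4, 10.2),
               "12Ci+13Co+N" = c(10.0, 10.1, 9.9),
               "12Ci+12Co+N+S" = 2, "12Ci+12Co+N" = 2)
  # delta ~0.3 pp < 0.5 and fold ~1.03 < 1.2 despite full support
  cl <- classify_taxon(heavy_table("t1", base), "t1")
  expect_false(cl$flags[["heterotroph_sulfide_oxidizer"]])

  # inconsistent replicates: mean passes but support fails
  mix <- list("12Ci+13Co+N+S" = c(30, 1, 1), "12Ci+13Co+N" = c(2, 2, 2),
              "12Ci+12Co+N+S" = 2, "12Ci+12Co+N" = 2)
  cl2 <- classify_taxon(heavy_table("t1", mix), "t1")
  ev <- cl2$evidence
  row <- ev[ev$rule == "heterotroph_sulfide_oxidizer" &
              ev$treatA == "12Ci+13Co+N+S" & ev$treatB == "12Ci+13Co+N", ]
  expect_lt(row$support, 2 / 3)
  expect_false(cl2$flags[["heterotroph_sulfide_oxidizer"]])
})

test_that("classify_community is deterministic and error-isolating", {
  tabA <- heavy_table("zeta", list("12Ci+13Co+N+S" = 16, "12Ci+13Co+N" = 8,
                                   "12Ci+12Co+N+S" = 2, "12Ci+12Co+N" = 2))
  tabB <- heavy_table("alpha", list("12Ci+13Co+N+S" = 2, "12Ci+13Co+N" = 2,
                                    "12Ci+12Co+N+S" = 2, "12Ci+12Co+N" = 2))
  calls <- classify_community(rbind(tabA, tabB))
  expect_identical(names(calls), c("alpha", "zeta"))  # sorted order
  tb <- calls_table(calls)
  expect_identical(tb$taxon, c("alpha", "zeta"))
  expect_true(tb$heterotroph[tb$taxon == "zeta"])
  expect_false(tb$heterotroph[tb$taxon == "alpha"])
})

test_that("guild composition computes abundance-weighted shares", {
  mk <- function(taxon, het, aut, r3) {
    # hand-build a function_call-shaped object
    structure(list(taxon = taxon,
                   flags = c(chemolithoautotroph = aut, heterotroph = het,
                             nitrate_reducer_sulfur_oxidizer = r3,
                             sulfide_oxidizer = FALSE,
                             autotroph_sulfide_oxidizer = FALSE,
                             heterotroph_sulfide_oxidizer = FALSE,
                             fsohd = FALSE)),
              class = "function_call")
  }
  calls <- list(a = mk("a", TRUE, FALSE, TRUE),   # heterotrophic S/N taxon
                b = mk("b", FALSE, TRUE, TRUE),   # autotrophic S/N taxon
                c = mk("c", TRUE, FALSE, FALSE))  # heterotroph outside ref set
  ab <- c(a = 30, b = 10, c = 60)
  gs <- guild_composition(calls, ab)
  expect_identical(sort(gs$reference_taxa), c("a", "b"))
  expect_equal(unname(gs$shares["heterotroph"]), 100 * 30 / 40)
  expect_equal(unname(gs$shares["chemolithoautotroph"]), 100 * 10 / 40)
  expect_equal(gs$denominator_pct, 40)
  expect_error(guild_composition(calls, c(a = 30)), "abundances missing")
  none <- list(c = mk("c", TRUE, FALSE, FALSE))
  expect_error(guild_composition(none, ab), "empty reference set")
})
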