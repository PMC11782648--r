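# Community-isotope-corrected function assignment.
#
# Carbon, nitrogen and sulfur functions are inferred per taxon by comparing
# its heavy-fraction relative abundance across an amendment-by-label
# treatment matrix: a taxon that enters the heavy DNA only when a particular
# 13C source and electron donor/acceptor combination is supplied is assigned
# the corresponding metabolism. Because the same comparisons are made against
# unlabelled controls of identical chemistry, community-wide responses to the
# amendments themselves cancel out (the "community isotope response"
# correction).

#' Parse a treatment code
#'
#' Strict grammar: tokens joined by `+`, each from
#' `12Ci, 13Ci, 12Co, 13Co, N, S`. At most one `13*` token (the label).
#' Examples: `"12Ci+13Co+N+S"`, `"13Ci+N+S"`, `"12Ci"`.
#'
#' @param code treatment code string.
#' @return object of class `treatment_key`: logicals `ci_present`,
#'   `co_present`, `n_present`, `s_present` and `label` in
#'   `{"12C", "13Ci", "13Co"}`.
#' @export
parse_treatment_code <- function(code) {
  toks <- strsplit(code, "+", fixed = TRUE)[[1]]
  allowed <- c("12Ci", "13Ci", "12Co", "13Co", "N", "S")
  bad <- setdiff(toks, allowed)
  if (length(bad) || !length(toks) || anyDuplicated(toks)) {
    stop("malformed treatment code '", code, "' (tokens must be from ",
         paste(allowed, collapse = ", "), ")")
  }
  labels <- intersect(toks, c("13Ci", "13Co"))
  if (length(labels) > 1) stop("treatment code '", code, "' has two labels")
  treatment_key(ci_present = any(toks %in% c("12Ci", "13Ci")),
                co_present = any(toks %in% c("12Co", "13Co")),
                n_present = "N" %in% toks, s_present = "S" %in% toks,
                label = if (length(labels)) labels else "12C")
}

#' Construct a treatment key
#' @param ci_present,co_present,n_present,s_present amendment booleans
#'   (inorganic carbon, organic carbon, nitrate, sulfide).
#' @param label `"12C"` (unlabelled), `"13Ci"` or `"13Co"`.
#' @return object of class `treatment_key`.
#' @export
treatment_key <- function(ci_present = FALSE, co_present = FALSE,
                          n_present = FALSE, s_present = FALSE,
                          label = c("12C", "13Ci", "13Co")) {
  label <- match.arg(label)
  if (label == "13Ci" && !ci_present) stop("label 13Ci requires ci_present")
  if (label == "13Co" && !co_present) stop("label 13Co requires co_present")
  structure(list(ci_present = ci_present, co_present = co_present,
                 n_present = n_present, s_present = s_present, label = label),
            class = "treatment_key")
}

#' Canonical treatment code for a key
#' @param key a [treatment_key()].
#' @return code string in canonical token order.
#' @export
treatment_code <- function(key) {
  toks <- c(
    if (key$ci_present) if (key$label == "13Ci") "13Ci" else "12Ci",
    if (key$co_present) if (key$label == "13Co") "13Co" else "12Co",
    if (key$n_present) "N",
    if (key$s_present) "S")
  paste(toks, collapse = "+")
}

#' Validate a heavy-fraction abundance table
#'
#' @param table data frame with columns `taxon`, `treatment` (code string),
#'   `replicate`, `rel_abundance_pct` in \[0, 100\]. Per treatment x replicate,
#'   listed taxa may sum to less than 100 (only abundant taxa are tabulated)
#'   but never materially more.
#' @param tol tolerance on the 100% column-sum bound.
#' @return the table, invisibly, after validation.
#' @export
validate_heavy_table <- function(table, tol = 0.5) {
  need <- c("taxon", "treatment", "replicate", "rel_abundance_pct")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("heavy table missing columns: ", paste(miss, collapse = ", "))
  if (any(table$rel_abundance_pct < 0 | table$rel_abundance_pct > 100)) {
    stop("relative abundances must lie in [0, 100]")
  }
  invisible(lapply(unique(table$treatment), parse_treatment_code))
  sums <- tapply(table$rel_abundance_pct,
                 interaction(table$treatment, table$replicate, drop = TRUE), sum)
  if (any(sums > 100 + tol)) {
    stop("per-treatment replicate abundances sum above 100%")
  }
  invisible(table)
}

#' Decision thresholds for calling an "increase"
#'
#' The source method never quantifies "increase in relative abundance"; these
#' three conjunctive knobs operationalize it and are recorded on every call.
#' Defaults separate the reported effect sizes (fractions of a point up to
#' tens of points, several-fold) from replicate noise.
#'
#' @param min_delta_pp minimum mean difference, percentage points.
#' @param min_fold minimum fold change (>= 1).
#' @param min_replicate_support minimum fraction of replicate pairings with a
#'   positive difference, in (0.5, 1].
#' @return object of class `decision_thresholds`.
#' @export
decision_thresholds <- function(min_delta_pp = 0.5, min_fold = 1.2,
                                min_replicate_support = 2 / 3) {
  if (min_delta_pp < 0) stop("min_delta_pp must be >= 0")
  if (min_fold < 1) stop("min_fold must be >= 1")
  if (min_replicate_support <= 0.5 || min_replicate_support > 1) {
    stop("min_replicate_support must lie in (0.5, 1]")
  }
  structure(list(min_delta_pp = min_delta_pp, min_fold = min_fold,
                 min_replicate_support = min_replicate_support),
            class = "decision_thresholds")
}

#' Heavy-fraction abundance difference between two treatments
#'
#' @param table heavy abundance table (see [validate_heavy_table()]).
#' @param taxon taxon identifier.
#' @param treatA,treatB treatment code strings (A is the putatively enriched
#'   condition).
#' @param eps pseudo-abundance (pp) substituted for a zero denominator in the
#'   fold change; flagged when used.
#' @return list: `delta_pp` (mean A - mean B), `fold` (mean A / mean B, with
#'   `eps` for zero baselines), `support` (fraction of replicate pairings
#'   with A > B; ties count 1/2), `flags`.
#' @export
abundance_delta <- function(table, taxon, treatA, treatB, eps = 0.01) {
  a <- table$rel_abundance_pct[table$taxon == taxon & table$treatment == treatA]
  b <- table$rel_abundance_pct[table$taxon == taxon & table$treatment == treatB]
  if (!length(a)) stop("treatment ", treatA, " absent for taxon ", taxon)
  if (!length(b)) stop("treatment ", treatB, " absent for taxon ", taxon)
  flags <- character(0)
  mb <- mean(b)
  if (mb <= 0) { mb <- eps; flags <- c(flags, "zero-baseline") }
  pairs <- outer(a, b, `-`)
  support <- mean((pairs > 0) + 0.5 * (pairs == 0))
  list(delta_pp = mean(a) - mean(b), fold = mean(a) / mb,
       support = support, flags = flags)
}

# The treatment-comparison rule book. Each rule is a conjunction of
# (enriched treatment, baseline treatment) comparisons over heavy-fraction
# relative abundances.
rule_comparisons <- function(rule3_label = c("13Ci", "12Ci"),
                             rule4_label = c("13Co", "13Ci", "12C")) {
  rule3_label <- match.arg(rule3_label)
  rule4_label <- match.arg(rule4_label)
  r3 <- if (rule3_label == "13Ci") c("13Ci+N+S", "13Ci") else c("12Ci+N+S", "12Ci")
  r4 <- switch(rule4_label,
               "13Co" = c("12Ci+13Co+N+S", "12Ci+13Co+N"),
               "13Ci" = c("13Ci+12Co+N+S", "13Ci+12Co+N"),
               "12C"  = c("12Ci+12Co+N+S", "12Ci+12Co+N"))
  list(
    chemolithoautotroph = list(
      c("13Ci+12Co+N+S", "12Ci+12Co+N+S"),
      c("13Ci+N+S", "12Ci+N+S")),
    heterotroph = list(
      c("12Ci+13Co+N+S", "12Ci+12Co+N+S"),
      c("12Ci+13Co+N", "12Ci+12Co+N")),
    nitrate_reducer_sulfur_oxidizer = list(r3),
    sulfide_oxidizer = list(r4),
    autotroph_sulfide_oxidizer = list(
      c("13Ci+12Co+N+S", "13Ci+12Co+N"),
      c("13Ci+12Co+N+S", "12Ci+12Co+N+S")),
    heterotroph_sulfide_oxidizer = list(
      c("12Ci+13Co+N+S", "12Ci+12Co+N+S"),
      c("12Ci+13Co+N+S", "12Ci+13Co+N"))
  )
}

#' Assign carbon, nitrogen and sulfur functions to one taxon
#'
#' Applies the treatment-comparison rules over heavy-fraction relative
#' abundances:
#' * chemolithoautotroph: increase in (13Ci+12Co)+N+S vs (12Ci+12Co)+N+S AND
#'   13Ci+N+S vs 12Ci+N+S;
#' * heterotroph: increase in (12Ci+13Co)+N+S vs (12Ci+12Co)+N+S AND
#'   (12Ci+13Co)+N vs (12Ci+12Co)+N;
#' * nitrate reduction + sulfur oxidation: increase in +Ci+N+S vs +Ci;
#' * sulfide oxidation: increase in +C+N+S vs +C+N;
#' * autotrophic sulfide oxidizer: increase in (13Ci+12Co)+N+S vs both
#'   (13Ci+12Co)+N and (12Ci+12Co)+N+S;
#' * heterotrophic sulfide oxidizer: increase in (12Ci+13Co)+N+S vs both
#'   (12Ci+12Co)+N+S and (12Ci+13Co)+N;
#' * fsohd (facultative sulfide-oxidizing heterotrophic denitrifier):
#'   heterotroph AND heterotrophic sulfide oxidizer.
#'
#' "Increase" means passing all three [decision_thresholds()]. A rule whose
#' required treatments are absent from the table is `NA` (not evaluable),
#' never `FALSE`. Every raised flag is backed by the evidence rows returned.
#'
#' @param table heavy abundance table.
#' @param taxon taxon identifier.
#' @param thresholds a [decision_thresholds()].
#' @param rule3_label whether the nitrate-reduction rule compares the
#'   13Ci-labelled (default) or unlabelled heavy fractions.
#' @param rule4_label label context of the sulfide-oxidation rule (default
#'   compares the 13Co-labelled heavy fractions).
#' @param eps pseudo-abundance for zero baselines.
#' @return object of class `function_call`: `taxon`, logical `flags`,
#'   `evidence` data frame (one row per comparison), `thresholds`, plus a
#'   fixed compositionality `caveat`.
#' @export
classify_taxon <- function(table, taxon, thresholds = decision_thresholds(),
                           rule3_label = "13Ci", rule4_label = "13Co",
                           eps = 0.01) {
  rules <- rule_comparisons(rule3_label, rule4_label)
  present <- unique(table$treatment[table$taxon == taxon])
  ev <- list(); flags <- stats::setNames(rep(NA, length(rules)), names(rules))
  for (rn in names(rules)) {
    cmps <- rules[[rn]]
    needed <- unique(unlist(cmps))
    if (!all(needed %in% present)) next  # not evaluable -> NA
    pass_all <- TRUE
    for (cmp in cmps) {
      d <- abundance_delta(table, taxon, cmp[1], cmp[2], eps)
      passed <- d$delta_pp >= thresholds$min_delta_pp &&
        d$fold >= thresholds$min_fold &&
        d$support >= thresholds$min_replicate_support
      ev[[length(ev) + 1L]] <- data.frame(
        taxon = taxon, rule = rn, treatA = cmp[1], treatB = cmp[2],
        delta_pp = d$delta_pp, fold = d$fold, support = d$support,
        passed = passed,
        flags = paste(d$flags, collapse = ";"))
      pass_all <- pass_all && passed
    }
    flags[rn] <- pass_all
  }
  flags <- c(flags, fsohd = unname(
    flags[["heterotroph"]] & flags[["heterotroph_sulfide_oxidizer"]]))
  structure(list(
    taxon = taxon, flags = flags,
    evidence = if (length(ev)) do.call(rbind, ev) else NULL,
    thresholds = thresholds,
    caveat = paste("relative-abundance deltas in heavy fractions are",
                   "compositional and do not measure absolute growth")),
    class = "function_call")
}

#' Classify every taxon in a heavy-abundance table
#'
#' @inheritParams classify_taxon
#' @return named list of [classify_taxon()] results in deterministic
#'   (sorted-taxon) order; per-taxon errors are captured as `NULL` entries
#'   with a warning rather than aborting the batch.
#' @export
classify_community <- function(table, thresholds = decision_thresholds(),
                               rule3_label = "13Ci", rule4_label = "13Co",
                               eps = 0.01) {
  validate_heavy_table(table)
  taxa <- sort(unique(table$taxon))
  calls <- lapply(taxa, function(tx) {
    tryCatch(classify_taxon(table, tx, thresholds, rule3_label, rule4_label, eps),
             error = function(e) {
               warning("taxon ", tx, " could not be classified: ",
                       conditionMessage(e))
               NULL
             })
  })
  stats::setNames(calls, taxa)
}

#' Tabulate community function calls
#' @param calls result of [classify_community()].
#' @return data frame, one row per taxon, one logical column per flag.
#' @export
calls_table <- function(calls) {
  calls <- Filter(Negate(is.null), calls)
  do.call(rbind, lapply(calls, function(cl) {
    cbind(data.frame(taxon = cl$taxon), as.data.frame(t(cl$flags)))
  }))
}

#' Guild composition among a reference set of taxa
#'
#' Shares (%) of each `group_flag` among taxa that belong to the reference
#' set (default: the denitrifying sulfur-oxidizer community, i.e. taxa with a
#' nitrate-reduction-plus-sulfur-oxidation or sulfide-oxidation flag),
#' weighted by supplied community abundances. The denominator choice is
#' recorded on the result.
#'
#' @param calls result of [classify_community()].
#' @param reference_abundances named numeric vector of community relative
#'   abundances (%) covering all called taxa used.
#' @param reference_flags flags defining membership in the reference set
#'   (any-of semantics).
#' @param group_flags flags whose shares within the reference set are wanted.
#' @return object of class `guild_summary`: named `shares` (%),
#'   `reference_taxa`, `reference_flags`, `denominator_pct`.
#' @export
guild_composition <- function(calls, reference_abundances,
                              reference_flags = c("nitrate_reducer_sulfur_oxidizer",
                                                  "sulfide_oxidizer"),
                              group_flags = c("heterotroph", "chemolithoautotroph")) {
  calls <- Filter(Negate(is.null), calls)
  in_ref <- vapply(calls, function(cl) {
    any(cl$flags[reference_flags] %in% TRUE)
  }, logical(1))
  ref <- names(calls)[in_ref]
  if (!length(ref)) stop("empty reference set: no taxon carries ",
                         paste(reference_flags, collapse = " or "))
  missing_ab <- setdiff(ref, names(reference_abundances))
  if (length(missing_ab)) {
    stop("abundances missing for taxa: ", paste(missing_ab, collapse = ", "))
  }
  denom <- sum(reference_abundances[ref])
  shares <- vapply(group_flags, function(fl) {
    sel <- ref[vapply(ref, function(tx) isTRUE(calls[[tx]]$flags[[fl]]), logical(1))]
    100 * sum(reference_abundances[sel]) / denom
  }, numeric(1))
  structure(list(shares = shares, reference_taxa = ref,
                 reference_flags = reference_flags, denominator_pct = denom),
            class = "guild_summary")
}
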