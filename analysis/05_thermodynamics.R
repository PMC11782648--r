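#!/usr/bin/env Rscript
# Step 5: standard Gibbs energies of the candidate metabolisms.
#
# Balances the bundled reaction presets against the formation-energy table
# and reports dG0 (pH 0) and dG0' (pH 7), total and per mol nitrate.
# Output: results/reaction_energies.tsv.

suppressPackageStartupMessages(library(sipflux))

lib <- species_library()
rows <- lapply(names(reaction_presets()), function(nm) {
  rxn <- reaction_presets()[[nm]]
  stopifnot(check_balance(rxn, lib)$ok)
  en <- delta_g_standard(rxn, lib)
  data.frame(reaction = nm, description = rxn$description,
             dG0_kJ = en$dG0, dG0_ph7_kJ = delta_g_ph7(en),
             dG0_per_nitrate_kJ = en$dG0_per_nitrate)
})
out <- do.call(rbind, rows)
write.table(out, "results/reaction_energies.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("per-nitrate dG0 (kJ): ",
        paste(sprintf("%s %.1f", out$reaction, out$dG0_per_nitrate_kJ),
              collapse = "; "))
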