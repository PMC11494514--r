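#!/usr/bin/env Rscript
# Step 1 — generate the study inputs.
#
# Two record sets are produced under results/data/:
#   * reference records: visitation + pollen records constructed to realize
#     the reference overlap structure exactly (25x115/352 visitation links,
#     413 diurnal pollen links with 183 shared, 96 nocturnal links with 13
#     shared), used by every downstream step;
#   * a synthetic community with three strongly planted modules and a
#     specialized nocturnal guild, with ground truth, used for recovery
#     checks in step 5.

suppressPackageStartupMessages(library(pollinet))
dir.create("results/data", showWarnings = FALSE, recursive = TRUE)

fx <- simulate_reference_records(seed = 1)
write.csv(fx$visits, "results/data/visits.csv", row.names = FALSE)
write.csv(fx$pollen, "results/data/pollen.csv", row.names = FALSE)
message(sprintf("reference records: %d visit events, %d pollen rows",
                nrow(fx$visits), nrow(fx$pollen)))

cfg <- community_config(n_plants = 12L, n_diurnal_pollinators = 18L,
                        n_nocturnal_pollinators = 4L, n_modules = 3L,
                        module_strength = 50, abundance_sigma = 0.5,
                        n_visit_events = 150L, seed = 7)
comm <- simulate_community(cfg)
sv <- simulate_visitation(comm)
write.csv(sv, "results/data/synthetic_visits.csv", row.names = FALSE)
truth <- rbind(
  data.frame(species = comm$plants$taxon, module = comm$plants$module),
  data.frame(species = comm$pollinators$taxon,
             module = comm$pollinators$module))
write.csv(truth, "results/data/synthetic_truth.csv", row.names = FALSE)
message(sprintf("synthetic community: %d species, %d planted modules",
                nrow(truth), cfg$n_modules))
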