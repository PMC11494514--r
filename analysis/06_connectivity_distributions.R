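#!/usr/bin/env Rscript
# Step 6 — connectivity distributions and the f-s relationship.
#
# Fits exponential / power-law / truncated power-law models to the
# cumulative connectivity distribution of each matrix (both guilds), then
# regresses log10 connectivity on log10 interaction frequency and tests
# whether the slope changes across V_d, V_dP_d and V_dP_dP_n.

suppressPackageStartupMessages(library(pollinet))
dir.create("results", showWarnings = FALSE)

visits <- read_visit_records("results/data/visits.csv")
pollen <- read_pollen_records("results/data/pollen.csv")
vd <- build_visitation_matrix(visits)
pd <- build_pollen_matrix(pollen, "diurnal")
pn <- build_pollen_matrix(pollen, "nocturnal")
vdpd <- superimpose(list(vd, pd), "V_dP_d")
vdpdpn <- superimpose(list(vdpd, pn), "V_dP_dP_n")
mats <- list(vd, pd, vdpd, pn, vdpdpn)

fits <- do.call(rbind, unlist(lapply(mats, function(M) {
  lapply(c("pollinators", "plants"), function(sd) {
    f <- fit_connectivity_models(cumulative_distribution(M, sd))
    cbind(matrix = M$name, side = sd, as.data.frame(f))
  })
}), recursive = FALSE))
write.csv(fits, "results/connectivity_fits.csv", row.names = FALSE)
message("selected model per matrix and side:")
print(fits[fits$selected, c("matrix", "side", "model", "b", "k_x")])

for (sd in c("pollinators", "plants")) {
  f <- interaction_frequency(visits, sd)
  groups <- lapply(list(vd, vdpd, vdpdpn), function(M) {
    con <- species_connectivity(M)
    con <- con[con$side == sd, ]
    sp <- intersect(con$species, names(f))
    list(f = as.numeric(f[sp]),
         s = as.numeric(con$degree[match(sp, con$species)]))
  })
  names(groups) <- c("V_d", "V_dP_d", "V_dP_dP_n")
  cmp <- compare_slopes(groups)
  message(sprintf("%s f-s slope comparison:", sd))
  print(cmp)
}
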