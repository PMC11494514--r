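#!/usr/bin/env Rscript
# Step 2 — build the five binary matrices and tally link provenance.
#
# V_d (diurnal visitation), P_d (diurnal pollen, >= 5 grains per
# specimen), their union V_dP_d, P_n (nocturnal pollen), and the full
# union V_dP_dP_n are written as CSV + JSON sidecars; the seven-category
# provenance tally of the full union goes to overlap_tally.csv.

suppressPackageStartupMessages(library(pollinet))
dir.create("results/networks", showWarnings = FALSE, recursive = TRUE)

visits <- read_visit_records("results/data/visits.csv")
pollen <- read_pollen_records("results/data/pollen.csv")

vd <- build_visitation_matrix(visits)
pd <- build_pollen_matrix(pollen, "diurnal")
pn <- build_pollen_matrix(pollen, "nocturnal")
vdpd <- superimpose(list(vd, pd), "V_dP_d")
vdpdpn <- superimpose(list(vdpd, pn), "V_dP_dP_n")

for (M in list(vd, pd, vdpd, pn, vdpdpn)) {
  write_bipartite_matrix(M, file.path("results/networks",
                                      paste0(M$name, ".csv")))
  print(M)
}

tal <- overlap_tally(vdpdpn)
print(tal)
write.csv(data.frame(category = names(tal), links = as.integer(tal)),
          "results/networks/overlap_tally.csv", row.names = FALSE)
message(sprintf("union: %d links; fold-change over visitation: %.2f",
                n_links(vdpdpn), n_links(vdpdpn) / n_links(vd)))
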