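#!/usr/bin/env Rscript
# Simulate the two study societies: a zebra-like population (few large,
# cohesive, occasionally fusing communities; 27 individuals x 44 daily
# samplings) and an onager-like population (mostly singleton communities
# with frequent visiting; 29 individuals x 82 samplings). Writes the
# sighting records, planted truth and synthetic attribute tables that the
# later scripts consume.

library(commdyn)
seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

for (nm in c("grevys-like", "onager-like")) {
  g <- generate(preset(nm, seed = seed))
  stub <- sub("-like", "", nm)
  write_sightings(g$timeline, file.path(out, paste0(stub, "_sightings.csv")))
  write.csv(g$truth$events, file.path(out, paste0(stub, "_truth.csv")),
            row.names = FALSE)
  at <- synthetic_attributes(g$timeline$individuals, species = nm,
                             seed = seed)
  write.csv(at, file.path(out, paste0(stub, "_attributes.csv")),
            row.names = FALSE)
  message(sprintf("%-12s %d individuals observed, %d steps, %d groups",
                  nm, length(g$timeline$individuals),
                  length(g$timeline$steps), sum(lengths(g$timeline$groups))))
}
message("wrote ", out)
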