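#!/usr/bin/env Rscript
# Classify brain state and detect population events in every session:
# theta/delta peak frequencies, 1.6 s state windows, sharp-wave ripples,
# MUA bursts and the SWR-coincident candidate events used for replay.

suppressPackageStartupMessages(library(placeseq))

cfg <- ps_config()
all_events <- list()
for (name in c("pre", "run", "post")) {
  s <- read_session(file.path("results/sessions", name))
  sp <- speed_estimate(s)
  st <- classify_states(s$lfp[[1]], s$position$t, sp, cfg)
  f_th <- band_peak_frequency(s$lfp[[1]], cfg$theta_band)
  f_de <- band_peak_frequency(s$lfp[[1]], cfg$delta_band)
  swr <- detect_swr(s$lfp, cfg)
  mua <- detect_mua(s$spikes, s$duration, cfg)
  joint <- joint_events(mua, swr)
  cat(sprintf(
    "%s: theta %.2f Hz, delta %.2f Hz; states %s; %d SWR, %d MUA, %d joint\n",
    toupper(name), f_th, f_de,
    paste(sprintf("%s %.0f%%", names(table(st$state)),
                  100 * prop.table(table(st$state))), collapse = ", "),
    nrow(swr), nrow(mua), nrow(joint)))
  if (nrow(joint))
    all_events[[name]] <- data.frame(session = name, joint)
}
ev <- do.call(rbind, all_events)
utils::write.table(format(ev, digits = 6), "results/events.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/events.tsv\n")
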