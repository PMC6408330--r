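#!/usr/bin/env Rscript
# Cell-pair reactivation across PRE / RUN / POST: place-field similarity
# against SWR co-firing correlations in each rest session, theta-cycle
# co-firing during RUN, and the plasticity (POST - PRE) curve over RUN
# co-activity.

suppressPackageStartupMessages(library(placeseq))

cfg <- ps_config()
pre <- read_session("results/sessions/pre")
run <- read_session("results/sessions/run")
post <- read_session("results/sessions/post")
geom <- run$track
filt <- filter_immobility(run)
lin <- linearize(filt, geom)
runs <- split_directional_runs(lin, filt$position$t, geom$perimeter)

ids <- sort(unique(filt$spikes$cell_id))
maps <- lapply(ids, function(cid)
  track_ratemaps(filt, geom, cid, lin = lin, runs = runs))
names(maps) <- as.character(ids)

theta <- demarcate_theta(run$lfp[[1]], filt$spikes, runs, cfg)
swr_pre <- detect_swr(pre$lfp, cfg)
swr_post <- detect_swr(post$lfp, cfg)

pairs <- build_pair_table(pre, filt, post, maps, swr_pre, swr_post,
                          boundaries = theta$boundaries, cfg = cfg)
utils::write.table(format(pairs, digits = 4), "results/pair_table.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("pair table: %d pairs from %d cells\n", nrow(pairs), length(ids)))

for (w in c("pre", "post")) {
  cp <- pfs_swr_coupling(pairs, w)
  cat(sprintf("PFS vs SWR correlation (%s): r = %.3f +/- %.3f, p = %.2g, n = %d\n",
              toupper(w), cp$r, cp$se, cp$p, cp$n))
}
cpre <- pfs_swr_coupling(pairs, "pre"); cpost <- pfs_swr_coupling(pairs, "post")
fz <- fisher_z_compare(cpost$r, cpost$n, cpre$r, cpre$n)
cat(sprintf("POST vs PRE coupling difference (Fisher z): z = %.2f, p = %.2g\n",
            fz$z, fz$p))

tcp <- pfs_swr_coupling(pairs, "post", x = "theta_cofire_r")
cat(sprintf("theta co-firing vs POST SWR correlation: r = %.3f, p = %.2g\n",
            tcp$r, tcp$p))

pc <- plasticity_curve(pairs, "n_cofire_cycles")
utils::write.table(format(pc$table, digits = 4),
                   "results/plasticity_curve.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("smallest co-firing bin with positive significant plasticity: %s\n",
            ifelse(is.na(pc$smallest_significant_bin), "none",
                   pc$smallest_significant_bin)))
cat("wrote results/pair_table.tsv, results/plasticity_curve.tsv\n")
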