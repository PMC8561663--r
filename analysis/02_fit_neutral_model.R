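#!/usr/bin/env Rscript
# Fit the Dirichlet-multinomial neutral sampling model to each lineage's
# count table by maximum likelihood and tabulate pi (expected relative
# abundances), theta (overdispersion), and the log-likelihood.

suppressPackageStartupMessages(library(nemacomm))

files <- Sys.glob("results/synthetic_*.csv")
files <- files[!grepl("interacting", files)]
stopifnot(length(files) > 0)  # run 01_simulate_communities.R first

rows <- list()
for (f in files) {
  m <- read_count_table(f)
  fit <- suppressWarnings(fit_dmn(m))
  cat("\n==", unique(m$lineage), "==\n")
  print(fit)
  rows[[f]] <- data.frame(
    lineage = unique(m$lineage), n_hosts = fit$n_hosts,
    t(round(fit$pi, 4)), theta = round(fit$theta, 4),
    se_theta = round(fit$se_theta, 4), loglik = fit$loglik,
    converged = fit$converged, check.names = FALSE
  )
}
# species columns can differ (daf-2 lacks MYb181); align before binding
all_cols <- Reduce(union, lapply(rows, names))
rows <- lapply(rows, function(r) { r[setdiff(all_cols, names(r))] <- NA; r[all_cols] })
tab <- do.call(rbind, rows)
rownames(tab) <- NULL
write.csv(tab, "results/dmn_fits.csv", row.names = FALSE)
cat("\nwrote results/dmn_fits.csv\n")
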