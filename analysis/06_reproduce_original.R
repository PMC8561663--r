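#!/usr/bin/env Rscript
# Reproduction against the original per-host CFU tables, when available.
# The original data are distributed as a supplementary XLSX workbook that
# cannot be bundled here. To run this script, convert it to the package's
# table layout (columns: host_id, lineage, then one column per species)
# and save it as inst/extdata/community_composition_original.csv (or pass
# a path as the first argument). XLSX input also works via
# read_count_table(path, format = "xlsx") given the same layout.

suppressPackageStartupMessages(library(nemacomm))

path <- commandArgs(trailingOnly = TRUE)[1L]
if (is.na(path)) {
  path <- system.file("extdata", "community_composition_original.csv",
                      package = "nemacomm")
}
if (!nzchar(path) || !file.exists(path)) {
  stop("original data set not found; see the header of this script")
}

m_all <- read_count_table(path)
pol <- lineage_filter_policy(c("daf-2" = 100), default_min_total = 1000)
m_all <- filter_low_count_hosts(m_all, pol)

for (lin in intersect(c("N2", "daf-16", "daf-2"), unique(m_all$lineage))) {
  m <- subset_community(m_all, hosts = m_all$lineage == lin)
  fit <- suppressWarnings(fit_dmn(m))
  cat("\n==", lin, "==\n")
  print(fit)
  res <- suppressWarnings(neutral_correlation_test(m, B = 10000L, seed = 7L,
                                                   fit = fit))
  print(res)
  print(diversity_size_fit(m))
}

if (all(c("N2", "daf-16") %in% m_all$lineage)) {
  n2 <- subset_community(m_all, hosts = m_all$lineage == "N2")
  d16 <- subset_community(m_all, hosts = m_all$lineage == "daf-16")
  cat("\nLRT daf-16 vs N2: ")
  print(diversity_size_lrt(d16, n2))
}

d <- bray_curtis(log_standardize(m_all, "none"))
print(anosim_test(d, m_all$lineage, n_perm = 9999L, seed = 7L))
print(permanova_test(d, m_all$lineage, n_perm = 999L, seed = 7L))
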