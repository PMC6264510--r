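#!/usr/bin/env Rscript
# Reproduction of the published field results. Requires the study's
# supplementary band matrices plus web/stratum metadata, which are not
# redistributed here. Place them under data-raw/field/ as
#   <species>_matrix.csv  (read_binary_matrix dialect)
#   <species>_meta.csv    (read_metadata columns)
# for species stems: miniaceus, fissifrons, fasciatus, trigonum.

library(kleptopop)

field_dir <- "data-raw/field"
species <- data.frame(
  stem = c("miniaceus", "fissifrons", "fasciatus", "trigonum"),
  n_webs = c(13, 14, 10, 11),
  stringsAsFactors = FALSE
)
mat_paths <- file.path(field_dir, paste0(species$stem, "_matrix.csv"))
if (!all(file.exists(mat_paths))) {
  cat("field data not found under", field_dir, "- nothing to do.\n")
  cat("Expected files:\n")
  cat(paste(" ", mat_paths, collapse = "\n"), "\n")
  quit(save = "no", status = 0)
}

dir.create("results/field", showWarnings = FALSE, recursive = TRUE)
seed <- 20181129L

for (i in seq_len(nrow(species))) {
  sp <- species$stem[i]
  cat("==", sp, "\n")
  m <- read_binary_matrix(file.path(field_dir, paste0(sp, "_matrix.csv")))
  cat(sprintf("   %d individuals x %d loci\n", nrow(m), ncol(m)))
  d <- jaccard_dissimilarity(m)
  ord <- suppressWarnings(nmds(d, k = 3, max_starts = 1000,
                               seed = derive_seed(seed, paste0("nmds_", sp))))
  cat(sprintf("   NMDS stress = %.3f\n", ord$stress))
  for (link in c("average", "complete", "single", "ward")) {
    sil <- optimal_clusters(d, C_max = species$n_webs[i], linkage = link)
    cat(sprintf("   optimal C (%s linkage) = %d\n", link, sil$optimal_C))
  }

  meta_path <- file.path(field_dir, paste0(sp, "_meta.csv"))
  if (!file.exists(meta_path)) {
    cat("   no metadata; skipping autocorrelation/relatedness/admixture\n")
    next
  }
  meta <- read_metadata(meta_path)
  fw <- filter_webs(m, meta, min_size = 2)
  cg <- correlogram(fw$matrix, fw$meta,
                    bounds = c(1, 5, 10, 25, 50, 100, 250, 500, 1000),
                    n_boot = 1000, n_perm = 999,
                    seed = derive_seed(seed, paste0("cg_", sp)))
  cat(sprintf("   same-web r = %.3f%s\n", cg$r[1],
              if (cg$significant[1]) " (significant)" else ""))
  utils::write.table(as.data.frame(cg),
                     sprintf("results/field/%s_correlogram.tsv", sp),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  rel <- group_relatedness_test(m, meta, n_perm = 999, n_boot = 1000,
                                seed = derive_seed(seed, paste0("rel_", sp)))
  utils::write.table(as.data.frame(rel),
                     sprintf("results/field/%s_relatedness.tsv", sp),
                     sep = "\t", row.names = FALSE, quote = FALSE)

  sc <- admixture_scan(m, K_range = 1:(species$n_webs[i] + 2), n_reps = 10,
                       seed = derive_seed(seed, paste0("adm_", sp)),
                       burn_in = 10000, n_iter = 20000)
  cat(sprintf("   delta-K optimal K = %d\n", sc$delta_k$optimal_K))
  utils::write.table(sc$delta_k$table,
                     sprintf("results/field/%s_delta_k.tsv", sp),
                     sep = "\t", row.names = FALSE, quote = FALSE)
}
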