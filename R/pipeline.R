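#' Derive a stage-specific child seed from a global seed
#'
#' A cheap splitmix-style integer hash so that every pipeline stage gets
#' its own reproducible RNG stream and can be rerun independently.
#'
#' @param seed global integer seed.
#' @param stage stage label.
#' @return an integer in \[0, 2^31).
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 9973 + 12345) %% 2147483647)
}

#' Default analysis configuration
#'
#' @param matrix_path,meta_path input CSV paths (may be `NULL` when a
#'   matrix and metadata are passed to [run_full_analysis()] directly).
#' @param seed global seed.
#' @param bounds autocorrelation distance-class upper bounds, meters.
#' @param C_max silhouette scan upper limit (default: number of webs).
#' @param linkage clustering linkage.
#' @param nmds_dims,nmds_starts NMDS dimensionality and random starts.
#' @param K_range,admix_reps,admix_burn_in,admix_iter admixture scan
#'   settings (default K range: 1 to webs + 2).
#' @param n_perm,n_boot permutation and bootstrap counts.
#' @param strata list of stratum selectors to run the autocorrelation and
#'   relatedness analyses on, in addition to "all".
#' @param run_admixture run the (comparatively slow) admixture scan?
#' @return a named list of class `"analysis_config"`.
#' @export
analysis_config <- function(matrix_path = NULL, meta_path = NULL, seed = 1L,
                            bounds = c(1, 5, 10, 25, 50, 100, 250, 500, 1000),
                            C_max = NULL, linkage = "average",
                            nmds_dims = 3, nmds_starts = 100,
                            K_range = NULL, admix_reps = 3,
                            admix_burn_in = 1000, admix_iter = 2000,
                            n_perm = 999, n_boot = 1000,
                            strata = list(), run_admixture = TRUE) {
  structure(list(matrix_path = matrix_path, meta_path = meta_path,
                 seed = as.integer(seed), bounds = bounds, C_max = C_max,
                 linkage = linkage, nmds_dims = nmds_dims,
                 nmds_starts = nmds_starts, K_range = K_range,
                 admix_reps = admix_reps, admix_burn_in = admix_burn_in,
                 admix_iter = admix_iter, n_perm = n_perm, n_boot = n_boot,
                 strata = strata, run_admixture = run_admixture),
            class = "analysis_config")
}

#' Run the full population-structure analysis
#'
#' Orchestrates every stage on one dataset: polymorphism and web
#' filtering, Jaccard dissimilarity, 3-D NMDS, average-silhouette cluster
#' number, the admixture scan with delta-K, per-web relatedness tests,
#' and the spatial autocorrelation correlogram (overall and per stratum).
#' Every stage draws its seed from the global seed via [derive_seed()],
#' so the whole run is reproducible and stages can be rerun alone.
#'
#' @param cfg an [analysis_config()].
#' @param m,meta a [marker_matrix()] and metadata; read from
#'   `cfg$matrix_path` / `cfg$meta_path` when missing.
#' @param out_dir optional output directory; when given, per-stage TSV/CSV
#'   tables and a `summary.json` are written.
#' @return list of class `"analysis_report"` with per-stage results and a
#'   `summary` list (stress, optimal C, optimal K, per-web relatedness
#'   flags, per-class autocorrelation significance, echoed config).
#' @export
run_full_analysis <- function(cfg, m = NULL, meta = NULL, out_dir = NULL) {
  stopifnot(inherits(cfg, "analysis_config"))
  if (is.null(m)) m <- read_binary_matrix(cfg$matrix_path)
  if (is.null(meta)) meta <- read_metadata(cfg$meta_path)
  validate_metadata(meta, m)

  m <- filter_loci(m)
  meta <- meta[meta$individual_id %in% rownames(m), , drop = FALSE]
  fw <- filter_webs(m, meta, min_size = 2L)
  m <- fw$matrix; meta <- fw$meta
  filter_report <- attr(m, "filter_report")
  n_webs <- length(unique(meta$web_id))

  diss <- jaccard_dissimilarity(m)
  ord <- nmds(diss, k = cfg$nmds_dims, max_starts = cfg$nmds_starts,
              seed = derive_seed(cfg$seed, "nmds"))

  C_max <- if (is.null(cfg$C_max)) n_webs else cfg$C_max
  sil <- optimal_clusters(diss, C_max = C_max, linkage = cfg$linkage)

  admix <- NULL
  if (isTRUE(cfg$run_admixture)) {
    K_range <- if (is.null(cfg$K_range)) seq_len(min(n_webs + 2, nrow(m) - 1))
               else cfg$K_range
    admix <- admixture_scan(m, K_range, n_reps = cfg$admix_reps,
                            seed = derive_seed(cfg$seed, "admixture"),
                            burn_in = cfg$admix_burn_in,
                            n_iter = cfg$admix_iter)
  }

  relat <- group_relatedness_test(m, meta, n_perm = cfg$n_perm,
                                  n_boot = cfg$n_boot,
                                  seed = derive_seed(cfg$seed, "relatedness"))

  strata <- c(list(all = "all"), cfg$strata)
  if (is.null(names(strata)) || any(names(strata) == "")) {
    names(strata) <- vapply(strata, function(s)
      if (is.character(s)) s else "custom", character(1))
  }
  correlograms <- list()
  for (s in names(strata)) {
    cg <- tryCatch(
      correlogram(m, meta, bounds = cfg$bounds, n_boot = cfg$n_boot,
                  n_perm = cfg$n_perm,
                  seed = derive_seed(cfg$seed, paste0("autocorr_", s)),
                  stratum = if (identical(strata[[s]], "all")) NULL
                            else strata[[s]]),
      error = function(e) e)
    correlograms[[s]] <- cg
  }

  summary <- list(
    n_individuals = nrow(m), n_loci = ncol(m), n_webs = n_webs,
    nmds_stress = ord$stress,
    optimal_C = sil$optimal_C,
    optimal_K = if (!is.null(admix)) admix$delta_k$optimal_K else NA,
    relatedness_flags = stats::setNames(relat$flag, relat$web_id),
    autocorr_significant = lapply(correlograms, function(cg) {
      if (inherits(cg, "error")) cg$message else
        stats::setNames(cg$significant, cg$upper_bound_m)
    }),
    config = unclass(cfg)
  )

  report <- structure(list(matrix = m, meta = meta,
                           filter_report = filter_report,
                           dissimilarity = diss, nmds = ord,
                           silhouette = sil, admixture = admix,
                           relatedness = relat,
                           correlograms = correlograms,
                           summary = summary),
                      class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an analysis report bundle to disk
#'
#' Plain-text tables per stage plus a top-level `summary.json`.
#'
#' @param report an `"analysis_report"`.
#' @param out_dir output directory, created if needed.
#' @return invisibly, the output directory.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  write_marker_matrix(report$matrix, fp("filtered_matrix.csv"),
                      fp("filter_report.json"))
  utils::write.csv(report$meta, fp("metadata.csv"), row.names = FALSE)
  coords <- data.frame(individual_id = rownames(report$nmds$config),
                       report$nmds$config)
  utils::write.table(coords, fp("nmds_coords.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(report$silhouette$profile, fp("silhouette_profile.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(individual_id = names(report$silhouette$labels),
                              cluster = report$silhouette$labels),
                   fp("cluster_labels.csv"), row.names = FALSE)
  if (!is.null(report$admixture)) {
    utils::write.table(report$admixture$delta_k$table, fp("delta_k.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    best_K <- report$admixture$delta_k$optimal_K
    if (!is.na(best_K)) {
      run <- report$admixture$runs[[paste0("K", best_K)]][[1]]
      utils::write.csv(data.frame(individual_id = rownames(run$Q), run$Q),
                       fp("ancestry_Q.csv"), row.names = FALSE)
    }
  }
  utils::write.table(as.data.frame(report$relatedness),
                     fp("relatedness.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (s in names(report$correlograms)) {
    cg <- report$correlograms[[s]]
    if (!inherits(cg, "error")) {
      utils::write.table(as.data.frame(cg),
                         fp(sprintf("correlogram_%s.tsv", s)), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  jsonlite::write_json(report$summary, fp("summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(out_dir)
}
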