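#' Construct and validate a binary marker matrix
#'
#' A marker matrix holds dominant band phenotypes: rows are individuals,
#' columns are loci, and every entry is 0 (band absent) or 1 (band present).
#' Dominance means a present band cannot distinguish a presence homozygote
#' from a heterozygote, so this is all the genotype information AFLP-style
#' fingerprinting provides.
#'
#' @param x numeric or integer matrix of 0/1 values.
#' @param individual_ids row labels; defaults to `rownames(x)`.
#' @param locus_ids column labels; defaults to `colnames(x)`.
#' @return an integer matrix of class `"marker_matrix"` with unique
#'   dimnames.
#' @export
marker_matrix <- function(x, individual_ids = rownames(x),
                          locus_ids = colnames(x)) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (is.null(individual_ids)) {
    individual_ids <- paste0("ind", seq_len(nrow(x)))
  }
  if (is.null(locus_ids)) {
    locus_ids <- paste0("locus", seq_len(ncol(x)))
  }
  if (length(individual_ids) != nrow(x)) {
    stop("length of 'individual_ids' (", length(individual_ids),
         ") does not match number of rows (", nrow(x), ")")
  }
  if (length(locus_ids) != ncol(x)) {
    stop("length of 'locus_ids' (", length(locus_ids),
         ") does not match number of columns (", ncol(x), ")")
  }
  if (anyDuplicated(individual_ids)) {
    stop("duplicate individual ids: ",
         paste(unique(individual_ids[duplicated(individual_ids)]),
               collapse = ", "))
  }
  if (anyDuplicated(locus_ids)) {
    stop("duplicate locus ids: ",
         paste(unique(locus_ids[duplicated(locus_ids)]), collapse = ", "))
  }
  bad <- which(!(x %in% c(0, 1)) | is.na(x))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(x)) + 1
    j <- ((bad[1] - 1) %/% nrow(x)) + 1
    stop("non-binary cell at individual '", individual_ids[i],
         "', locus '", locus_ids[j], "': ", x[i, j])
  }
  storage.mode(x) <- "integer"
  dimnames(x) <- list(individual_ids, locus_ids)
  class(x) <- c("marker_matrix", class(x))
  x
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat("Binary marker matrix:", nrow(x), "individuals x", ncol(x), "loci\n")
  cat("Band presence rate:",
      format(mean(x), digits = 3), "\n")
  rep <- attr(x, "filter_report")
  if (!is.null(rep)) {
    cat("Filtered:", rep$n_loci_dropped, "loci and",
        rep$n_individuals_dropped, "individuals dropped\n")
  }
  invisible(x)
}

#' Read a binary marker matrix from CSV
#'
#' Expects a header row of locus ids and a first column of individual ids
#' (the layout used for raw AFLP band tables); every remaining cell must
#' parse to 0 or 1.
#'
#' @param path CSV file path.
#' @param sep field separator, default comma.
#' @param id_col column index carrying individual ids.
#' @return a validated [marker_matrix()] preserving file order.
#' @export
read_binary_matrix <- function(path, sep = ",", id_col = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, colClasses = "character",
                          stringsAsFactors = FALSE)
  ids <- df[[id_col]]
  vals <- df[, -id_col, drop = FALSE]
  loci <- colnames(vals)
  m <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(vals))))
  if (nrow(vals) == 1L) m <- matrix(m, nrow = 1L)
  bad <- which(is.na(m) | !(m %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(m)) + 1
    j <- ((bad[1] - 1) %/% nrow(m)) + 1
    stop("cell at row '", ids[i], "', column '", loci[j],
         "' is not 0/1: '", vals[i, j], "'")
  }
  marker_matrix(m, individual_ids = ids, locus_ids = loci)
}

#' Read per-individual metadata
#'
#' Metadata columns: `individual_id`, `web_id`, `age_class`
#' (instar1..instar4, adult, unknown), `sex` (male/female/unknown) and
#' either `easting`/`northing` in meters or `lat`/`lon` in degrees (in
#' which case coordinates are projected with [to_planar()]).
#'
#' @param path CSV file path.
#' @return a data.frame with planar coordinates.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("individual_id", "web_id", "age_class", "sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "))
  if (!all(c("easting", "northing") %in% names(df))) {
    if (!all(c("lat", "lon") %in% names(df))) {
      stop("metadata must carry easting/northing or lat/lon")
    }
    pl <- to_planar(df$lat, df$lon)
    df$easting <- pl$easting
    df$northing <- pl$northing
  }
  validate_metadata(df)
  df
}

#' Validate metadata against an optional marker matrix
#'
#' Checks id uniqueness, coordinate finiteness, one-position-per-web, legal
#' age/sex levels, and (if `m` is given) a one-to-one match between matrix
#' rows and metadata rows.
#'
#' @param meta metadata data.frame.
#' @param m optional [marker_matrix()].
#' @return `meta`, invisibly.
#' @export
validate_metadata <- function(meta, m = NULL) {
  if (anyDuplicated(meta$individual_id)) {
    stop("duplicate individual_id in metadata")
  }
  ages <- c("instar1", "instar2", "instar3", "instar4", "adult", "unknown")
  if (!all(meta$age_class %in% ages)) {
    stop("age_class must be one of: ", paste(ages, collapse = ", "))
  }
  if (!all(meta$sex %in% c("male", "female", "unknown"))) {
    stop("sex must be male, female or unknown")
  }
  if (!all(is.finite(meta$easting)) || !all(is.finite(meta$northing))) {
    stop("non-finite coordinates for: ",
         paste(meta$individual_id[!is.finite(meta$easting) |
                                  !is.finite(meta$northing)],
               collapse = ", "))
  }
  # a web is a single host structure with one GPS fix
  pos <- unique(meta[, c("web_id", "easting", "northing")])
  if (anyDuplicated(pos$web_id)) {
    stop("webs with more than one coordinate: ",
         paste(unique(pos$web_id[duplicated(pos$web_id)]), collapse = ", "))
  }
  if (!is.null(m)) {
    if (!setequal(rownames(m), meta$individual_id)) {
      stop("metadata individuals do not match marker matrix rows")
    }
  }
  invisible(meta)
}

#' Filter loci by polymorphism and drop bandless individuals
#'
#' Retains exactly the loci whose presence count `c` satisfies
#' `2 <= c <= n - 2`: invariant loci carry no information, and singleton
#' loci (a band seen in only one individual, or missing from only one) are
#' indistinguishable from scoring artefacts. Individuals left with no bands
#' at all after locus filtering are dropped by default, since every
#' downstream dissimilarity is undefined on an empty profile.
#'
#' @param m a [marker_matrix()].
#' @param drop_empty_individuals drop all-zero profiles after filtering?
#' @return filtered `marker_matrix` with a `filter_report` attribute
#'   (counts of dropped loci and individuals per rule).
#' @export
filter_loci <- function(m, drop_empty_individuals = TRUE) {
  n <- nrow(m)
  cnt <- colSums(m)
  keep <- cnt >= 2 & cnt <= n - 2
  if (!any(keep)) {
    stop("no loci left after polymorphism filtering (all invariant or singleton)")
  }
  out <- m[, keep, drop = FALSE]
  n_dropped_ind <- 0L
  dropped_ind <- character(0)
  if (drop_empty_individuals) {
    empty <- rowSums(out) == 0
    if (any(empty)) {
      dropped_ind <- rownames(out)[empty]
      out <- out[!empty, , drop = FALSE]
      n_dropped_ind <- sum(empty)
      # counts can shift after individuals leave; re-filter until stable
      return_rep <- TRUE
      repeat {
        cnt2 <- colSums(out)
        keep2 <- cnt2 >= 2 & cnt2 <= nrow(out) - 2
        if (all(keep2)) break
        if (!any(keep2)) stop("no loci left after polymorphism filtering")
        out <- out[, keep2, drop = FALSE]
        empty2 <- rowSums(out) == 0
        if (any(empty2)) {
          dropped_ind <- c(dropped_ind, rownames(out)[empty2])
          out <- out[!empty2, , drop = FALSE]
          n_dropped_ind <- n_dropped_ind + sum(empty2)
        }
      }
    }
  }
  res <- marker_matrix(unclass(out))
  attr(res, "filter_report") <- list(
    n_loci_in = ncol(m),
    n_loci_retained = ncol(res),
    n_loci_dropped = ncol(m) - ncol(res),
    n_individuals_in = n,
    n_individuals_retained = nrow(res),
    n_individuals_dropped = n_dropped_ind,
    dropped_individuals = dropped_ind
  )
  res
}

#' Remove individuals from under-sampled webs
#'
#' Population-genetic comparisons of web-mates need at least two members
#' per web; the permutation relatedness test needs at least three.
#'
#' @param m a [marker_matrix()].
#' @param meta metadata data.frame.
#' @param min_size minimum web size kept (>= 1).
#' @return list with elements `matrix` and `meta`, both restricted to
#'   individuals of webs with at least `min_size` members.
#' @export
filter_webs <- function(m, meta, min_size = 2L) {
  if (min_size < 1) stop("min_size must be >= 1")
  meta <- meta[match(rownames(m), meta$individual_id), , drop = FALSE]
  sz <- table(meta$web_id)
  keep_webs <- names(sz)[sz >= min_size]
  keep <- meta$web_id %in% keep_webs
  if (!any(keep)) warning("no individuals left after web-size filtering")
  list(matrix = m[keep, , drop = FALSE],
       meta = meta[keep, , drop = FALSE])
}

#' Select individuals by age/sex stratum
#'
#' The field strata are: juveniles (instars 1-3, sex usually not scorable),
#' sub-adult and adult females, and sub-adult and adult males; solitary or
#' small samples pool the sexes ("adults" = instar 4 + adult of either
#' sex). Instar 4 is treated as sub-adult: genitalia are distinguishable
#' but undifferentiated.
#'
#' @param meta metadata data.frame.
#' @param selector one of "all", "juveniles", "females", "males", "adults",
#'   or a predicate `function(meta)` returning a logical vector.
#' @param juvenile_instars age classes counted as juvenile (configurable
#'   mapping; default instars 1-3).
#' @return character vector of individual ids (possibly empty, with a
#'   warning).
#' @export
stratify <- function(meta, selector = "all",
                     juvenile_instars = c("instar1", "instar2", "instar3")) {
  older <- setdiff(c("instar1", "instar2", "instar3", "instar4", "adult"),
                   juvenile_instars)
  keep <- if (is.function(selector)) {
    selector(meta)
  } else {
    switch(selector,
      all = rep(TRUE, nrow(meta)),
      juveniles = meta$age_class %in% juvenile_instars,
      females = meta$age_class %in% older & meta$sex == "female",
      males = meta$age_class %in% older & meta$sex == "male",
      adults = meta$age_class %in% older,
      stop("unknown stratum selector: ", selector))
  }
  ids <- meta$individual_id[keep]
  if (!length(ids)) warning("stratum '", if (is.function(selector)) "<function>"
                            else selector, "' selected no individuals")
  ids
}

#' Pairwise planar geographic distances
#'
#' Euclidean distance in meters on the projected coordinates; all members
#' of one web share a position, so same-web pairs are at distance zero.
#'
#' @param meta metadata data.frame with `easting`/`northing` in meters.
#' @return symmetric n x n matrix of distances with individual ids as
#'   dimnames.
#' @export
geo_distance_matrix <- function(meta) {
  miss <- !is.finite(meta$easting) | !is.finite(meta$northing)
  if (any(miss)) {
    stop("missing coordinates for: ",
         paste(meta$individual_id[miss], collapse = ", "))
  }
  d <- as.matrix(stats::dist(cbind(meta$easting, meta$northing)))
  dimnames(d) <- list(meta$individual_id, meta$individual_id)
  d
}

#' Write a filtered matrix and its filter report
#'
#' @param m a filtered [marker_matrix()].
#' @param matrix_path output CSV path.
#' @param report_path optional JSON path for the filter report.
#' @return invisibly, the paths written.
#' @export
write_marker_matrix <- function(m, matrix_path, report_path = NULL) {
  df <- data.frame(individual_id = rownames(m), unclass(m),
                   check.names = FALSE)
  utils::write.csv(df, matrix_path, row.names = FALSE, quote = FALSE)
  if (!is.null(report_path)) {
    rep <- attr(m, "filter_report")
    if (is.null(rep)) rep <- list(note = "matrix not produced by filter_loci")
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(c(matrix_path, report_path))
}
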