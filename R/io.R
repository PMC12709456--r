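# File I/O (TSV everywhere), motion scrubbing, and pipeline orchestration.

#' Write a parcellated time-series matrix as TSV
#'
#' Columns are regions (header row of region IDs), rows are timepoints;
#' full double precision is preserved.
#'
#' @param ts regions x timepoints matrix; rownames used as region IDs
#'   (default R1..RN).
#' @param path output file.
#' @export
write_timeseries <- function(ts, path) {
  if (is.null(rownames(ts))) rownames(ts) <- paste0("R", seq_len(nrow(ts)))
  df <- as.data.frame(t(ts))
  write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a parcellated time-series TSV
#'
#' Expects a header row of region IDs and one row per timepoint (the
#' orientation written by [write_timeseries()]).
#'
#' @param path TSV file.
#' @return regions x timepoints matrix with region IDs as rownames.
#' @export
read_timeseries <- function(path) {
  first <- readLines(path, n = 1)
  ids <- strsplit(first, "\t", fixed = TRUE)[[1]]
  if (any(!is.na(suppressWarnings(as.numeric(ids)))))
    stop("missing header of region IDs in ", path)
  if (anyDuplicated(ids)) stop("duplicated region IDs in ", path)
  df <- read.delim(path, check.names = FALSE)
  m <- t(as.matrix(df))
  if (!is.numeric(m)) stop("non-numeric or ragged rows in ", path)
  m
}

# Square-matrix TSV helpers (region IDs as header, no row names).
write_matrix_tsv <- function(M, path) {
  colnames(M) <- if (is.null(colnames(M))) paste0("R", seq_len(ncol(M)))
    else colnames(M)
  write.table(format(as.data.frame(M), digits = 17, trim = TRUE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path) {
  as.matrix(read.delim(path, check.names = FALSE))
}

#' Scrub high-motion volumes and apply the minimum-length rule
#'
#' Removes volumes whose framewise displacement exceeds \code{fd_thresh}
#' (mm) or whose standardized DVARS exceeds \code{dvars_thresh}; subjects
#' left with fewer than \code{min_timepoints} volumes are flagged for
#' exclusion.
#'
#' @param ts regions x timepoints matrix.
#' @param fd per-volume framewise displacement (mm).
#' @param dvars per-volume standardized DVARS.
#' @param fd_thresh,dvars_thresh,min_timepoints QC thresholds.
#' @return list with \code{ts} (scrubbed matrix or NULL when excluded),
#'   \code{excluded} flag, \code{n_kept}, \code{n_flagged}.
#' @export
apply_scrubbing <- function(ts, fd, dvars, fd_thresh = 0.5,
                            dvars_thresh = 3, min_timepoints = 150) {
  if (length(fd) != ncol(ts) || length(dvars) != ncol(ts))
    stop("confound length (", length(fd), ", ", length(dvars),
         ") does not match ", ncol(ts), " volumes")
  if (any(fd < 0)) stop("negative framewise displacement")
  bad <- fd > fd_thresh | dvars > dvars_thresh
  kept <- sum(!bad)
  if (kept < min_timepoints)
    return(list(ts = NULL, excluded = TRUE, n_kept = kept,
                n_flagged = sum(bad)))
  list(ts = ts[, !bad, drop = FALSE], excluded = FALSE, n_kept = kept,
       n_flagged = sum(bad))
}

#' Run the full synthetic-cohort pipeline in memory
#'
#' Orchestrates the stages in order: cohort generation, per-subject
#' empirical statistics, two-stage GEC fitting, hierarchy metrics,
#' multi-site harmonization of the regional trophic levels, and the
#' group-contrast permutation test on directedness. Intended for
#' moderate problem sizes; the analysis scripts wrap the same calls with
#' on-disk artifacts.
#'
#' @param config a [cohort_config()].
#' @param fit_cfg a [fit_config()].
#' @param out_dir optional directory; when given, stage outputs are
#'   written as TSV plus a JSON run manifest.
#' @return list with the cohort bundle, fits, hierarchy table, harmonized
#'   levels and the directedness group test.
#' @export
run_pipeline <- function(config = cohort_config(), fit_cfg = fit_config(),
                         out_dir = NULL) {
  bundle <- generate_cohort(config)
  stats_list <- lapply(bundle$timeseries, empirical_stats,
                       tau_trs = fit_cfg$tau_trs)
  mask <- (bundle$truth$network$coupling > 0 |
             t(bundle$truth$network$coupling) > 0) * 1
  omega <- estimate_node_frequencies(bundle$timeseries[[1]], config$TR)
  params <- hopf_params(a = rep(-0.02, config$n_regions), omega = omega,
                        sigma = 0.01)
  fits <- fit_cohort(stats_list, mask, params, fit_cfg,
                     tau_seconds = fit_cfg$tau_trs * config$TR)
  hier <- hierarchy_table(fits$subjects, bundle$network_map)
  meta <- bundle$metadata
  keep <- filter_unique_sites(meta)$kept
  cov_df <- meta[keep, c("age", "gender", "education"), drop = FALSE]
  cov_df$diagnosis <- meta$group[keep]
  cmb <- fit_combat(hier$levels[keep, , drop = FALSE], meta$site[keep],
                    cov_df)
  levels_h <- apply_combat(cmb, hier$levels[keep, , drop = FALSE],
                           meta$site[keep], cov_df)
  extremes <- meta$group %in% c("HCneg", "ADpos")
  test <- permutation_group_test(
    hier$global$directedness[extremes],
    droplevels(meta$group[extremes]),
    meta[extremes, c("age", "gender", "education")],
    n_perm = 5000, seed = config$seed)
  out <- list(bundle = bundle, fits = fits, hierarchy = hier,
              harmonized_levels = levels_h, directedness_test = test)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.table(hier$global, file.path(out_dir, "global_metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_matrix_tsv(hier$levels, file.path(out_dir, "trophic_levels.tsv"))
    jsonlite::write_json(
      list(config = unclass(config), fit_config = unclass(fit_cfg),
           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
           directedness_p = test$p_value),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Hierarchy metrics for a list of fitted GECs
#'
#' @param gec_list list of \code{gec_result} objects (or plain coupling
#'   matrices).
#' @param network_map optional region -> network assignment for network
#'   averages.
#' @return list with \code{levels} (subjects x regions), \code{global}
#'   (subject, F0, directedness, asymmetry), and \code{network_levels}
#'   when a mapping is given.
#' @export
hierarchy_table <- function(gec_list, network_map = NULL) {
  getC <- function(x) if (inherits(x, "gec_result")) x$coupling else x
  subjects <- names(gec_list)
  if (is.null(subjects)) subjects <- paste0("sub", seq_along(gec_list))
  H <- t(vapply(gec_list, function(x) trophic_levels(getC(x)),
                numeric(nrow(getC(gec_list[[1]])))))
  rownames(H) <- subjects
  glob <- do.call(rbind, lapply(gec_list, function(x) {
    C <- getC(x)
    f0 <- trophic_incoherence(C)
    data.frame(F0 = f0, directedness = 1 - f0,
               asymmetry = asymmetry_index(C))
  }))
  glob <- cbind(subject = subjects, glob)
  rownames(glob) <- NULL
  out <- list(levels = H, global = glob)
  if (!is.null(network_map)) {
    out$network_levels <- t(apply(H, 1, network_average,
                                  mapping = network_map))
  }
  out
}
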