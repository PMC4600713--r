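#' Rank a vector of regional values
#'
#' Ascending ranks `1..N`, ties receiving the mean of their rank range —
#' the normalization applied to every controllability diagnostic before
#' cross-subject comparison, since raw scales differ by orders of magnitude
#' across diagnostics and subjects.
#'
#' @param values finite numeric vector.
#' @return numeric rank vector (names preserved).
#' @export
rank_regions <- function(values) {
  if (any(!is.finite(values))) stop("non-finite values cannot be ranked")
  rank(values, ties.method = "average")
}

#' Average rank vectors across scans and subjects
#'
#' @param per_scan_ranks non-empty list of equal-length rank vectors (one
#'   per scan).
#' @return elementwise mean vector.
#' @export
aggregate_ranks <- function(per_scan_ranks) {
  if (length(per_scan_ranks) == 0) stop("no rank vectors supplied")
  len <- unique(lengths(per_scan_ranks))
  if (length(len) != 1) stop("rank vectors have unequal lengths")
  colMeans(do.call(rbind, per_scan_ranks))
}

#' Select control hubs
#'
#' The `k` regions with the largest aggregated value, in descending order.
#' Ties at the cutoff are broken by lexicographic region id, making the hub
#' set deterministic.
#'
#' @param agg_values named numeric vector of aggregated values per region.
#' @param k hub count (default 30).
#' @return character vector of hub region ids, length `min(k, N)`.
#' @export
select_control_hubs <- function(agg_values, k = 30) {
  if (is.null(names(agg_values))) stop("agg_values must be named by region")
  if (k < 1) stop("k must be >= 1")
  if (k > length(agg_values)) {
    warning("k exceeds the number of regions; returning all regions")
    k <- length(agg_values)
  }
  ord <- order(-agg_values, names(agg_values))
  names(agg_values)[ord][seq_len(k)]
}

#' Size-normalized cognitive-system enrichment of a hub set
#'
#' The raw fraction of hubs falling in system `c` is divided by the system
#' size `n_c`, so large systems get no free advantage in housing hubs, and
#' the normalized scores are rescaled to sum to 100 across systems.
#'
#' @param hubs character vector of hub region ids.
#' @param labels data.frame with columns `region_id`, `system` (every hub
#'   must be labelled).
#' @return data.frame per system: `system`, `n_regions`, `n_hubs`,
#'   `raw_pct` (100 * hub fraction), `norm_score` (raw fraction / n_c),
#'   `norm_pct` (normalized scores rescaled to sum to 100).
#' @export
system_enrichment <- function(hubs, labels) {
  stopifnot(is.data.frame(labels),
            all(c("region_id", "system") %in% names(labels)))
  sys_of <- stats::setNames(labels$system, labels$region_id)
  if (any(!hubs %in% names(sys_of)))
    stop("unlabelled hub region(s): ",
         paste(setdiff(hubs, names(sys_of)), collapse = ", "))
  systems <- unique(labels$system)
  n_c <- table(factor(labels$system, levels = systems))
  h_c <- table(factor(sys_of[hubs], levels = systems))
  raw <- as.numeric(h_c) / length(hubs)
  score <- raw / as.numeric(n_c)
  data.frame(system = systems,
             n_regions = as.integer(n_c),
             n_hubs = as.integer(h_c),
             raw_pct = 100 * raw,
             norm_score = score,
             norm_pct = 100 * score / sum(score),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Default hypothesis-driven system groups
#'
#' Default mode alone; the two cognitive control systems (frontoparietal +
#' cingulo-opercular); the two attention systems (ventral + dorsal).
#' @return named list of character vectors of system names.
#' @export
system_groups <- function() {
  list(default_mode = "default_mode",
       cognitive_control = c("frontoparietal", "cingulo_opercular"),
       attention = c("ventral_attention", "dorsal_attention"))
}

#' Mean controllability of hubs within system groups
#'
#' For each system group and each diagnostic: the mean aggregated
#' controllability over the group's hub members, plus the dispersion
#' (standard deviation) of the per-subject group-hub means.
#'
#' @param profiles tidy profile data.frame (one row per region x scan) as
#'   produced by [control_profile] / [read_profiles].
#' @param hubs_per_diagnostic named list: diagnostic column -> hub region
#'   ids.
#' @param labels region-system label data.frame.
#' @param groups named list of system groupings (default [system_groups]).
#' @return data.frame: `group`, `diagnostic`, `n_hub_members`, `mean_ctrl`,
#'   `sd_across_subjects`. Groups with no hub members are omitted with a
#'   warning.
#' @export
system_hub_means <- function(profiles, hubs_per_diagnostic, labels,
                             groups = system_groups()) {
  sys_of <- stats::setNames(labels$system, labels$region_id)
  out <- list()
  for (gname in names(groups)) {
    members <- labels$region_id[labels$system %in% groups[[gname]]]
    for (diag_col in names(hubs_per_diagnostic)) {
      gh <- intersect(hubs_per_diagnostic[[diag_col]], members)
      if (length(gh) == 0) {
        warning("no ", diag_col, " hubs in group '", gname, "'; row omitted")
        next
      }
      rows <- profiles[profiles$region_id %in% gh, ]
      per_subj <- tapply(rows[[diag_col]], rows$subject, mean)
      out[[length(out) + 1]] <- data.frame(
        group = gname, diagnostic = diag_col,
        n_hub_members = length(gh),
        mean_ctrl = mean(rows[[diag_col]]),
        sd_across_subjects = stats::sd(per_subj),
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Correlation between a controllability diagnostic and weighted degree
#'
#' Pearson correlation with its two-sided p-value. By default both vectors
#' are ranked first (the convention for cross-diagnostic comparability);
#' `ranked = FALSE` gives the raw-value correlation.
#'
#' @param ctrl_values,degree_values equal-length numeric vectors
#'   (length >= 3).
#' @param ranked rank both vectors before correlating (default TRUE).
#' @return list with elements `r` and `p`.
#' @export
degree_correlation <- function(ctrl_values, degree_values, ranked = TRUE) {
  if (length(ctrl_values) != length(degree_values))
    stop("length mismatch")
  if (length(ctrl_values) < 3) stop("need at least 3 observations")
  x <- if (ranked) rank_regions(ctrl_values) else ctrl_values
  y <- if (ranked) rank_regions(degree_values) else degree_values
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Cross-subject cohort analysis
#'
#' Runs the full rank-aggregation pipeline over a set of per-scan control
#' profiles: per-scan ranking of each diagnostic, averaging of ranks across
#' all scans and subjects, hub extraction (top `k` per diagnostic),
#' size-normalized system enrichment, group-wise hub means, and
#' ranked/raw correlations of each diagnostic with weighted degree.
#'
#' @param profiles tidy data.frame of per-scan profiles (rows =
#'   region x scan), with the diagnostic columns of [control_profile].
#' @param labels region-system label data.frame (`region_id`, `system`);
#'   NULL skips enrichment.
#' @param k hub count per diagnostic (default 30).
#' @param diagnostics profile columns to aggregate.
#' @return object of class `cohort_result`: `mean_ranks` (data.frame,
#'   region x diagnostic), `hubs` (named list), `enrichment` (data.frame or
#'   NULL), `hub_means` (data.frame or NULL), `correlations` (data.frame:
#'   diagnostic, r_ranked, p_ranked, r_raw, p_raw), `k`.
#' @export
cohort_analysis <- function(profiles, labels = NULL, k = 30,
                            diagnostics = c("avg_ctrl", "modal_ctrl",
                                            "boundary_ctrl")) {
  stopifnot(is.data.frame(profiles), "region_id" %in% names(profiles))
  missing_cols <- setdiff(diagnostics, names(profiles))
  if (length(missing_cols))
    stop("profiles lack columns: ", paste(missing_cols, collapse = ", "))
  scan_id <- interaction(profiles$subject, profiles$scan, drop = TRUE)
  scans <- split(profiles, scan_id)
  regions <- sort(unique(profiles$region_id))
  mean_ranks <- data.frame(region_id = regions, stringsAsFactors = FALSE)
  per_scan_degree <- lapply(scans, function(df)
    rank_regions(stats::setNames(df$degree, df$region_id)[regions]))
  mean_ranks$degree <- unname(aggregate_ranks(per_scan_degree))
  hubs <- list()
  cors <- list()
  for (d in diagnostics) {
    per_scan <- lapply(scans, function(df)
      rank_regions(stats::setNames(df[[d]], df$region_id)[regions]))
    agg <- aggregate_ranks(per_scan)
    names(agg) <- regions
    mean_ranks[[d]] <- unname(agg)
    hubs[[d]] <- select_control_hubs(agg, k = k)
    rk <- degree_correlation(mean_ranks[[d]], mean_ranks$degree,
                             ranked = TRUE)
    # raw-value correlation on scan-averaged raw values
    raw_vals <- tapply(profiles[[d]], profiles$region_id, mean)[regions]
    raw_deg <- tapply(profiles$degree, profiles$region_id, mean)[regions]
    rr <- degree_correlation(as.numeric(raw_vals), as.numeric(raw_deg),
                             ranked = FALSE)
    cors[[d]] <- data.frame(diagnostic = d, r_ranked = rk$r, p_ranked = rk$p,
                            r_raw = rr$r, p_raw = rr$p,
                            stringsAsFactors = FALSE)
  }
  enrichment <- NULL
  hub_means <- NULL
  if (!is.null(labels)) {
    enr <- lapply(diagnostics, function(d) {
      e <- system_enrichment(hubs[[d]], labels)
      e$diagnostic <- d
      e
    })
    enrichment <- do.call(rbind, enr)
    hub_means <- system_hub_means(profiles, hubs, labels)
  }
  structure(list(mean_ranks = mean_ranks, hubs = hubs,
                 enrichment = enrichment, hub_means = hub_means,
                 correlations = do.call(rbind,
                                        c(cors, list(make.row.names = FALSE))),
                 k = k),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d regions, top-%d hubs per diagnostic\n",
              nrow(x$mean_ranks), x$k))
  print(x$correlations)
  invisible(x)
}
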