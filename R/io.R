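#' Read a connectome from disk
#'
#' Two plain-text formats are supported:
#'
#' * dense matrix CSV: header row of region ids, one numeric row per region
#'   (row order = header order);
#' * edge-list TSV with header `region_a`, `region_b`, `weight`, each
#'   undirected edge listed once (listing both orientations is accepted
#'   only when the weights agree; a conflict is an error).
#'
#' Asymmetric dense input beyond 1e-9 and negative weights are errors;
#' a nonzero diagonal is zeroed with a warning.
#'
#' @param path file path.
#' @param format `"auto"` (by extension: `.csv` dense, `.tsv` edge list),
#'   `"dense"` or `"edgelist"`.
#' @param subject,scan optional tags.
#' @return a [connectome].
#' @export
read_connectome <- function(path, format = c("auto", "dense", "edgelist"),
                            subject = NA_character_, scan = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "dense"
              else "edgelist"
  if (format == "dense") {
    df <- utils::read.csv(path, check.names = FALSE)
    A <- as.matrix(df)
    if (nrow(A) != ncol(A)) stop("dense matrix is not square")
    regions <- colnames(A)
    rownames(A) <- regions
    return(connectome(A, regions = regions, subject = subject, scan = scan))
  }
  el <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("region_a", "region_b", "weight")
  if (!all(need %in% names(el)))
    stop("edge list must have columns: ", paste(need, collapse = ", "))
  if (any(el$weight < 0)) stop("negative edge weights")
  if (any(el$region_a == el$region_b)) {
    warning("self-loop entries dropped")
    el <- el[el$region_a != el$region_b, ]
  }
  key <- paste(pmin(el$region_a, el$region_b),
               pmax(el$region_a, el$region_b))
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    w_by_key <- tapply(el$weight, key, function(w) length(unique(w)))
    if (any(w_by_key > 1))
      stop("conflicting duplicate edges: ",
           paste(names(w_by_key)[w_by_key > 1], collapse = "; "))
    el <- el[!duplicated(key), ]
  }
  regions <- unique(c(el$region_a, el$region_b))
  n <- length(regions)
  A <- matrix(0, n, n, dimnames = list(regions, regions))
  A[cbind(el$region_a, el$region_b)] <- el$weight
  A[cbind(el$region_b, el$region_a)] <- el$weight
  connectome(A, regions = regions, subject = subject, scan = scan)
}

#' Write a connectome to disk
#'
#' @param conn a [connectome].
#' @param path output path.
#' @param format `"dense"` (matrix CSV, header = region ids) or
#'   `"edgelist"` (TSV, each undirected edge once, positive weights only).
#' @return `path`, invisibly.
#' @export
write_connectome <- function(conn, path, format = c("dense", "edgelist")) {
  stopifnot(inherits(conn, "connectome"))
  format <- match.arg(format)
  if (format == "dense") {
    utils::write.csv(as.data.frame(conn$A, check.names = FALSE), path,
                     row.names = FALSE)
  } else {
    idx <- which(upper.tri(conn$A) & conn$A > 0, arr.ind = TRUE)
    el <- data.frame(region_a = conn$regions[idx[, 1]],
                     region_b = conn$regions[idx[, 2]],
                     weight = conn$A[idx], stringsAsFactors = FALSE)
    utils::write.table(el, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read / write region-system labels (TSV: region_id, system)
#'
#' @param path file path.
#' @return data.frame with columns `region_id`, `system`.
#' @export
read_system_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("region_id", "system") %in% names(df)))
    stop("label file must have columns region_id, system")
  df
}

#' @rdname read_system_labels
#' @param labels label data.frame.
#' @export
write_system_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write / read tidy control profiles (TSV)
#'
#' One row per region x subject x scan; columns `region_id`, `subject`,
#' `scan`, `avg_ctrl`, `modal_ctrl`, `boundary_ctrl`, `global_ctrl`,
#' `degree`. Numeric columns are serialized at full precision
#' (`digits = 17`) so a write/read round trip is exact.
#'
#' @param profiles profile data.frame ([control_profile] rows, possibly
#'   concatenated over scans).
#' @param path file path.
#' @return `path` (write) or the profile data.frame (read).
#' @export
write_profiles <- function(profiles, path) {
  cols <- c("region_id", "subject", "scan", "avg_ctrl", "modal_ctrl",
            "boundary_ctrl", "global_ctrl", "degree")
  missing_cols <- setdiff(cols, names(profiles))
  if (length(missing_cols))
    stop("profiles lack columns: ", paste(missing_cols, collapse = ", "))
  out <- profiles[, cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 17,
                                                  trim = TRUE,
                                                  scientific = NA))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(region_id = "character",
                                   subject = "character",
                                   scan = "character"))
}

# shared table writer for result TSVs (full numeric precision, no quoting)
write_result_table <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17, trim = TRUE,
                                                scientific = NA))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
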