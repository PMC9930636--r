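#' Construct a parcellated BOLD time-series object
#'
#' A `bold_ts` holds a regions-by-timepoints real matrix of parcellated BOLD
#' signals together with the sampling interval (TR). It is the raw input of
#' the whole stability pipeline: `N` regions (rows) sampled at `T` timepoints
#' (columns), typically an AAL-116 parcellation with T = 261 (rest,
#' sensorimotor task) or T = 193 (movie watching) at TR close to 2 s.
#'
#' @param values numeric matrix, regions x timepoints. Must be finite,
#'   with at least 2 regions and 8 timepoints.
#' @param tr_seconds positive sampling interval in seconds.
#' @param region_labels optional character vector of unique region names;
#'   defaults to `"ROI001"`, `"ROI002"`, ...
#' @param subject_id subject identifier string.
#' @param condition one of `"rest"`, `"movie"`, `"smt"`, `"synthetic"`.
#' @return An object of class `"bold_ts"`: a list with elements `values`,
#'   `tr_seconds`, `region_labels`, `subject_id`, `condition`.
#' @examples
#' ts <- bold_ts(matrix(rnorm(3 * 20), 3, 20), tr_seconds = 2)
#' ts
#' @export
bold_ts <- function(values, tr_seconds, region_labels = NULL,
                    subject_id = "subject", condition = "synthetic") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at region %d, timepoint %d",
                 bad[1], bad[2]), call. = FALSE)
  }
  if (nrow(values) < 2)
    stop("need at least 2 regions (rows)", call. = FALSE)
  if (ncol(values) < 8)
    stop("need at least 8 timepoints (columns)", call. = FALSE)
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1 || tr_seconds <= 0)
    stop("tr_seconds must be a positive scalar", call. = FALSE)
  if (is.null(region_labels))
    region_labels <- sprintf("ROI%03d", seq_len(nrow(values)))
  region_labels <- as.character(region_labels)
  if (length(region_labels) != nrow(values))
    stop("region_labels length must equal number of regions", call. = FALSE)
  if (anyDuplicated(region_labels))
    stop("region_labels must be unique", call. = FALSE)
  condition <- match.arg(condition, c("rest", "movie", "smt", "synthetic"))
  rownames(values) <- region_labels
  structure(
    list(values = values, tr_seconds = as.numeric(tr_seconds),
         region_labels = region_labels,
         subject_id = as.character(subject_id), condition = condition),
    class = "bold_ts")
}

#' @export
print.bold_ts <- function(x, ...) {
  cat(sprintf("<bold_ts> %s [%s]: %d regions x %d timepoints, TR = %g s\n",
              x$subject_id, x$condition, nrow(x$values), ncol(x$values),
              x$tr_seconds))
  invisible(x)
}

#' @export
dim.bold_ts <- function(x) dim(x$values)

#' Read a parcellated time series from delimited text
#'
#' Reads a CSV/TSV numeric matrix (optional single header row, auto-detected)
#' and orients it to regions x timepoints. The bundled convention is
#' regions-major on disk (one row per region, header row of region labels),
#' but `layout = "time_by_regions"` transposes on read for timepoint-major
#' files.
#'
#' @param path path to a delimited text file.
#' @param layout `"regions_by_time"` (default) or `"time_by_regions"`.
#' @param tr_seconds sampling interval in seconds.
#' @param sep field separator; `NULL` (default) auto-detects comma vs tab.
#' @param ... passed on to [bold_ts()] (e.g. `subject_id`, `condition`).
#' @return A [bold_ts()] object.
#' @export
read_timeseries <- function(path, layout = c("regions_by_time", "time_by_regions"),
                            tr_seconds, sep = NULL, ...) {
  layout <- match.arg(layout)
  if (!file.exists(path))
    stop(sprintf("time-series file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2)
    stop(sprintf("'%s': need at least 2 data rows", path), call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  split1 <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(split1)))
  header <- if (has_header) trimws(split1) else NULL
  data_lines <- if (has_header) lines[-1] else lines
  cells <- strsplit(data_lines, sep, fixed = TRUE)
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1) {
    bad <- which(ncols != ncols[1])[1]
    stop(sprintf("'%s': ragged row at data line %d (%d fields, expected %d)",
                 path, bad, ncols[bad], ncols[1]), call. = FALSE)
  }
  num <- suppressWarnings(vapply(cells, as.numeric, numeric(ncols[1])))
  if (ncols[1] == 1) num <- matrix(num, nrow = 1)
  # num is ncol x nrow here (vapply stacks by column); transpose to file shape
  mat <- t(num)
  if (anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("'%s': non-numeric or missing cell at data row %d, column %d",
                 path, bad[1], bad[2]), call. = FALSE)
  }
  labels <- NULL
  if (layout == "time_by_regions") {
    mat <- t(mat)
    if (has_header) labels <- header
  } else {
    # header of a regions-major file labels timepoints, or is a label column?
    # convention: header row carries region labels only when it matches rows
    if (has_header && length(header) == nrow(mat)) labels <- header
  }
  if (!is.null(labels) && anyDuplicated(labels)) labels <- NULL
  bold_ts(mat, tr_seconds = tr_seconds, region_labels = labels, ...)
}

#' Write / read a numeric matrix as delimited text
#'
#' Round-trip faithful to full double precision (17 significant digits).
#' Used for stability matrices and other result matrices.
#'
#' @param mat finite numeric matrix.
#' @param path file path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns a
#'   numeric matrix.
#' @export
write_matrix <- function(mat, path) {
  mat <- as.matrix(mat)
  if (!all(is.finite(mat)))
    stop("matrix has non-finite entries", call. = FALSE)
  txt <- apply(mat, 1, function(r) paste(formatC(r, format = "g", digits = 17),
                                         collapse = ","))
  ok <- tryCatch({ writeLines(txt, path); TRUE },
                 error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("failed writing matrix to '%s': %s", path,
                 conditionMessage(ok)), call. = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path))
    stop(sprintf("matrix file not found: '%s'", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncols <- lengths(cells)
  if (length(unique(ncols)) != 1)
    stop(sprintf("'%s': ragged rows", path), call. = FALSE)
  num <- suppressWarnings(vapply(cells, as.numeric, numeric(ncols[1])))
  if (ncols[1] == 1) num <- matrix(num, nrow = 1)
  mat <- t(num)
  if (anyNA(mat))
    stop(sprintf("'%s': non-numeric cell", path), call. = FALSE)
  mat
}

#' Define a named set of atlas regions (resting-state network)
#'
#' @param name network name, e.g. `"DMN"`, `"CEN"`, `"SM"`, `"salience"`,
#'   `"visual"`, `"whole_brain"` or any custom label.
#' @param region_indices 1-based atlas indices (AAL convention), unique,
#'   at least 4 of them (a k = 3 subspace needs >= 4 rows).
#' @param n_regions optional atlas size used to bound-check indices.
#' @return An object of class `"network_definition"`.
#' @export
network_definition <- function(name, region_indices, n_regions = NULL) {
  region_indices <- as.integer(region_indices)
  if (any(region_indices < 1))
    stop(sprintf("network '%s': indices are 1-based; got index < 1", name),
         call. = FALSE)
  if (anyDuplicated(region_indices))
    stop(sprintf("network '%s': duplicate region index", name), call. = FALSE)
  if (length(region_indices) < 4)
    stop(sprintf("network '%s': need at least 4 regions", name), call. = FALSE)
  if (!is.null(n_regions) && any(region_indices > n_regions))
    stop(sprintf("network '%s': index exceeds atlas size %d", name, n_regions),
         call. = FALSE)
  structure(list(name = as.character(name), region_indices = region_indices),
            class = "network_definition")
}

#' @export
print.network_definition <- function(x, ...) {
  cat(sprintf("<network_definition> %s: %d regions\n", x$name,
              length(x$region_indices)))
  invisible(x)
}

#' Read network definitions from JSON
#'
#' The file maps network names to arrays of 1-based atlas indices, e.g.
#' `{"SM": [1, 2, 19, 20, 57, 58]}`. Keys starting with `"_"` are treated as
#' comments and skipped. A bundled default for the 116-region AAL ordering is
#' shipped at `system.file("extdata", "aal116_networks.json",
#' package = "dfcstab")`; it is a documented reference *reconstruction* of
#' commonly used AAL memberships for DMN, CEN, SM, salience and visual
#' networks, intended to be edited for any given study.
#'
#' @param path JSON file path; defaults to the bundled AAL-116 file.
#' @param n_regions optional atlas size for bound checking.
#' @return Named list of [network_definition()] objects.
#' @export
read_network_definition <- function(path = system.file("extdata",
                                                       "aal116_networks.json",
                                                       package = "dfcstab"),
                                    n_regions = NULL) {
  if (!file.exists(path))
    stop(sprintf("network-definition file not found: '%s'", path),
         call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw <- raw[!startsWith(names(raw), "_")]
  out <- lapply(names(raw), function(nm)
    network_definition(nm, raw[[nm]], n_regions = n_regions))
  names(out) <- names(raw)
  out
}

#' Read a subject table
#'
#' CSV with columns `subject_id`, `age_years`, `condition`, `path`. One row
#' per subject/condition recording where that run's parcellated time series
#' lives on disk.
#'
#' @param path CSV file path.
#' @param age_range permitted age range (inclusive), default the adult
#'   lifespan 18-88 used throughout the lifespan analyses.
#' @return A data.frame with the four columns, `subject_id` as character.
#' @export
read_subject_table <- function(path, age_range = c(18, 88)) {
  if (!file.exists(path))
    stop(sprintf("subject table not found: '%s'", path), call. = FALSE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "age_years", "condition", "path")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("subject table missing column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  tab$subject_id <- as.character(tab$subject_id)
  tab$age_years <- as.numeric(tab$age_years)
  bad <- tab$age_years < age_range[1] | tab$age_years > age_range[2] |
    !is.finite(tab$age_years)
  if (any(bad))
    stop(sprintf("age out of [%g, %g] for subject(s): %s",
                 age_range[1], age_range[2],
                 paste(unique(tab$subject_id[bad]), collapse = ", ")),
         call. = FALSE)
  dup <- duplicated(tab[, c("subject_id", "condition")])
  if (any(dup))
    stop("duplicate (subject_id, condition) rows in subject table",
         call. = FALSE)
  tab
}
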