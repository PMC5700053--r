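detect_delimiter <- function(line) {
  if (grepl(",", line, fixed = TRUE)) "," else "\t| +"
}

parse_delimited_numeric <- function(path, what = "matrix") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)
  sep <- detect_delimiter(lines[1])
  cells <- lapply(lines, function(l) {
    x <- strsplit(trimws(l), sep)[[1]]
    x[nzchar(x)]
  })
  widths <- lengths(cells)
  # header row of labels?
  first_num <- suppressWarnings(as.numeric(cells[[1]]))
  has_header <- anyNA(first_num)
  labels <- NULL
  if (has_header) {
    labels <- cells[[1]]
    cells <- cells[-1]
    widths <- widths[-1]
    if (!length(cells)) stop("no data rows in ", path, call. = FALSE)
  }
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1])[1]
    stop(sprintf("ragged rows in %s: row %d has %d cells, expected %d",
                 path, bad + has_header, widths[bad], widths[1]), call. = FALSE)
  }
  # leading label column? (first cell non-numeric on data rows)
  row_labels <- NULL
  if (anyNA(suppressWarnings(as.numeric(vapply(cells, `[`, "", 1L))))) {
    row_labels <- vapply(cells, `[`, "", 1L)
    cells <- lapply(cells, `[`, -1L)
    if (!is.null(labels) && length(labels) == length(cells[[1]]) + 1L) {
      labels <- labels[-1L]
    }
  }
  m <- matrix(NA_real_, length(cells), length(cells[[1]]))
  for (i in seq_along(cells)) {
    v <- suppressWarnings(as.numeric(cells[[i]]))
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop(sprintf("non-numeric cell in %s at data row %d, column %d: '%s'",
                   path, i, j, cells[[i]][j]), call. = FALSE)
    }
    m[i, ] <- v
  }
  list(matrix = m, col_labels = labels, row_labels = row_labels)
}

#' Read a delimited multivariate time series
#'
#' Parses a plain-text delimited (comma or whitespace) matrix of node
#' signals, one row per time point, with an optional header row of node
#' labels. Malformed input (ragged rows, non-numeric cells) raises an error
#' naming the offending row and column.
#'
#' @param path File path.
#' @param transpose If `TRUE` the file is nodes x time and is transposed.
#' @return List with `values` (T x N numeric matrix, labelled columns) and
#'   `labels`.
#' @export
read_timeseries <- function(path, transpose = FALSE) {
  p <- parse_delimited_numeric(path)
  m <- p$matrix
  labels <- p$col_labels
  if (transpose) {
    m <- t(m)
    labels <- p$row_labels
  }
  if (nrow(m) < 2L) {
    stop("time series needs at least 2 samples (rows): ", path, call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("n", seq_len(ncol(m)))
  colnames(m) <- labels
  list(values = m, labels = labels)
}

#' Read a signed connectivity matrix from a delimited file
#'
#' @param path File path to a square delimited matrix, optional header
#'   row/column of labels; the sign of each entry carries the attitude.
#' @return A [signed_connectivity()] matrix.
#' @export
read_connectivity <- function(path) {
  p <- parse_delimited_numeric(path)
  labels <- p$col_labels
  if (is.null(labels)) labels <- p$row_labels
  signed_connectivity(p$matrix, labels = labels)
}

fmt_full <- function(x) {
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

#' Write a labelled numeric matrix as delimited text
#'
#' Values are written at full double precision, so
#' `read -> write -> read` round-trips exactly.
#'
#' @param m Numeric matrix (a [signed_connectivity()] works too).
#' @param path Output file path.
#' @param labels Column labels; defaults to the matrix's dimnames or
#'   `n1..nN`.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, labels = NULL, sep = ",") {
  m <- as.matrix(unclass(m))
  if (is.null(labels)) {
    labels <- colnames(m)
    if (is.null(labels)) labels <- paste0("n", seq_len(ncol(m)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(labels, collapse = sep), con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(fmt_full(m[i, ]), collapse = sep), con)
  }
  invisible(path)
}

#' Write a trajectory as a delimited time-series file
#'
#' @param traj An [trajectory()] object (or T x N matrix).
#' @param path Output file path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(traj, path, sep = ",") {
  m <- if (inherits(traj, "egnb_trajectory")) traj$states else as.matrix(traj)
  write_matrix(m, path, sep = sep)
}

run_config_defaults <- function() {
  list(dt = 3, delta = 0.05, ridge = 0, seed = 1L,
       solver = list(method = "rk4_fixed", step = NULL,
                     abs_tol = 1e-8, rel_tol = 1e-8, state_clip_eps = 1e-9))
}

#' Load and validate a JSON run configuration
#'
#' Known keys: `dt`, `delta`, `ridge`, `seed`, and a `solver` object with
#' the [solver_options()] fields. Missing keys take defaults; unknown keys
#' are rejected with a warning listing them.
#'
#' @param path Path to a JSON file (or `NULL` for the defaults).
#' @return A validated list of class `run_config` with a `solver_options`
#'   entry under `$solver`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    user <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      warning("ignoring unknown config key(s): ",
              paste(unknown, collapse = ", "), call. = FALSE)
      user <- user[setdiff(names(user), unknown)]
    }
    if (!is.null(user$solver)) {
      sunknown <- setdiff(names(user$solver), names(cfg$solver))
      if (length(sunknown)) {
        warning("ignoring unknown solver key(s): ",
                paste(sunknown, collapse = ", "), call. = FALSE)
      }
      cfg$solver <- utils::modifyList(cfg$solver,
                                      user$solver[setdiff(names(user$solver),
                                                          sunknown)])
      user$solver <- NULL
    }
    cfg <- utils::modifyList(cfg, user)
  }
  stopifnot(cfg$dt > 0, cfg$delta > 0, cfg$delta <= 0.25, cfg$ridge >= 0)
  cfg$solver <- solver_options(method = cfg$solver$method,
                               step = cfg$solver$step,
                               abs_tol = cfg$solver$abs_tol,
                               rel_tol = cfg$solver$rel_tol,
                               state_clip_eps = cfg$solver$state_clip_eps)
  class(cfg) <- "run_config"
  cfg
}

#' Write a JSON provenance record for a run
#'
#' @param path Output JSON path.
#' @param command Name of the command or analysis step.
#' @param params Named list of parameters actually used.
#' @return `path`, invisibly.
#' @export
write_provenance <- function(path, command, params) {
  rec <- list(command = command,
              package = "egnb",
              version = as.character(utils::packageVersion("egnb")),
              params = params)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
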