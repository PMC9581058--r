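#' Read TCSPC histograms from CSV
#'
#' Reads a CSV with a `time_ns` column (left bin edges, strictly increasing,
#' starting at 0) and one count column per molecule. Malformed rows are
#' reported with their line numbers.
#'
#' @param path CSV file path.
#' @param period Repetition period in ns. Defaults to `K * delta_t` implied
#'   by the time axis.
#' @return A list: `counts` (`J x K` matrix, one row per molecule), `grid`
#'   (the [tcspc_grid()]) and `names` (count column names).
#' @export
read_histograms <- function(path, period = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0 || ncol(df) < 2)
    stop("empty input: no histogram data in ", path, call. = FALSE)
  if (!"time_ns" %in% names(df))
    stop("format error: missing `time_ns` column in ", path, call. = FALSE)
  t <- df$time_ns
  bad <- which(!is.finite(t))
  if (length(bad))
    stop("format error: non-numeric time_ns at data line(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  dt <- diff(t)
  if (any(dt <= 0))
    stop("format error: time axis not strictly increasing at data line(s) ",
         paste(utils::head(which(dt <= 0) + 1, 5), collapse = ", "),
         call. = FALSE)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("format error: time bins are not equally spaced", call. = FALSE)
  cnt <- as.matrix(df[setdiff(names(df), "time_ns")])
  badc <- which(rowSums(!is.finite(cnt) | cnt < 0) > 0)
  if (length(badc))
    stop("format error: negative or non-numeric counts at data line(s) ",
         paste(utils::head(badc, 5), collapse = ", "), call. = FALSE)
  delta_t <- dt[1]
  K <- length(t)
  if (is.null(period)) period <- K * delta_t
  grid <- tcspc_grid(delta_t, period, K)
  list(counts = t(cnt), grid = grid,
       names = setdiff(names(df), "time_ns"))
}

#' Write TCSPC histograms to CSV
#'
#' Inverse of [read_histograms()]: writes a `time_ns` column plus one count
#' column per molecule; the round trip is lossless for integer counts.
#'
#' @param counts `J x K` matrix (or vector) of counts.
#' @param grid The [tcspc_grid()].
#' @param path Output CSV path.
#' @param names Optional column names for the molecules.
#' @export
write_histograms <- function(counts, grid, path, names = NULL) {
  if (is.vector(counts)) counts <- matrix(counts, nrow = 1)
  stopifnot(ncol(counts) == grid$K)
  if (is.null(names)) names <- paste0("m", seq_len(nrow(counts)))
  df <- data.frame(time_ns = grid$bin_start_times)
  for (i in seq_len(nrow(counts))) df[[names[i]]] <- counts[i, ]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

molecule_columns <- c("id", "x_nm", "y_nm", "psf_sigma_nm", "n_photons",
                      "tau_ns", "b", "red_chi2", "sigma_tau_ns")

#' Read or write a molecule table
#'
#' Molecule tables are CSV files with the columns `id`, `x_nm`, `y_nm`,
#' `psf_sigma_nm`, `n_photons`, `tau_ns`, `b`, `red_chi2`, `sigma_tau_ns`
#' (extra columns such as species labels and posteriors are preserved).
#'
#' @param path CSV file path.
#' @return `read_molecules()` returns a tibble.
#' @export
read_molecules <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tibble::as_tibble(utils::read.csv(path))
  missing <- setdiff(c("id", "n_photons"), names(df))
  if (length(missing))
    stop("format error: molecule table lacks column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' @rdname read_molecules
#' @param records Molecule tibble.
#' @export
write_molecules <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

# JSON run manifest (seed, package version, parameters) written next to an
# output file so that deterministic stages can be reproduced bit-identically.
write_manifest <- function(path, seed, params = list()) {
  manifest <- list(
    package = "flsmlm",
    version = as.character(utils::packageVersion("flsmlm")),
    seed = seed,
    params = params,
    written = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
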