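#' Read an allele-frequency time-series table
#'
#' Reads the package's TSV dialect: a header line \code{time<TAB>locus_0
#' <TAB>locus_1 ...} followed by one row per sampled time, frequencies as
#' decimal fractions in \[0, 1\]. The first locus column is taken as focal
#' unless \code{focal} names/indexes another column.
#'
#' @param path file path.
#' @param focal focal-locus column (index into the locus columns, or name).
#' @return a \code{"trajectory_set"} with the focal locus first.
#' @seealso [write_timeseries()]
#' @export
read_timeseries <- function(path, focal = 1L) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "time")
    stop("expected a TSV with a 'time' first column and >= 1 locus column")
  if (anyNA(df))
    stop("missing or non-numeric value at line ",
         which(rowSums(is.na(df)) > 0)[1L] + 1L)
  times <- df[[1L]]
  if (any(diff(times) <= 0))
    stop("times not strictly increasing at line ",
         which(diff(times) <= 0)[1L] + 2L)
  f <- as.matrix(df[, -1L, drop = FALSE])
  if (any(f < 0 | f > 1)) {
    bad <- which(f < 0 | f > 1, arr.ind = TRUE)[1L, ]
    stop(sprintf("frequency outside [0, 1] at line %d, column '%s'",
                 bad[1L] + 1L, colnames(f)[bad[2L]]))
  }
  if (is.character(focal)) focal <- match(focal, colnames(f))
  if (is.na(focal) || focal < 1L || focal > ncol(f))
    stop("unknown focal column")
  ord <- c(focal, setdiff(seq_len(ncol(f)), focal))
  new_trajectory_set(times, f[, ord, drop = FALSE])
}

#' Write an allele-frequency time-series table
#'
#' Deterministic TSV output (up to 10 significant digits, no scientific
#' notation surprises), suitable for diffing; exact 0 and 1 serialize as
#' \code{"0"} and \code{"1"}.
#'
#' @param traj a \code{"trajectory_set"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_timeseries <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory_set"))
  f <- traj$freqs
  cells <- matrix(vapply(as.vector(f), function(v)
    format(v, digits = 10, scientific = FALSE, trim = TRUE), character(1)),
    nrow = nrow(f))
  lines <- c(paste(c("time", colnames(f)), collapse = "\t"),
             vapply(seq_len(nrow(f)), function(i)
               paste(c(traj$times[i], cells[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}
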