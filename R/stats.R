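#' Standardized allele-frequency increments for the FIT
#'
#' For a focal-locus frequency series \eqn{x_0, \dots, x_L} observed at
#' times \eqn{t_0 < \dots < t_L}, the standardized increment over interval i
#' is \deqn{Y_i = \frac{x_i - x_{i-1}}{\sqrt{2 x_{i-1} (1 - x_{i-1}) (t_i -
#' t_{i-1})}},} which under neutral Wright-Fisher drift (and short sampling
#' scales relative to N) is approximately normal with mean zero and a
#' variance set by the unknown population size, identical across intervals
#' when N is constant.
#'
#' @param x focal allele-frequency series (length L + 1), with
#'   \code{x[1..L]} strictly inside (0, 1).
#' @param times sampling times (generations), strictly increasing.
#' @return numeric vector \code{Y} of length L.
#' @examples
#' fit_increments(c(0.5, 0.6, 0.7), times = c(0, 1, 2))
#' @export
fit_increments <- function(x, times) {
  if (length(x) != length(times) || length(x) < 2L)
    stop("'x' and 'times' must have equal length >= 2")
  if (any(diff(times) <= 0)) stop("'times' must be strictly increasing")
  L <- length(x) - 1L
  src <- x[seq_len(L)]
  bad <- src <= 0 | src >= 1
  if (any(bad))
    stop_fitr("fitr_focal_degenerate",
              paste0("focal frequency is 0 or 1 at t = ",
                     paste(times[which(bad)], collapse = ", "),
                     "; increment undefined"))
  diff(x) / sqrt(2 * src * (1 - src) * diff(times))
}

#' The frequency increment test (FIT)
#'
#' Tests neutrality of a single focal locus from its time series alone:
#' the standardized increments \eqn{Y_1, \dots, Y_L} (see
#' [fit_increments()]) share a common zero-mean normal distribution under
#' neutral drift with constant population size, so
#' \deqn{t_{FIT} = \bar{Y} / \sqrt{S^2 / L}} follows a Student-t
#' distribution with L - 1 degrees of freedom (\eqn{S^2} is the unbiased
#' sample variance). The reported p-value is two-sided.
#'
#' @param x a frequency series, or a \code{"trajectory_set"} (the focal
#'   column is used).
#' @param times sampling times; taken from the trajectory set if omitted.
#' @param focal focal-locus column when \code{x} is a trajectory set.
#' @return object of class \code{"fitr_test_result"} with the statistic,
#'   degrees of freedom and two-sided p-value.
#' @examples
#' fit_test(c(0.5, 0.62, 0.55, 0.7), times = c(0, 10, 20, 30))
#' @export
fit_test <- function(x, times = NULL, focal = 1L) {
  if (inherits(x, "trajectory_set")) {
    times <- x$times
    x <- x$freqs[, focal]
  }
  L <- length(x) - 1L
  if (L < 2L) stop("FIT needs at least L = 2 increments (3 time points)")
  Y <- fit_increments(x, times)
  S2 <- stats::var(Y)
  if (S2 == 0)
    stop_fitr("fitr_degenerate_variance",
              "all standardized increments identical; FIT undefined")
  tstat <- mean(Y) / sqrt(S2 / L)
  p <- 2 * stats::pt(-abs(tstat), df = L - 1L)
  new_test_result(statistic = tstat, test = "FIT", df = L - 1L, p_value = p,
                  L = L)
}

new_test_result <- function(statistic, test, p_value, L, df = NULL,
                            R_used = NULL, removed_loci = character(),
                            null_draws = NULL) {
  structure(list(statistic = statistic, test = test, df = df,
                 p_value = p_value, L = L, R_used = R_used,
                 removed_loci = removed_loci, null_draws = null_draws),
            class = "fitr_test_result")
}

#' @export
print.fitr_test_result <- function(x, ...) {
  cat(x$test, "test of neutrality\n")
  cat(sprintf("  statistic = %.6g", x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df = %g", x$df))
  cat(sprintf(", two-sided p = %.4g\n", x$p_value))
  if (!is.null(x$R_used)) {
    cat("  reference loci used:", x$R_used)
    if (length(x$removed_loci))
      cat("  (removed:", paste(x$removed_loci, collapse = ", "), ")")
    cat("\n")
  }
  if (!is.null(x$null_draws))
    cat("  empirical null draws:", x$null_draws, "\n")
  invisible(x)
}

#' Per-interval standardized increments for all loci
#'
#' Computes \eqn{\Delta x_{h,i} = (x_{h,i} - x_{h,i-1}) /
#' \sqrt{x_{h,i-1}(1 - x_{h,i-1})}} for the focal locus (h = 0) and every
#' reference locus, and flags unusable loci. A reference locus is flagged
#' if its frequency is 0 or 1 at any sampled time (once fixed, its
#' increments no longer carry drift information and the statistic using it
#' is undefined or degenerate). The focal locus only requires interior
#' frequencies at \eqn{t_0, \dots, t_{L-1}} -- its final increment is still
#' defined if fixation occurs exactly at \eqn{t_L}, as happens under strong
#' selection. Flagged loci are retained here; [filter_reference_loci()]
#' removes them.
#'
#' @param traj a \code{"trajectory_set"} (first column focal), or a numeric
#'   matrix of frequencies (rows = times) together with \code{times}.
#' @param times sampling times when \code{traj} is a bare matrix.
#' @return object of class \code{"increment_matrix"}: list with \code{d}
#'   (L x (R+1) matrix, NA where undefined), \code{dt}, \code{valid}
#'   (per-locus flag), \code{removed} (identifiers removed so far).
#' @export
fitr_increments <- function(traj, times = NULL) {
  if (inherits(traj, "trajectory_set")) {
    times <- traj$times
    x <- traj$freqs
  } else {
    x <- as.matrix(traj)
  }
  if (is.null(colnames(x)))
    colnames(x) <- paste0("locus_", seq_len(ncol(x)) - 1L)
  L <- nrow(x) - 1L
  if (L < 1L) stop("need at least two time points")
  if (length(times) != nrow(x) || any(diff(times) <= 0))
    stop("'times' must be strictly increasing and match the rows")
  src <- x[seq_len(L), , drop = FALSE]
  # focal: usable iff interior before the last time (its increments exist);
  # references: discarded on fixation at any sampled time, including t_L
  valid <- apply(x > 0 & x < 1, 2L, all)
  valid[1L] <- all(src[, 1L] > 0 & src[, 1L] < 1)
  if (!valid[1L])
    stop_fitr("fitr_focal_degenerate",
              "focal locus hits frequency 0 or 1 before the final time point")
  d <- (x[-1L, , drop = FALSE] - src) / sqrt(src * (1 - src))
  d[, !valid] <- NA_real_
  structure(list(d = d, dt = diff(times), valid = valid,
                 removed = character()),
            class = "increment_matrix")
}

#' Remove unusable reference loci
#'
#' Drops every reference locus flagged invalid (frequency 0 or 1 at some
#' time before the last) from an [fitr_increments()] result. The surviving
#' reference count \code{R_used} calibrates the FITR statistic's degrees of
#' freedom; removal is all-or-nothing per locus.
#'
#' @param inc an \code{"increment_matrix"}.
#' @return an \code{"increment_matrix"} with only valid loci, and
#'   \code{removed} recording the dropped identifiers.
#' @export
filter_reference_loci <- function(inc) {
  stopifnot(inherits(inc, "increment_matrix"))
  if (ncol(inc$d) < 2L) stop("no reference loci present")
  drop <- !inc$valid
  drop[1L] <- FALSE  # focal handled by fitr_increments
  if (all(drop[-1L]))
    stop_fitr("fitr_no_reference",
              "all reference loci fixed before the final time; FITR undefined")
  out <- inc
  out$removed <- c(inc$removed, colnames(inc$d)[drop])
  out$d <- inc$d[, !drop, drop = FALSE]
  out$valid <- inc$valid[!drop]
  out
}

#' One interval's reference-standardized statistic
#'
#' \deqn{t^{(i)} = \Delta x_{0,i} \Big/ \sqrt{\tfrac{1}{R} \sum_{h=1}^R
#' \Delta x_{h,i}^2}.} Both the interval length and the (variance effective)
#' population size over the interval cancel between numerator and
#' denominator, so under neutrality of the focal locus \eqn{t^{(i)}}
#' follows a Student-t distribution with R degrees of freedom regardless of
#' how N fluctuates.
#'
#' @param d0 focal standardized increment for the interval.
#' @param dref vector of the R reference increments for the same interval.
#' @return the t-distributed interval statistic.
#' @examples
#' fitr_component(0.3, c(0.1, -0.2, 0.2))
#' @export
fitr_component <- function(d0, dref) {
  if (length(dref) < 1L) stop("need at least one reference increment")
  denom2 <- mean(dref^2)
  if (denom2 == 0)
    stop_fitr("fitr_zero_denominator",
              "all reference increments zero for this interval")
  unname(d0 / sqrt(denom2))
}

#' The FITR statistic
#'
#' The standardized sum of the per-interval statistics,
#' \deqn{t_{FITR} = \frac{1}{\sqrt{L}} \sum_{i=1}^L t^{(i)}
#'   = \sum_{i=1}^{L} \frac{\Delta x_{0,i}}{\sqrt{\frac{L}{R} \sum_h
#'     \Delta x_{h,i}^2}},} computed from a filtered increment matrix (all
#' loci usable). It approaches a standard normal as R grows; its exact null
#' distribution for finite R is obtained empirically by [fitr_null()].
#'
#' @param inc a filtered \code{"increment_matrix"} (see
#'   [filter_reference_loci()]).
#' @return the FITR statistic (numeric scalar).
#' @export
fitr_statistic <- function(inc) {
  stopifnot(inherits(inc, "increment_matrix"))
  d <- inc$d
  if (ncol(d) < 2L) stop("no reference loci present")
  ti <- vapply(seq_len(nrow(d)),
               function(i) fitr_component(d[i, 1L], d[i, -1L]),
               numeric(1))
  sum(ti) / sqrt(nrow(d))
}

.fitr_null_cache <- new.env(parent = emptyenv())

#' Empirical null distribution of the FITR statistic
#'
#' Draws M realizations of \eqn{\frac{1}{\sqrt{L}} \sum_{i=1}^L T_i} with
#' independent \eqn{T_i \sim t_R}, which is the exact null distribution of
#' the FITR statistic when every standardized increment is normal. Samples
#' are cached in memory per (L, R, M, seed) so repeated tests at the same
#' design reuse one null.
#'
#' @param L number of intervals.
#' @param R number of (surviving) reference loci.
#' @param M number of null draws (default 1e5).
#' @param seed seed for the null draws (default 1; the draw does not disturb
#'   the caller's RNG stream).
#' @return numeric vector of M null draws.
#' @examples
#' quantile(fitr_null(L = 5, R = 10, M = 1e4), c(0.025, 0.975))
#' @export
fitr_null <- function(L, R, M = 1e5, seed = 1L) {
  stopifnot(L >= 1, R >= 1, M >= 1000)
  key <- paste(L, R, M, seed, sep = "_")
  hit <- .fitr_null_cache[[key]]
  if (!is.null(hit)) return(hit)
  draws <- with_seed(seed, {
    colSums(matrix(stats::rt(L * M, df = R), nrow = L)) / sqrt(L)
  })
  .fitr_null_cache[[key]] <- draws
  draws
}

#' The frequency increment test with reference loci (FITR)
#'
#' Tests neutrality of the focal locus using R independently evolving
#' neutral reference loci to calibrate the magnitude of drift per interval,
#' which makes the test exact irrespective of fluctuations in population
#' size (the unknown per-interval effective size cancels). Pipeline:
#' [fitr_increments()] then [filter_reference_loci()] then
#' [fitr_statistic()], with a two-sided p-value against the empirical null
#' of [fitr_null()] using the add-one Monte-Carlo estimator
#' \eqn{(1 + \#\{|null| \ge |obs|\}) / (M + 1)}. For L = 1 the statistic is
#' exactly Student-t with \code{R_used} degrees of freedom and the analytic
#' p-value is used.
#'
#' @param traj a \code{"trajectory_set"} (or matrix plus \code{times});
#'   first column is the focal locus.
#' @param times sampling times when \code{traj} is a bare matrix.
#' @param M empirical null draws (default 1e5).
#' @param null_seed seed for the empirical null (default 1).
#' @return object of class \code{"fitr_test_result"}.
#' @examples
#' cfg <- sim_config(builtin_model("model1", 100), x0 = 0.5,
#'                   s = c(0.1, rep(0, 10)), sample_times = seq(0, 100, 20))
#' fitr_test(simulate_replicate(cfg, seed = 7))
#' @export
fitr_test <- function(traj, times = NULL, M = 1e5, null_seed = 1L) {
  inc <- filter_reference_loci(fitr_increments(traj, times))
  L <- nrow(inc$d)
  R_used <- ncol(inc$d) - 1L
  tstat <- fitr_statistic(inc)
  if (L == 1L) {
    p <- 2 * stats::pt(-abs(tstat), df = R_used)
    null_draws <- NULL
  } else {
    null <- fitr_null(L, R_used, M = M, seed = null_seed)
    p <- (1 + sum(abs(null) >= abs(tstat))) / (M + 1)
    null_draws <- M
  }
  new_test_result(statistic = tstat, test = "FITR", p_value = p, L = L,
                  R_used = R_used, removed_loci = inc$removed,
                  null_draws = null_draws)
}

# ---- vectorized batch versions used by the experiment drivers ----
# These recompute the same statistics across many replicates with matrix
# algebra; their agreement with fit_test()/fitr_test() is under test.

# x: replicates x (L+1) matrix of focal frequencies.
# Returns list(p, degenerate); degenerate replicates have p = NA.
fit_test_batch <- function(x, times) {
  L <- ncol(x) - 1L
  src <- x[, seq_len(L), drop = FALSE]
  degen <- rowSums(src <= 0 | src >= 1) > 0L
  dt <- diff(times)
  Y <- (x[, -1L, drop = FALSE] - src) /
    sqrt(2 * src * (1 - src) * rep(dt, each = nrow(x)))
  Ybar <- rowMeans(Y)
  S2 <- rowSums((Y - Ybar)^2) / (L - 1L)
  degen <- degen | S2 == 0
  tstat <- Ybar / sqrt(S2 / L)
  p <- 2 * stats::pt(-abs(tstat), df = L - 1L)
  p[degen] <- NA_real_
  list(p = p, statistic = tstat, degenerate = degen)
}

# arr: replicates x (L+1) x (R+1) array. Returns list(p, R_used, degenerate).
fitr_test_batch <- function(arr, times, M = 1e5, null_seed = 1L) {
  dims <- dim(arr)
  reps <- dims[1L]; L <- dims[2L] - 1L; R <- dims[3L] - 1L
  src <- arr[, seq_len(L), , drop = FALSE]
  inside <- arr > 0 & arr < 1
  # references: usable iff interior at every sampled time t_0..t_L;
  # focal: only needs interior frequencies at t_0..t_{L-1}
  valid <- matrix(TRUE, reps, R + 1L)
  for (i in seq_len(L + 1L))
    valid <- valid & matrix(inside[, i, ], reps, R + 1L)
  focal_ok <- rep(TRUE, reps)
  for (i in seq_len(L))
    focal_ok <- focal_ok & inside[, i, 1L]
  valid[, 1L] <- focal_ok
  R_used <- rowSums(valid[, -1L, drop = FALSE])
  d <- (arr[, -1L, , drop = FALSE] - src) / sqrt(src * (1 - src))
  d0 <- matrix(d[, , 1L], reps, L)
  dref2 <- matrix(d[, , -1L, drop = FALSE]^2, nrow = reps * L, ncol = R)
  # mask aligned with dref2's layout (replicate fastest, then interval)
  vref <- valid[, -1L, drop = FALSE]
  vmask <- vref[rep(seq_len(reps), times = L), , drop = FALSE]
  masked <- dref2 * vmask
  masked[is.na(masked)] <- 0  # NaN increments only occur at invalid loci
  S <- matrix(rowSums(masked), reps, L)  # sum over valid refs
  zero_denom <- rowSums(S == 0) > 0L
  degen <- !focal_ok | R_used == 0L | zero_denom
  ti <- d0 / sqrt(S / R_used)
  tstat <- rowSums(ti) / sqrt(L)
  p <- rep(NA_real_, reps)
  ok <- !degen
  if (L == 1L) {
    p[ok] <- 2 * stats::pt(-abs(tstat[ok]), df = R_used[ok])
  } else {
    for (Ru in sort(unique(R_used[ok]))) {
      sel <- ok & R_used == Ru
      s_abs <- sort(abs(fitr_null(L, Ru, M = M, seed = null_seed)))
      cnt_ge <- M - findInterval(abs(tstat[sel]), s_abs, left.open = TRUE)
      p[sel] <- (1 + cnt_ge) / (M + 1)
    }
  }
  list(p = p, statistic = tstat, R_used = R_used, degenerate = degen)
}
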