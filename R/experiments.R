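#' Evenly spaced sampling times
#'
#' \code{L + 1} equally spaced integer sampling times from 0 to \code{T}.
#'
#' @param T study duration in generations.
#' @param L number of sampling intervals.
#' @return integer vector of length L + 1 starting at 0.
#' @export
sampling_times <- function(T, L) as.integer(round(seq(0, T, length.out = L + 1L)))

#' Monte-Carlo rejection rate of the FIT or FITR
#'
#' Simulates \code{replicates} independent studies under one parameter
#' configuration, applies the chosen neutrality test to each, and returns
#' the fraction of replicates rejected at level \code{alpha} together with
#' its binomial standard error. With \code{s0 = 0} this estimates the
#' actual type-I error rate; with \code{s0 > 0}, the power. Replicates in
#' which the test is undefined (focal locus fixed before the final time, no
#' surviving reference loci, or a zero reference denominator) are counted
#' in \code{n_degenerate} and excluded from the denominator.
#'
#' @param test \code{"FITR"} or \code{"FIT"}.
#' @param model a [demographic_model()] (e.g. from [builtin_model()]).
#' @param sample_times integer sampling times starting at 0 (see
#'   [sampling_times()]).
#' @param R number of reference loci (FITR only).
#' @param s0 selection coefficient at the focal locus.
#' @param s_ref selection coefficient at every reference locus (default 0).
#' @param x0 initial focal frequency.
#' @param x0_ref initial reference frequency (default \code{x0}).
#' @param method \code{"pseudo"} or \code{"binomial"} reproduction.
#' @param recombination \code{"free"} or a fraction in \[0, 0.5\]
#'   (individual-based simulation; binomial method required).
#' @param sample_n diploid individuals sampled per time point (\code{Inf} =
#'   census).
#' @param replicates number of simulated studies.
#' @param alpha nominal significance level.
#' @param null_draws empirical null draws for FITR p-values.
#' @param seed integer seed; the run is fully reproducible given
#'   (arguments, seed).
#' @return an object of class \code{"rejection_rate"}: list with
#'   \code{rate}, \code{se}, \code{n_tested}, \code{n_degenerate}, and for
#'   the FITR the mean surviving reference count \code{mean_R_used}.
#' @examples
#' rejection_rate("FIT", builtin_model("model1", 10),
#'                sampling_times(10, 2), replicates = 500, seed = 1)
#' @export
rejection_rate <- function(test = c("FITR", "FIT"), model, sample_times,
                           R = 10L, s0 = 0, s_ref = 0, x0 = 0.5,
                           x0_ref = x0, method = c("pseudo", "binomial"),
                           recombination = "free", sample_n = Inf,
                           replicates = 1e4, alpha = 0.05,
                           null_draws = 1e5, seed = NULL) {
  test <- match.arg(test)
  method <- match.arg(method)
  if (test == "FIT") R <- 0L
  cfg <- sim_config(model,
                    x0 = c(x0, rep(x0_ref, R)),
                    s = c(s0, rep(s_ref, R)),
                    sample_times = sample_times, method = method,
                    recombination = recombination, sample_n = sample_n)
  if (identical(recombination, "free")) {
    arr <- simulate_trajectories(cfg, replicates = replicates, seed = seed)
  } else {
    arr <- array(NA_real_,
                 c(replicates, length(sample_times), R + 1L))
    for (k in seq_len(replicates)) {
      tr <- simulate_linked(cfg, seed = derive_seed(seed, paste0("rep", k)))
      arr[k, , ] <- tr$freqs
    }
  }
  res <- if (test == "FIT") {
    fit_test_batch(matrix(arr[, , 1L], replicates), sample_times)
  } else {
    fitr_test_batch(arr, sample_times, M = null_draws)
  }
  ok <- !res$degenerate
  n_tested <- sum(ok)
  if (n_tested == 0L) stop("all replicates degenerate; nothing to test")
  rate <- mean(res$p[ok] <= alpha)
  out <- list(test = test, rate = rate,
              se = sqrt(rate * (1 - rate) / n_tested),
              n_tested = n_tested, n_degenerate = sum(!ok),
              alpha = alpha, replicates = replicates)
  if (test == "FITR") out$mean_R_used <- mean(res$R_used[ok])
  class(out) <- "rejection_rate"
  out
}

#' @export
print.rejection_rate <- function(x, ...) {
  cat(sprintf("%s rejection rate at alpha = %g: %.2f%% (SE %.2f%%)\n",
              x$test, x$alpha, 100 * x$rate, 100 * x$se))
  cat(sprintf("  %d replicates tested, %d degenerate\n",
              x$n_tested, x$n_degenerate))
  if (!is.null(x$mean_R_used))
    cat(sprintf("  mean reference loci used: %.2f\n", x$mean_R_used))
  invisible(x)
}

table_grid <- function(table) {
  rows_std <- data.frame(T = c(10, 100, 1000, 10, 100, 1000),
                         L = c(2, 20, 200, 5, 5, 5))
  switch(as.character(table),
    "1" = {
      g <- expand.grid(model = paste0("model", 1:5), row = 1:6,
                       stringsAsFactors = FALSE)
      cbind(g, rows_std[g$row, ], test = "FIT", R = 0L, s0 = 0,
            x0_ref = 0.5, method = "pseudo", recombination = "free")
    },
    "2" = {
      Rmap <- c(model1 = 5L, model2 = 2L, model3 = 20L, model4 = 1L,
                model5 = 10L)
      g <- expand.grid(model = paste0("model", 1:5), row = 1:6,
                       stringsAsFactors = FALSE)
      cbind(g, rows_std[g$row, ], test = "FITR", R = Rmap[g$model], s0 = 0,
            x0_ref = 0.5, method = "pseudo", recombination = "free")
    },
    "3" = {
      base <- rbind(
        expand.grid(model = "model1p", row = 1:2, r = c("free", "0.1", "0.01", "0"),
                    s0 = c(0, 0.05), stringsAsFactors = FALSE),
        expand.grid(model = "model5p", row = 1:2, r = c("free", "0.1", "0.01", "0"),
                    s0 = c(0, 0.05), stringsAsFactors = FALSE))
      TL <- function(m, i)
        if (m == "model1p") c(T = c(10, 20)[i], L = c(2, 5)[i])
        else c(T = c(5, 10)[i], L = c(1, 5)[i])
      tl <- t(mapply(TL, base$model, base$row))
      base$T <- tl[, 1L]; base$L <- tl[, 2L]
      # binomial runs at every r; pseudo only for free recombination
      bin <- cbind(base, method = "binomial")
      ps <- cbind(base[base$r == "free", ], method = "pseudo")
      g <- rbind(bin, ps)
      g$test <- "FITR"; g$R <- 10L; g$x0_ref <- 0.5
      g$recombination <- g$r; g$r <- NULL
      g
    },
    "4" = {
      g <- expand.grid(model = c("model1", "model5"), L = c(2, 10),
                       x0_ref = c(0.5, 0.1, 0.05, 0.01),
                       selective = c(FALSE, TRUE), stringsAsFactors = FALSE)
      g$T <- 1000
      g$s0 <- ifelse(g$selective, ifelse(g$model == "model1", 0.002, 5e-4), 0)
      g$selective <- NULL
      g$test <- "FITR"; g$R <- 10L; g$method <- "pseudo"
      g$recombination <- "free"
      g
    },
    stop("unknown table id: ", table))
}

#' Regenerate a validation table
#'
#' Runs the full grid of one of the package's four validation experiments
#' at a configurable replicate count and returns the estimated rejection
#' rates with Monte-Carlo standard errors:
#' \describe{
#'   \item{1}{FIT type-I error under demographic models 1-5.}
#'   \item{2}{FITR type-I error under models 1-5 (R = 5/2/20/1/10).}
#'   \item{3}{FITR under small populations (models 1'/5'): exact binomial
#'     vs pseudo-sampling, free vs limited recombination (r = 0.1, 0.01,
#'     0), neutral and s0 = 0.05.}
#'   \item{4}{FITR with low-frequency reference loci (removal of fixed
#'     references), neutral and selective, reporting the mean surviving
#'     reference count.}
#' }
#' Each cell runs on its own seed derived from \code{seed} and the cell
#' coordinates, so any subset of rows reproduces the full run's values.
#'
#' @param table 1, 2, 3 or 4.
#' @param replicates replicates per cell (default 1e4).
#' @param seed master seed.
#' @param rows optional integer subset of grid rows (see the returned
#'   columns for the grid layout); useful because full tables are costly.
#' @param alpha nominal level.
#' @param verbose print one line per completed cell to stderr.
#' @return data.frame with one row per cell: the grid coordinates plus
#'   \code{rate_pct}, \code{se_pct}, \code{n_degenerate}, and
#'   \code{mean_R_used} for FITR tables.
#' @export
run_table <- function(table, replicates = 1e4, seed = 1L, rows = NULL,
                      alpha = 0.05, verbose = FALSE) {
  grid <- table_grid(table)
  if (!is.null(rows)) grid <- grid[rows, , drop = FALSE]
  out <- vector("list", nrow(grid))
  for (j in seq_len(nrow(grid))) {
    cell <- grid[j, ]
    key <- paste(c(table, unlist(lapply(cell, as.character))), collapse = ":")
    rec <- if (cell$recombination == "free") "free"
           else as.numeric(cell$recombination)
    rr <- rejection_rate(test = cell$test,
                         model = builtin_model(cell$model, cell$T),
                         sample_times = sampling_times(cell$T, cell$L),
                         R = cell$R, s0 = cell$s0, x0 = 0.5,
                         x0_ref = cell$x0_ref, method = cell$method,
                         recombination = rec, replicates = replicates,
                         alpha = alpha, seed = derive_seed(seed, key))
    row <- cbind(cell,
                 rate_pct = 100 * rr$rate, se_pct = 100 * rr$se,
                 n_degenerate = rr$n_degenerate,
                 mean_R_used = if (is.null(rr$mean_R_used)) NA_real_
                               else rr$mean_R_used)
    if (verbose)
      message(sprintf("cell %d/%d: %s %s T=%g L=%g -> %.2f%%", j, nrow(grid),
                      cell$test, cell$model, cell$T, cell$L,
                      100 * rr$rate))
    out[[j]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Power of the tests along a grid of selection coefficients
#'
#' Calls [rejection_rate()] at each selection coefficient in \code{s_grid}
#' (the \code{s = 0} point estimates the type-I error) and returns the
#' power curve. Power is non-decreasing in s up to Monte-Carlo noise.
#'
#' @param s_grid selection coefficients at the focal locus.
#' @inheritParams rejection_rate
#' @return data.frame with columns \code{s}, \code{power_pct},
#'   \code{se_pct}, \code{n_degenerate}.
#' @export
power_curve <- function(test = c("FITR", "FIT"), model, sample_times,
                        s_grid, R = 10L, x0 = 0.5, x0_ref = x0,
                        method = "pseudo", replicates = 1e4, alpha = 0.05,
                        seed = NULL) {
  test <- match.arg(test)
  rows <- lapply(s_grid, function(s0) {
    rr <- rejection_rate(test, model, sample_times, R = R, s0 = s0,
                         x0 = x0, x0_ref = x0_ref, method = method,
                         replicates = replicates, alpha = alpha,
                         seed = derive_seed(seed, paste0("s=", s0)))
    data.frame(s = s0, power_pct = 100 * rr$rate, se_pct = 100 * rr$se,
               n_degenerate = rr$n_degenerate)
  })
  do.call(rbind, rows)
}
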