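#' Deterministic change in allele frequency due to genic selection
#'
#' One generation of viability selection with genotype fitnesses
#' 1, 1 + s/2 and 1 + s for 0, 1 and 2 copies of the selected allele
#' (no dominance). Under Hardy-Weinberg proportions the post-selection
#' frequency is \deqn{x' = x (1 + 0.5 s (1 + x)) / (1 + s x).}
#'
#' @param x allele frequency (vectorized), in \[0, 1\].
#' @param s selection coefficient (recycled against \code{x}); \code{s = 0}
#'   returns \code{x} unchanged.
#' @return post-selection expected frequency, same length as \code{x}.
#' @examples
#' selection_update(0.5, 0.1)
#' @export
selection_update <- function(x, s) {
  if (any(x < 0 | x > 1)) stop("frequencies must lie in [0, 1]")
  denom <- 1 + s * x
  if (any(denom <= 0)) stop("pathological selection: 1 + s*x <= 0")
  x * (1 + 0.5 * s * (1 + x)) / denom
}

#' Wright-Fisher reproduction steps
#'
#' Advance allele frequencies by one generation into a population of
#' \code{N_next} diploids (2\code{N_next} gene copies).
#' \code{step_binomial()} performs exact binomial reproduction:
#' \code{k/(2 N_next)} with \code{k ~ Binomial(2 N_next, x')} where
#' \code{x'} is the post-selection frequency. \code{step_pseudo()} is the
#' fast pseudo-sampling approximation: when the expected minor-allele count
#' \code{2 N_next min(x', 1 - x')} is at most \code{minor_count_threshold},
#' the minor-allele count is drawn from a Poisson with that mean (capped at
#' \code{2 N_next}); otherwise the frequency is drawn from a normal with the
#' binomial mean and variance, clipped to \[0, 1\]. Frequencies exactly 0 or
#' 1 are absorbing in both schemes.
#'
#' @param x current frequencies (vectorized).
#' @param N_next diploid size of the offspring generation (scalar).
#' @param s selection coefficient(s), recycled against \code{x}.
#' @param minor_count_threshold expected minor-allele count at or below which
#'   the Poisson branch is used (default 5).
#' @return vector of next-generation frequencies.
#' @examples
#' set.seed(1)
#' step_binomial(0.5, 100, s = 0.05)
#' step_pseudo(rep(0.5, 4), 1e6, s = 0)
#' @export
step_binomial <- function(x, N_next, s = 0) {
  stopifnot(N_next >= 1)
  p <- selection_update(x, s)
  stats::rbinom(length(p), 2L * N_next, p) / (2 * N_next)
}

#' @rdname step_binomial
#' @export
step_pseudo <- function(x, N_next, s = 0, minor_count_threshold = 5) {
  stopifnot(N_next >= 1)
  p <- selection_update(x, s)
  out <- p
  m <- 2 * N_next
  live <- p > 0 & p < 1
  if (!any(live)) return(out)
  minor <- pmin(p, 1 - p)
  cnt <- m * minor
  pois <- live & cnt <= minor_count_threshold
  norm <- live & !pois
  if (any(pois)) {
    k <- pmin(stats::rpois(sum(pois), cnt[pois]), m)
    f <- k / m
    flip <- p[pois] > 0.5
    f[flip] <- 1 - f[flip]
    out[pois] <- f
  }
  if (any(norm)) {
    pn <- p[norm]
    out[norm] <- pmin(pmax(
      stats::rnorm(sum(norm), pn, sqrt(pn * (1 - pn) / m)), 0), 1)
  }
  out
}

#' Simulation configuration
#'
#' Bundles everything a forward simulation needs: the demographic model, the
#' initial frequency and selection coefficient of each locus (locus 1 is the
#' focal locus, the rest are references), the sampling times, the
#' reproduction scheme, the recombination fraction between adjacent loci,
#' and optional binomial sampling of individuals at observation.
#'
#' @param model a [demographic_model()].
#' @param x0 initial allele frequency per locus (length R + 1; recycled).
#' @param s selection coefficient per locus (recycled to length of x0).
#' @param sample_times strictly increasing integer generations, starting
#'   at 0, all within \code{[0, model$T]}.
#' @param method \code{"pseudo"} (default) or \code{"binomial"}.
#' @param recombination \code{"free"} (independent loci) or a per-generation
#'   recombination fraction in \[0, 0.5\] between adjacent loci (uses the
#'   individual-based simulator).
#' @param sample_n diploid individuals sampled at each time point
#'   (\code{Inf} = census frequencies).
#' @param seed optional integer seed.
#' @return an object of class \code{"sim_config"}.
#' @examples
#' sim_config(builtin_model("model1", 10), x0 = 0.5, s = c(0.05, rep(0, 10)),
#'            sample_times = c(0, 5, 10))
#' @export
sim_config <- function(model, x0 = 0.5, s = 0, sample_times,
                       method = c("pseudo", "binomial"),
                       recombination = "free", sample_n = Inf, seed = NULL) {
  stopifnot(inherits(model, "demographic_model"))
  method <- match.arg(method)
  n_loci <- max(length(x0), length(s))
  x0 <- rep_len(x0, n_loci)
  s <- rep_len(s, n_loci)
  if (any(x0 < 0 | x0 > 1)) stop("x0 must lie in [0, 1]")
  sample_times <- as.integer(sample_times)
  if (sample_times[1L] != 0L || any(diff(sample_times) <= 0L))
    stop("sample_times must start at 0 and be strictly increasing")
  if (any(sample_times > model$T))
    stop("sample_times must lie within [0, T]")
  if (!identical(recombination, "free")) {
    recombination <- as.numeric(recombination)
    if (recombination < 0 || recombination > 0.5)
      stop("recombination fraction must lie in [0, 0.5]")
  }
  structure(list(model = model, x0 = x0, s = s, sample_times = sample_times,
                 method = method, recombination = recombination,
                 sample_n = sample_n, seed = seed),
            class = "sim_config")
}

new_trajectory_set <- function(times, freqs, s = NULL, model = NULL,
                               seed = NULL) {
  freqs <- as.matrix(freqs)
  if (is.null(colnames(freqs)))
    colnames(freqs) <- paste0("locus_", seq_len(ncol(freqs)) - 1L)
  structure(list(times = as.integer(times), freqs = freqs, s = s,
                 model = model, seed = seed),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("Allele-frequency trajectories:", ncol(x$freqs), "loci at",
      length(x$times), "time points (t =", paste(x$times, collapse = ", "),
      ")\n")
  print(utils::head(cbind(time = x$times, round(x$freqs, 4)), 12))
  invisible(x)
}

# Core vectorized forward simulation of independently evolving loci.
# Returns an array [replicate, time point, locus].
simulate_freq_array <- function(model, x0, s, sample_times, method,
                                replicates) {
  n_loci <- length(x0)
  step <- if (method == "binomial") step_binomial else step_pseudo
  x <- matrix(rep(x0, each = replicates), replicates, n_loci)
  sv <- rep(s, each = replicates)
  constant_s <- all(s == 0)
  out <- array(NA_real_, dim = c(replicates, length(sample_times), n_loci))
  idx <- match(0L, sample_times)
  if (!is.na(idx)) out[, idx, ] <- x
  T_end <- max(sample_times)
  # The draw advancing the population from generation t-1 to t uses
  # N(t-1): the interval (t-1, t] accrues drift variance 1/(2 N(t-1)), so
  # a bottleneck declared on [a, b) contributes exactly b - a generations
  # of reduced size to the sampled increments.
  for (t in seq_len(T_end)) {
    N_t <- population_size(model, t - 1L)
    xv <- if (constant_s) step(as.vector(x), N_t, 0)
          else step(as.vector(x), N_t, sv)
    x <- matrix(xv, replicates, n_loci)
    idx <- match(t, sample_times)
    if (!is.na(idx)) out[, idx, ] <- x
  }
  out
}

#' Simulate allele-frequency trajectories
#'
#' \code{simulate_trajectories()} runs \code{replicates} independent
#' Wright-Fisher forward simulations of R + 1 independently evolving loci
#' (free recombination) and returns the sampled frequencies as an array
#' indexed \code{[replicate, time point, locus]}.
#' \code{simulate_replicate()} returns a single replicate as a
#' [new_trajectory_set()]-style object; with a numeric recombination
#' fraction it delegates to [simulate_linked()].
#'
#' @param config a [sim_config()].
#' @param replicates number of independent replicates.
#' @param seed optional integer seed (defaults to \code{config$seed}).
#' @return \code{simulate_trajectories()}: a 3-d array;
#'   \code{simulate_replicate()}: a \code{"trajectory_set"}.
#' @examples
#' cfg <- sim_config(builtin_model("model1", 10), x0 = 0.5, s = 0,
#'                   sample_times = c(0, 5, 10))
#' simulate_replicate(cfg, seed = 1)
#' @export
simulate_trajectories <- function(config, replicates = 1L, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!identical(config$recombination, "free"))
    stop("simulate_trajectories assumes free recombination; ",
         "use simulate_linked() for linked loci")
  if (is.null(seed)) seed <- config$seed
  arr <- with_seed(seed, {
    a <- simulate_freq_array(config$model, config$x0, config$s,
                             config$sample_times, config$method, replicates)
    if (is.finite(config$sample_n))
      a[] <- stats::rbinom(length(a), 2L * config$sample_n, a) /
        (2 * config$sample_n)
    a
  })
  dimnames(arr) <- list(NULL, paste0("t", config$sample_times),
                        paste0("locus_", seq_along(config$x0) - 1L))
  arr
}

#' @rdname simulate_trajectories
#' @export
simulate_replicate <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  if (!identical(config$recombination, "free"))
    return(simulate_linked(config, seed = seed))
  arr <- simulate_trajectories(config, replicates = 1L, seed = seed)
  new_trajectory_set(config$sample_times, arr[1L, , , drop = TRUE],
                     s = config$s, model = config$model, seed = seed)
}

#' Individual-based simulation of linked loci
#'
#' Maintains \code{N(t)} diploid individuals as pairs of haplotypes over the
#' R + 1 ordered loci. At t = 0 the loci are in linkage equilibrium: alleles
#' are drawn independently per locus at the configured initial frequencies
#' and combined at random into haplotypes. Each generation, every offspring
#' draws two parents with probability proportional to fitness (multiplied
#' across loci; per-locus genotype fitnesses 1, 1 + s/2, 1 + s), and each
#' parent transmits a gamete in which crossovers between adjacent loci occur
#' independently with probability \code{r} (\code{recombination = "free"}
#' means r = 0.5). Census allele frequencies are recorded at the sampling
#' times.
#'
#' @inheritParams simulate_trajectories
#' @return a \code{"trajectory_set"} of population allele frequencies.
#' @examples
#' cfg <- sim_config(builtin_model("model1p", 10), x0 = 0.5,
#'                   s = c(0.05, rep(0, 3)), sample_times = c(0, 5, 10),
#'                   method = "binomial", recombination = 0.01)
#' simulate_linked(cfg, seed = 1)
#' @export
simulate_linked <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (config$method != "binomial")
    stop("simulate_linked is individual-based and requires method = 'binomial'")
  r <- if (identical(config$recombination, "free")) 0.5 else config$recombination
  model <- config$model
  Tmax <- max(config$sample_times)
  if (max(population_size(model, 0:Tmax)) > 1e5)
    stop("population too large for individual-based simulation (N > 1e5); ",
         "use free recombination with simulate_trajectories()")
  if (is.null(seed)) seed <- config$seed
  n_loci <- length(config$x0)
  with_seed(seed, {
    N <- population_size(model, 0L)
    # 2N haplotype rows; individual i owns rows 2i-1, 2i
    hap <- matrix(stats::rbinom(2L * N * n_loci, 1L,
                                rep(config$x0, each = 2L * N)),
                  2L * N, n_loci)
    freqs <- matrix(NA_real_, length(config$sample_times), n_loci)
    rec <- function(t) {
      i <- match(t, config$sample_times)
      if (!is.na(i)) freqs[i, ] <<- colMeans(hap)
      invisible(NULL)
    }
    rec(0L)
    for (t in seq_len(Tmax)) {
      N_next <- population_size(model, t)
      geno <- hap[seq(1L, 2L * N - 1L, by = 2L), , drop = FALSE] +
              hap[seq(2L, 2L * N,      by = 2L), , drop = FALSE]
      w <- apply(1 + 0.5 * sweep(geno, 2L, config$s, `*`), 1L, prod)
      parent <- sample.int(N, 2L * N_next, replace = TRUE, prob = w)
      # gamete assembly: starting chromosome plus cumulative crossovers
      c0 <- stats::rbinom(2L * N_next, 1L, 0.5)
      cross <- matrix(stats::rbinom(2L * N_next * (n_loci - 1L), 1L, r),
                      2L * N_next, n_loci - 1L)
      cum <- cbind(0L, if (n_loci > 1L)
        matrix(apply(cross, 1L, cumsum),
               nrow = 2L * N_next, byrow = TRUE) else NULL)
      chrom <- (c0 + cum) %% 2L  # 0 or 1: which parental chromosome
      row_idx <- (parent - 1L) * 2L + 1L + chrom
      hap <- matrix(hap[cbind(as.vector(row_idx),
                              rep(seq_len(n_loci), each = 2L * N_next))],
                    2L * N_next, n_loci)
      N <- N_next
      rec(t)
    }
    out <- new_trajectory_set(config$sample_times, freqs, s = config$s,
                              model = model, seed = seed)
    if (is.finite(config$sample_n)) out <- sample_individuals(out, config$sample_n)
    out
  })
}

#' Binomial sampling of individuals from a trajectory
#'
#' Emulates observing each locus at each time point through a finite sample
#' of \code{n} diploid individuals: every census frequency x is replaced by
#' \code{k/(2n)} with \code{k ~ Binomial(2n, x)}. \code{n = Inf} returns the
#' input unchanged.
#'
#' @param traj a \code{"trajectory_set"}.
#' @param n diploid sample size per time point, or \code{Inf} for all.
#' @return a \code{"trajectory_set"} of sample frequencies.
#' @export
sample_individuals <- function(traj, n) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (is.infinite(n)) return(traj)
  stopifnot(n >= 1)
  f <- traj$freqs
  f[] <- stats::rbinom(length(f), 2L * as.integer(n), f) / (2 * n)
  traj$freqs <- f
  traj
}
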