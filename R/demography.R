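#' Demographic models: population size as a function of generation time
#'
#' A demographic model describes the diploid population size \code{N(t)} over
#' a study of \code{T} discrete generations. Three kinds are supported:
#' \describe{
#'   \item{constant}{\code{N(t) = N} for all t.}
#'   \item{exponential}{\code{N(t) = round(N_start * (N_end/N_start)^(t/T))},
#'     so that \code{N(0) = N_start} and \code{N(T) = N_end} exactly.}
#'   \item{piecewise}{a step function given as segments of \code{[0, T]}
#'     expressed as fractions of T; segments are half-open on the right
#'     except the last, which is closed.}
#' }
#'
#' @param kind one of \code{"constant"}, \code{"exponential"},
#'   \code{"piecewise"}.
#' @param T total duration in generations (integer, >= 1).
#' @param N constant diploid size (kind \code{"constant"}).
#' @param N_start,N_end sizes at t = 0 and t = T (kind \code{"exponential"}).
#' @param segments for kind \code{"piecewise"}: a data.frame or matrix with
#'   columns \code{from}, \code{to} (fractions of T, covering [0, 1] without
#'   overlap, in order) and \code{N}.
#'
#' @return An object of class \code{"demographic_model"}.
#' @seealso [population_size()], [builtin_model()]
#' @examples
#' m <- demographic_model("exponential", T = 10, N_start = 1e4, N_end = 1e5)
#' population_size(m, c(0, 5, 10))
#' @export
demographic_model <- function(kind = c("constant", "exponential", "piecewise"),
                              T, N = NULL, N_start = NULL, N_end = NULL,
                              segments = NULL) {
  kind <- match.arg(kind)
  T <- as.integer(T)
  if (length(T) != 1L || is.na(T) || T < 1L)
    stop("'T' must be a single integer >= 1")
  m <- list(kind = kind, T = T)
  if (kind == "constant") {
    if (is.null(N) || N < 2) stop("constant model needs N >= 2")
    m$N <- as.integer(round(N))
  } else if (kind == "exponential") {
    if (is.null(N_start) || is.null(N_end) || N_start < 2 || N_end < 2)
      stop("exponential model needs N_start >= 2 and N_end >= 2")
    m$N_start <- N_start
    m$N_end <- N_end
  } else {
    segments <- as.data.frame(segments)
    if (!all(c("from", "to", "N") %in% names(segments)))
      stop("'segments' needs columns from, to, N")
    if (nrow(segments) < 1L) stop("at least one segment required")
    if (segments$from[1L] != 0 || segments$to[nrow(segments)] != 1)
      stop("segments must cover [0, 1] in fractions of T")
    if (nrow(segments) > 1L &&
        any(abs(segments$from[-1L] - segments$to[-nrow(segments)]) > 1e-12))
      stop("segments must be contiguous and non-overlapping")
    if (any(segments$N < 2)) stop("all segment sizes must be >= 2")
    m$segments <- segments
  }
  class(m) <- "demographic_model"
  m
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("Demographic model (", x$kind, "), T = ", x$T, " generations\n", sep = "")
  if (x$kind == "constant") {
    cat("  N =", x$N, "\n")
  } else if (x$kind == "exponential") {
    cat("  N(0) =", x$N_start, "-> N(T) =", x$N_end, "\n")
  } else {
    for (i in seq_len(nrow(x$segments)))
      cat(sprintf("  N = %g on [%g T, %g T%s\n", x$segments$N[i],
                  x$segments$from[i], x$segments$to[i],
                  if (i == nrow(x$segments)) "]" else ")"))
  }
  invisible(x)
}

#' Evaluate a demographic model at one or more generations
#'
#' Returns the diploid population size at generation \code{t}. For the
#' exponential kind the size is rounded to the nearest integer each
#' generation; for the piecewise kind, generation \code{t} falls in the
#' segment whose real-valued window \code{[from*T, to*T)} contains it (the
#' last segment is closed on the right).
#'
#' @param model a [demographic_model()].
#' @param t vector of generation indices in \code{[0, T]}.
#' @return integer vector of diploid sizes (all >= 2).
#' @examples
#' population_size(builtin_model("model5", T = 1000), c(0, 600, 1000))
#' @export
population_size <- function(model, t) {
  stopifnot(inherits(model, "demographic_model"))
  if (any(t < 0 | t > model$T))
    stop("generation index outside [0, T]")
  n <- switch(model$kind,
    constant = rep(model$N, length(t)),
    exponential = as.integer(round(
      model$N_start * (model$N_end / model$N_start)^(t / model$T))),
    piecewise = {
      seg <- model$segments
      out <- rep(NA_real_, length(t))
      for (i in seq_len(nrow(seg))) {
        hi <- seg$to[i] * model$T
        sel <- t >= seg$from[i] * model$T &
          (if (i == nrow(seg)) t <= hi else t < hi)
        out[sel] <- seg$N[i]
      }
      as.integer(round(out))
    })
  n
}

#' Built-in demographic models
#'
#' The demographic scenarios used throughout the package's validation
#' experiments, parameterized by the study duration \code{T}:
#' \describe{
#'   \item{model1}{constant N = 1e4.}
#'   \item{model2}{slow growth, exponential 1e4 -> 1e5.}
#'   \item{model3}{moderate bottleneck: N = 5e4 outside, 1e4 inside the
#'     window \code{[0.5 T, 0.75 T)}.}
#'   \item{model4}{rapid growth, exponential 1e4 -> 1e8.}
#'   \item{model5}{severe bottleneck: N = 1e6 outside, 1e4 inside the same
#'     window.}
#'   \item{model1p}{constant N = 100 (a scale suitable for exact binomial
#'     and individual-based simulation).}
#'   \item{model5p}{model5 with every size divided by 200 (5000/50/5000).}
#' }
#'
#' @param name model name, see Details.
#' @param T study duration in generations.
#' @return a [demographic_model()].
#' @examples
#' builtin_model("model3", T = 1000)
#' @export
builtin_model <- function(name, T) {
  bottleneck <- function(N_out, N_in)
    data.frame(from = c(0, 0.5, 0.75), to = c(0.5, 0.75, 1),
               N = c(N_out, N_in, N_out))
  switch(as.character(name),
    model1  = demographic_model("constant", T, N = 1e4),
    model2  = demographic_model("exponential", T, N_start = 1e4, N_end = 1e5),
    model3  = demographic_model("piecewise", T, segments = bottleneck(5e4, 1e4)),
    model4  = demographic_model("exponential", T, N_start = 1e4, N_end = 1e8),
    model5  = demographic_model("piecewise", T, segments = bottleneck(1e6, 1e4)),
    model1p = demographic_model("constant", T, N = 100),
    model5p = demographic_model("piecewise", T, segments = bottleneck(5000, 50)),
    stop("unknown builtin model: ", name)
  )
}
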