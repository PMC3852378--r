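# internal helpers

# Run `expr` under a given seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Stable 31-bit seed derived from a master seed and a character key, so that
# every cell of an experiment grid gets an independently reproducible stream.
derive_seed <- function(master, key) {
  if (is.null(master)) return(NULL)
  h <- as.double(master %% 2147483647L)
  for (b in utf8ToInt(paste0(key, collapse = "|"))) {
    h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h) + 1L
}

stop_fitr <- function(class, msg) {
  stop(structure(class = c(class, "fitr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
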