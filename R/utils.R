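#' @keywords internal
"_PACKAGE"

# Shared internal helpers: argument checking and seed plumbing.

abort_invalid <- function(msg, class = "weakeeg_invalid_argument") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort_invalid(sprintf("`%s` must be a positive finite scalar", name))
  invisible(x)
}

#' Derive a stage seed from a global seed
#'
#' One global seed fans out to per-stage seeds through a fixed integer mixing
#' function, so any pipeline stage can be rerun in isolation and still draw
#' from its own reproducible stream. The result is always in [1, 2^31 - 2].
#'
#' @param seed Integer global seed.
#' @param stage Character stage label (e.g. "simulate", "train").
#' @param k Optional integer sub-index (e.g. replicate number).
#' @return An integer seed usable with [set.seed()].
#' @export
derive_seed <- function(seed, stage, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647 # 2^31 - 1, Mersenne prime
  h <- (as.double(seed) %% m)
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + (as.double(k) %% m)) %% m
  as.integer(h %% (m - 1)) + 1L
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's RNG
# state is untouched. Keeps every generator a pure function of (args, seed).
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}
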