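# Internal helpers shared across modules.

# Evaluate `expr` under a given RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = env)
    on.exit(assign(".Random.seed", old, envir = env), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = env)), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Connected components of an adjacency list (named list of character
# vectors). Returns an integer label per id, named.
connected_components <- function(adj) {
  ids <- names(adj)
  lab <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  comp <- 0L
  for (start in ids) {
    if (!is.na(lab[[start]])) next
    comp <- comp + 1L
    queue <- start
    while (length(queue)) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      if (!is.na(lab[[v]])) next
      lab[[v]] <- comp
      nb <- adj[[v]]
      queue <- c(queue, nb[is.na(lab[nb])])
    }
  }
  lab
}

# Population standard deviation (divisor n, not n-1).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Month-of-year for time indices 1..T anchored at calendar month
# `anchor_month` (1-12) for t = 1.
month_of_year <- function(t, anchor_month) {
  ((t - 1L + anchor_month - 1L) %% 12L) + 1L
}

# Stable RNG sub-seed derivation; keeps results within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k * 9973) %% 2147483647)
}
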