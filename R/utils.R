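# Internal helpers shared across modules.

abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min) {
    abort_field(field, sprintf("must be a single integer >= %d", min))
  }
  as.integer(x)
}

check_number <- function(x, field, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) || x < lower || x > upper) {
    abort_field(field, sprintf("must be a single finite number in [%s, %s]", lower, upper))
  }
  as.numeric(x)
}

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Deterministic 31-bit string hash (polynomial rolling hash mod 2^31 - 1).
# Used to spawn per-site RNG substreams so each site's stream depends only on
# its own labels and the root seed, never on how many other sites exist.
hash31 <- function(...) {
  s <- paste(..., sep = "\r", collapse = "\n")
  m <- 2147483647
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% m
  h
}

substream_seed <- function(root_seed, ...) {
  m <- 2147483647
  as.integer((hash31(...) + (root_seed %% m) * 2654435) %% m)
}

# Evaluate `expr` with its own RNG stream; caller's .Random.seed is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

rms <- function(x) sqrt(mean(x^2))
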