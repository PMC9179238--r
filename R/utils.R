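# internal helpers shared across modules

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# Keeps package functions free of set.seed() side effects.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Counter-based seed fan-out: derive a stream seed from a base seed and a
# string key, staying inside 32-bit integer range so set.seed() accepts it.
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(paste0(key))) h <- (h * 131 + ch) %% 1009600007
  as.integer((as.numeric(seed) * 748201 + h) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}

assert_cols <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

`%na%` <- function(x, y) if (is.null(x) || (length(x) == 1 && is.na(x))) y else x
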