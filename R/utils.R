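# Internal helpers shared across modules.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible sub-seed for a named stage
#'
#' All randomness in the package flows from one root seed through named
#' substreams, so that individual stages (patch growth, band noise, cloud
#' placement, ...) are reproducible in isolation.
#'
#' @param seed Integer root seed.
#' @param name Character name of the substream.
#' @param index Optional integer (e.g. acquisition date index).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
substream_seed <- function(seed, name, index = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 48271 + h * 1299721 + index * 69427) %%
               2147483647)
}

with_substream <- function(seed, name, index = 0L, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name, index))
  force(code)
}

stop_cfg <- function(...) stop(sprintf(...), call. = FALSE)

same_dim <- function(a, b) identical(dim(a), dim(b))

# fraction of finite entries
n_valid <- function(x) sum(is.finite(x))
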