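# internal helpers shared across modules

sigmoid <- function(x) stats::plogis(x)

deg2rad <- function(deg) deg * pi / 180

rad2deg <- function(rad) rad * 180 / pi

# wrap an angle in degrees to [0, 360)
wrap360 <- function(deg) ((deg %% 360) + 360) %% 360

rms <- function(x) sqrt(mean(x^2))

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# run code with a temporary RNG seed, restoring the caller's RNG state;
# seed = NULL leaves the current stream untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}
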