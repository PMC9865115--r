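# small internal helpers shared across modules

.unit <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < .Machine$double.eps^0.5) stop("cannot normalize a near-zero vector")
  v / nv
}

.cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# row-wise cross product of two n x 3 matrices
.cross3_rows <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

.row_norms <- function(m) sqrt(rowSums(m^2))

# evaluate `code` under a fixed seed without disturbing the caller's RNG state
with_preserved_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.gp_message <- function(...) {
  if (isTRUE(getOption("gaitplanes.verbose", FALSE))) message(...)
}

# clamp into [-1, 1] before acos
.clamp1 <- function(x) pmin(1, pmax(-1, x))
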