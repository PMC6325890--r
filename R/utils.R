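#' Derive independent replicate seeds from a root seed
#'
#' A single root seed governs a whole experiment; per-replicate streams are
#' derived from it so that replicates are mutually independent yet the whole
#' run is reproducible from one integer.
#'
#' @param seed Root seed (integer).
#' @param n Number of seeds to derive.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seeds(1, 3)
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) return(invisible(NULL))
  assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# scalar checks used at user-facing boundaries
.check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

.check_prob <- function(x, name, lo = 0, hi = 1, lo_open = TRUE, hi_open = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort(sprintf(
      "`%s` must be a single number in %s%g, %g%s", name,
      if (lo_open) "(" else "[", lo, hi, if (hi_open) ")" else "]"
    ))
  }
  as.numeric(x)
}
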