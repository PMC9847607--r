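# Internal helpers shared across modules.

#' Nominal SOA steps of the SJ test design
#'
#' The 23 nominal stimulus onset asynchronies (ms) used in a test session:
#' 0 and +/- 50, 100, 150, 200, 250, 300, 350, 400, 500, 600, 800 ms.
#' Negative SOAs mean odor first; positive, taste first.
#'
#' @return Integer vector of length 23, sorted ascending.
#' @export
soa_steps_ms <- function() {
  base <- c(50L, 100L, 150L, 200L, 250L, 300L, 350L, 400L, 500L, 600L, 800L)
  sort(c(-base, 0L, base))
}

# Run code under a given seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
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

# Deterministic child seed from a master seed; keeps values inside the
# 32-bit integer range so set.seed() accepts them on any platform.
derive_seed <- function(master, index) {
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 1103 + as.numeric(index) * 7919) %% 2147483629) + 1L
}

assert_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

response_levels <- function() c("simultaneous", "successive", "none")
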