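## Small internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG state
#'
#' Seeds the RNG, runs `code`, and restores the caller's RNG state, so
#' simulation functions are deterministic under a fixed seed without
#' clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
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
  }
  force(code)
}

## Random DNA of length n with a given GC content.
random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## Reverse complement of a plain character vector of DNA strings.
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## Sample one integer from 1..n uniformly (sample() misbehaves for length-1 x).
sample_int <- function(n, size = 1, replace = FALSE, prob = NULL) {
  sample.int(n, size = size, replace = replace, prob = prob)
}

## Assert helper producing consistent error messages.
check_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

## Integer range c(min, max) validation for simulation configs.
check_range <- function(r, name, min_allowed = 1L) {
  check_that(length(r) == 2 && all(is.finite(r)) && r[1] <= r[2] &&
               r[1] >= min_allowed,
             sprintf("'%s' must be a range c(min, max) with %d <= min <= max",
                     name, min_allowed))
  as.integer(r)
}

## Draw one integer uniformly from an inclusive range.
draw_range <- function(r) {
  if (r[1] == r[2]) return(as.integer(r[1]))
  as.integer(sample(seq.int(r[1], r[2]), 1L))
}
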