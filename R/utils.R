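# Internal helpers: seeded evaluation and deterministic substreams.

#' Evaluate code under a fixed RNG seed, restoring global RNG state afterwards
#' @noRd
.withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Derive a reproducible substream seed from a master seed and string labels.
#'
#' Polynomial string hash modulo a Mersenne prime, so adding one labelled
#' stream never perturbs another (all randomness flows from one master seed).
#' @noRd
.substream <- function(seed, ...) {
  label <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
                 collapse = "/")
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

#' @noRd
.assertMatrixLike <- function(x, what = "matrix") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop(what, " must be a matrix or data.frame")
  x
}

# Menstrual-cycle phase labels for visits 1-4.
.PHASES <- c("F", "O", "EL", "LL")

#' Map visit numbers 1-4 to phase labels
#' @param visit integer vector of visit numbers in 1..4.
#' @return character vector of phase labels (F, O, EL, LL).
#' @export
visitPhase <- function(visit) {
  stopifnot(all(visit %in% 1:4))
  .PHASES[visit]
}
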