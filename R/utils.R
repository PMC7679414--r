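#' Round half away from zero
#'
#' Base \code{round()} rounds half to even; printed secretome tables use
#' conventional half-up rounding (55.6 -> 56), so percentage and
#' discretization code goes through this helper.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' roundHalfUp(0.5)   # 1, where round(0.5) is 0
#' roundHalfUp(2.345, 2)
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Integer percentage with half-up rounding
#'
#' @param count numerator count.
#' @param total denominator count; \code{NA} returned when zero.
#' @return integer percent, half-up rounded.
#' @examples
#' percentHalfUp(102, 112)  # 91
#' percentHalfUp(25, 45)    # 56
#' @export
percentHalfUp <- function(count, total) {
  ifelse(total > 0, roundHalfUp(100 * count / total), NA_real_)
}

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Sample key helpers: columns are keyed "fungus|substrate|replicate".
makeSampleKey <- function(fungus, substrate, replicate) {
  paste(fungus, substrate, replicate, sep = "|")
}

parseSampleKey <- function(keys) {
  parts <- strsplit(keys, "|", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad))
    stop("malformed sample key(s): ", paste(keys[bad], collapse = ", "),
         " (expected 'fungus|substrate|replicate')")
  rep_ <- suppressWarnings(as.integer(vapply(parts, `[`, "", 3L)))
  if (anyNA(rep_))
    stop("malformed sample key(s): replicate field is not an integer")
  data.frame(fungus = vapply(parts, `[`, "", 1L),
             substrate = vapply(parts, `[`, "", 2L),
             replicate = rep_,
             stringsAsFactors = FALSE)
}
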