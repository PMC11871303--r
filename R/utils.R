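#' @keywords internal
#' @importFrom stats rnorm mad median quantile coef vcov resid sd cor pt setNames
#' @importFrom utils head tail write.table read.table write.csv
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("carnmr_invalid_argument", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf, allow_inf = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (allow_inf || is.finite(x)) && x >= lower && x <= upper
  if (!ok) {
    stop_invalid(sprintf("`%s` must be a single number in [%s, %s]", name,
                         format(lower), format(upper)))
  }
  invisible(x)
}

#' Derive an independent child seed from a master seed
#'
#' Generators in this package take a single integer master seed; independent
#' random streams per (ligand, assay, replicate) are obtained by hashing the
#' master seed together with a string key. The hash is a plain polynomial
#' string hash reduced modulo 2^31 - 1, so derived seeds are valid R integer
#' seeds and identical (seed, key) pairs always give identical streams.
#'
#' @param seed Integer master seed.
#' @param ... Character or numeric key components identifying the stream.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  check_number(seed, "seed")
  key <- paste(c(format(seed), vapply(list(...), function(x) paste(format(x), collapse = ","),
                                      character(1))), collapse = "|")
  m <- 2147483647  # 2^31 - 1, keeps the result a valid 32-bit seed
  h <- 17
  for (code in utf8ToInt(key)) {
    h <- (h * 31 + code) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

with_seed <- function(seed, code) {
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
  code
}
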