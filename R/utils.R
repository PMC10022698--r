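#' Round half away from zero
#'
#' Fixed-precision rounding in which exact halves move away from zero, the
#' convention used in forensic report tables. Base [round()] rounds halves to
#' even, which disagrees with published tables on boundary values such as
#' 118.5.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return `x` rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(0.12345, 4)
#' round_half_up(2.5, 0)  # 3, not 2
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # tiny nudge guards against binary representations just under .5
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Render 1 - x as a fixed-point decimal string beyond double resolution
#'
#' Combined discrimination powers of large marker panels sit so close to 1
#' that `1 - x` underflows to exactly 1 in double precision. This renders the
#' value from its complement: the complement (around 1e-24 for a 57-locus
#' panel) is representable, so the decimal digits of `1 - complement` can be
#' produced exactly by integer arithmetic on `round(complement * 10^digits)`.
#'
#' @param complement numeric in `[0, 1)`, the value of `1 - x`.
#' @param digits number of decimal places to render.
#' @return character scalar, e.g. `"0.99999...99822"`.
#' @export
#' @examples
#' format_unity_complement(3.00178e-24, 29)
format_unity_complement <- function(complement, digits) {
  stopifnot(is.numeric(complement), length(complement) == 1L,
            complement >= 0, complement < 1, digits >= 1)
  m <- round(complement * 10^digits)
  if (m == 0) {
    return(paste0("1.", strrep("0", digits)))
  }
  if (m >= 2^53 || m >= 10^digits) {
    # complement large enough that plain formatting is exact
    return(sprintf("%.*f", digits, 1 - complement))
  }
  width <- nchar(sprintf("%.0f", m))
  suffix <- sprintf("%0*.0f", width, 10^width - m)
  paste0("0.", strrep("9", digits - width), suffix)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never disturbs user
# simulations.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    env <- globalenv()
    old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      get(".Random.seed", envir = env)
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = env, inherits = FALSE)) {
          rm(".Random.seed", envir = env)
        }
      } else {
        assign(".Random.seed", old, envir = env)
      }
    })
    set.seed(seed)
  }
  force(code)
}
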