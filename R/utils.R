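#' @keywords internal
"_PACKAGE"

#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used in the panel
#' summary tables (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by a relative epsilon so values sitting exactly on .5 after
  # floating-point representation still round up
  floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p * sign(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# `seed = NULL` evaluates in the caller's RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# locus keys "chrom:pos" used throughout as matrix dimnames
locus_key <- function(chrom, pos) paste0(chrom, ":", pos)

split_locus_key <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[`, "", 1L),
    pos = as.integer(vapply(parts, `[`, "", 2L)),
    stringsAsFactors = FALSE
  )
}
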