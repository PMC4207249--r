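# Shared numeric helpers.

#' Geometric mean
#'
#' Potency values are approximately log-normally distributed, so consolidated
#' potencies are geometric rather than arithmetic means.
#'
#' @param x numeric vector of positive values; `NA`s are dropped.
#' @return the geometric mean, or `NA` if no finite positive values remain.
#' @export
geometric_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_real_)
  if (any(x <= 0)) abort("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

# Round half away from zero (table-style percentage rounding); base round()
# rounds half to even.
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Tukey five-number summary with type-7 quartiles, as a one-row tibble.
five_number_summary <- function(x) {
  q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE))
  tibble(
    min = min(x), lower_quartile = q[1], median = q[2],
    upper_quartile = q[3], max = max(x)
  )
}
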