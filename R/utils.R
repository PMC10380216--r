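#' Geometric mean
#'
#' @param x numeric vector, all values must be positive.
#' @param na.rm drop missing values first.
#' @return the geometric mean \code{exp(mean(log(x)))}.
#' @export
geom_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(is.na(x))) return(NA_real_)
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

# Geometric standard deviation on natural-log scale. `population = TRUE`
# divides by n rather than n - 1.
geom_sd <- function(x, population = TRUE) {
  if (any(x <= 0)) stop("geometric SD requires strictly positive values")
  lx <- log(x)
  n <- length(lx)
  v <- if (population) sum((lx - mean(lx))^2) / n else stats::var(lx)
  exp(sqrt(v))
}

#' Adjusted Rand index between two label vectors
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions, 0 is the expected value for random labels.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return the adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  choose2 <- function(m) m * (m - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# Quantile with linear interpolation between order statistics ("type 7").
# Kept as a named wrapper so the convention is stated once.
quantile7 <- function(x, probs) {
  stats::quantile(x, probs = probs, type = 7, names = FALSE)
}

# stop() with a consistent prefix for user configuration errors
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration: field '%s' %s", field, msg), call. = FALSE)
}
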