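# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn .data
#' @importFrom stats median sd cor cor.test setNames coef anova lm glm
#'   binomial poisson rnorm rpois rbinom rbeta runif logLik pchisq predict
#'   quantile var
#' @importFrom utils head tail
NULL

# Shift a numeric vector by an integer number of positions, filling vacated
# entries with the edge value (no wrap-around).
shift_fill <- function(x, s) {
  n <- length(x)
  if (s == 0L) return(x)
  if (abs(s) >= n) return(rep(if (s > 0) x[1] else x[n], n))
  if (s > 0) c(rep(x[1], s), x[seq_len(n - s)])
  else c(x[seq.int(-s + 1L, n)], rep(x[n], -s))
}

# Standardize to mean 0, sd 1 (n - 1 denominator); constant input errors.
standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) abort("cannot standardize a constant vector")
  (x - mean(x)) / s
}

# md5 of an arbitrary R object via base serialization (version 3, no
# compression) so equal objects hash equally across runs.
object_md5 <- function(object) {
  f <- tempfile(fileext = ".bin")
  on.exit(unlink(f), add = TRUE)
  con <- file(f, "wb")
  serialize(object, con, version = 3L)
  close(con)
  unname(tools::md5sum(f))
}

# Draw per-sample sub-seeds from one parent seed (documented splitting
# scheme: a single parent stream yields one 31-bit sub-seed per sample).
sub_seeds <- function(seed, n) {
  withr_seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

withr_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort("`seed` must be a single integer")
  set.seed(as.integer(seed))
}

vcat <- function(...) invisible(NULL)

# Vectorized column standard deviations (n - 1 denominator).
col_sds <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  v <- (colSums(x^2) - n * mu^2) / (n - 1)
  sqrt(pmax(v, 0))
}
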