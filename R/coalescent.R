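#' Rising factorial
#'
#' Computes the rising factorial (Pochhammer symbol)
#' \eqn{a_{(k)} = a(a+1)\cdots(a+k-1)}, with \eqn{a_{(0)} = 1}.
#'
#' @param a Numeric base.
#' @param k Non-negative integer number of factors.
#' @return Numeric value of \eqn{a_{(k)}}.
#' @examples
#' rising_factorial(6, 3)  # 6*7*8 = 336
#' @export
rising_factorial <- function(a, k) {
  stopifnot(is.numeric(a), length(a) == 1L, length(k) == 1L,
            k >= 0, k == round(k))
  if (k == 0) return(1)
  prod(a + 0:(k - 1))
}

#' Falling factorial
#'
#' Computes the falling factorial
#' \eqn{a_{[k]} = a(a-1)\cdots(a-k+1)}, with \eqn{a_{[0]} = 1}.
#'
#' @inheritParams rising_factorial
#' @return Numeric value of \eqn{a_{[k]}}.
#' @examples
#' falling_factorial(6, 3)  # 6*5*4 = 120
#' @export
falling_factorial <- function(a, k) {
  stopifnot(is.numeric(a), length(a) == 1L, length(k) == 1L,
            k >= 0, k == round(k))
  if (k == 0) return(1)
  prod(a - 0:(k - 1))
}

#' Kingman lineage-counting probability g[i,j](T)
#'
#' Probability that `i` gene lineages entering a population at time 0
#' leave exactly `j` lineages after `t` coalescent time units, i.e. that
#' exactly `i - j` coalescent events occur in time `t` under the Kingman
#' coalescent.  This is the classical Tavare spectral sum
#' \deqn{g_{i,j}(T)=\sum_{k=j}^{i}
#'   e^{-k(k-1)T/2}\,\frac{(2k-1)(-1)^{k-j} j_{(k-1)}\,i_{[k]}}
#'   {j!\,(k-j)!\,i_{(k)}},}
#' where \eqn{a_{(k)}} and \eqn{a_{[k]}} are rising and falling
#' factorials.
#'
#' The sum is alternating and can lose many significant digits when the
#' result is small (short branches, many lineages).  Terms are therefore
#' accumulated with compensated (Kahan) summation, and whenever heavy
#' cancellation is detected the value is recomputed by uniformization of
#' the pure-death chain on lineage counts -- a series with all
#' non-negative terms, free of cancellation -- so that results are
#' accurate to ~1e-12 relative error throughout the supported range.
#'
#' @param i Integer number of entering lineages, `i >= 1`.
#' @param j Integer number of exiting lineages, `1 <= j <= i`.
#' @param t Branch length in coalescent time units (vectorized);
#'   non-negative, `Inf` allowed (all lineages coalesce: the value is 1
#'   for `j = 1` and 0 otherwise).
#' @return Numeric vector of probabilities, same length as `t`.
#' @examples
#' g_ij(2, 1, 1)              # 1 - exp(-1)
#' g_ij(6, 1, 0.1)            # ~1.28e-4
#' sum(g_ij(5, 1:5, 0.3))     # 1: lineage counts partition the space
#' @seealso [cover_prob_bound()] which uses `g_ij(k - 2, 1, t_min)`.
#' @export
g_ij <- function(i, j, t) {
  stopifnot(length(i) == 1L, length(j) == 1L || length(t) == 1L)
  if (length(j) > 1L) return(vapply(j, function(jj) g_ij(i, jj, t), 0))
  if (i != round(i) || j != round(j) || j < 1 || i < j)
    stop("require integer i >= j >= 1, got i = ", i, ", j = ", j)
  if (any(is.na(t)) || any(t < 0)) stop("branch length t must be >= 0")
  vapply(t, function(tt) .g_scalar(i, j, tt), 0)
}

.g_scalar <- function(i, j, t) {
  if (is.infinite(t)) return(if (j == 1) 1 else 0)
  if (t == 0) return(as.numeric(i == j))
  if (i == j) return(exp(-i * (i - 1) * t / 2))
  # Tavare sum, Kahan-compensated; coefficients stay < 1e60 for i <= ~80
  s <- 0; comp <- 0; max_term <- 0
  for (k in j:i) {
    coef <- (2 * k - 1) * (-1)^(k - j) *
      rising_factorial(j, k - 1) * falling_factorial(i, k) /
      (factorial(j) * factorial(k - j) * rising_factorial(i, k))
    term <- exp(-k * (k - 1) * t / 2) * coef
    max_term <- max(max_term, abs(term))
    y <- term - comp
    tsum <- s + y
    comp <- (tsum - s) - y
    s <- tsum
  }
  # > ~3 digits cancelled: redo with the non-alternating uniformization series
  if (max_term > 0 && abs(s) < 1e-3 * max_term) s <- .g_uniformization(i, j, t)
  min(max(s, 0), 1)
}

# g_{i,j}(t) by uniformization of the death chain m -> m-1 at rate
# m(m-1)/2.  All series terms are non-negative, so small probabilities
# are obtained with full relative accuracy (no cancellation).
.g_uniformization <- function(i, j, t) {
  lam <- i * (i - 1) / 2          # uniformization rate (max death rate)
  mu <- lam * t                   # Poisson mean of jump-attempt count
  # v[m] = P(count == m) after step; state vector over counts 1..i
  v <- numeric(i); v[i] <- 1
  p_down <- (1:i) * (0:(i - 1)) / 2 / lam   # per-state death probability
  acc <- 0
  w <- exp(-mu)                   # Poisson(mu) weight, updated iteratively
  log_w <- -mu                    # tracked in logs while w underflows
  m <- 0
  m_max <- ceiling(mu + 12 * sqrt(mu + 1) + 60)
  repeat {
    if (w == 0 && log_w > -745) w <- exp(log_w)
    acc <- acc + w * v[j]
    if (m >= m_max) break
    # Poisson recurrence; geometric tail bound controls truncation
    if (m + 1 > mu && w > 0) {
      r <- mu / (m + 1)
      tail_bound <- w * r / (1 - r)
      if (tail_bound < acc * 1e-15 + 1e-320) break
    }
    m <- m + 1
    log_w <- log_w + log(mu) - log(m)
    w <- w * mu / m
    # one uniformized step: deaths move mass down one state
    moved <- v * p_down
    v <- v - moved
    v[1:(i - 1)] <- v[1:(i - 1)] + moved[2:i]
  }
  acc
}
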