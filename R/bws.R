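#' Baumgartner-Weiss-Schindler two-sample rank statistic
#'
#' Computes the BWS statistic on pooled mid-ranks. The statistic weights
#' squared deviations of the ordered sample ranks from their null
#' expectation by the inverse of their null variance, so departures in the
#' distribution tails count more than in the centre. It depends on the data
#' only through ranks and is therefore invariant under any strictly
#' increasing transform of the pooled values and under swapping the two
#' samples.
#'
#' For sample sizes \eqn{n} (of `x`) and \eqn{m} (of `y`), with
#' \eqn{N = n + m}, let \eqn{R_{(i)}} be the ordered pooled mid-ranks of the
#' `x` values. Then
#' \deqn{B_X = \frac{1}{n} \sum_{i=1}^n
#'   \frac{(R_{(i)} - \frac{N}{n} i)^2}
#'        {\frac{i}{n+1}(1 - \frac{i}{n+1}) \cdot \frac{mN}{n}}}
#' and symmetrically for \eqn{B_Y}; the statistic is
#' \eqn{B = (B_X + B_Y)/2}.
#'
#' @param x,y Numeric vectors, each with at least two values. Ties across
#'   the pooled data are handled with mid-ranks.
#' @return An object of class `bws_test`: a list with elements `B`, `B_X`,
#'   `B_Y`, `n`, `m`, `N`. Has a [generics::tidy()] method.
#' @examples
#' bws_statistic(c(1, 2), c(3, 4))
#' @export
bws_statistic <- function(x, y) {
  check_two_samples(x, y)
  n <- length(x)
  m <- length(y)
  N <- n + m
  r <- rank(c(x, y))
  rx <- sort.int(r[seq_len(n)])
  ry <- sort.int(r[n + seq_len(m)])
  bx <- bws_component(rx, n, m, N, signed = FALSE)
  by <- bws_component(ry, m, n, N, signed = FALSE)
  structure(
    list(B = (bx + by) / 2, B_X = bx, B_Y = by, n = n, m = m, N = N),
    class = "bws_test"
  )
}

#' @export
print.bws_test <- function(x, ...) {
  cat("BWS two-sample rank statistic\n")
  cat(sprintf("  n = %d, m = %d\n", x$n, x$m))
  cat(sprintf("  B = %.6g (B_X = %.6g, B_Y = %.6g)\n", x$B, x$B_X, x$B_Y))
  invisible(x)
}

check_two_samples <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop_dmrlink("both samples need at least 2 values",
                 "dmrlink_insufficient_data")
  }
  if (anyNA(x) || anyNA(y)) {
    stop_dmrlink("missing values are not supported", "dmrlink_data_error")
  }
  invisible(NULL)
}

# one component of the BWS statistic from the ordered pooled ranks of one
# sample; signed = TRUE replaces each squared deviation d^2 by d|d|,
# giving the directional component used for one-sided testing
bws_component <- function(sorted_ranks, n, other, N, signed = FALSE) {
  i <- seq_len(n)
  d <- sorted_ranks - (N / n) * i
  w <- (i / (n + 1)) * (1 - i / (n + 1)) * (other * N / n)
  dev <- if (signed) d * abs(d) else d * d
  sum(dev / w) / n
}

#' One-sided BWS permutation test
#'
#' Permutation p-values for a directional variant of the BWS statistic. In
#' each component statistic the squared rank deviation \eqn{d^2} is
#' replaced by the signed \eqn{d\,|d|}, and the directional statistic is
#' \eqn{D = (\tilde B_Y - \tilde B_X)/2}. Large positive \eqn{D} indicates
#' that `x` is stochastically smaller than `y` ("shifted left").
#' `p_right` is the permutation probability of \eqn{D \ge D_{obs}} and
#' `p_left` of \eqn{D \le D_{obs}}; swapping `x` and `y` swaps the two
#' p-values.
#'
#' When the number of distinct label assignments `choose(n+m, n)` is at
#' most `max_exhaustive`, the full permutation distribution is enumerated
#' and p-values are exact. Otherwise `n_perm` random assignments are drawn
#' and the observed arrangement is included in both numerator and
#' denominator, so every p-value is at least `1/(n_perm + 1)`.
#'
#' @inheritParams bws_statistic
#' @param n_perm Number of Monte Carlo label permutations when exhaustive
#'   enumeration is infeasible.
#' @param seed Optional integer seed applied locally to the permutation
#'   draw (the caller's RNG state is restored on exit).
#' @param max_exhaustive Enumerate all arrangements when their count does
#'   not exceed this value.
#' @return A list with `p_left`, `p_right`, `D_obs`, `n_arrangements`, and
#'   `exhaustive`.
#' @examples
#' bws_one_sided(c(1, 2, 3), c(4, 5, 6))$p_right  # exact 1/20
#' @export
bws_one_sided <- function(x, y, n_perm = 2000, seed = NULL,
                          max_exhaustive = 10000) {
  check_two_samples(x, y)
  if (n_perm < 1) {
    stop_dmrlink("n_perm must be at least 1", "dmrlink_parameter_error")
  }
  n <- length(x)
  m <- length(y)
  N <- n + m
  arr <- with_local_seed(seed, bws_arrangements(N, n, n_perm, max_exhaustive))
  pooled <- c(x, y)
  r <- rank(pooled)
  ord <- order(pooled)
  s <- r[ord]
  pos_obs <- which(ord <= n)
  d_all <- bws_directional(s, arr)
  d_obs <- bws_directional_one(s, pos_obs, n, m, N)
  perm_pvalues(d_all, d_obs, arr$exhaustive)
}

# exact p-values under exhaustive enumeration (observed arrangement is one
# of the enumerated ones); add-one estimator for Monte Carlo
perm_pvalues <- function(d_all, d_obs, exhaustive) {
  tol <- 1e-9 * (1 + abs(d_obs))
  n_arr <- length(d_all)
  le <- sum(d_all <= d_obs + tol)
  ge <- sum(d_all >= d_obs - tol)
  if (exhaustive) {
    list(p_left = le / n_arr, p_right = ge / n_arr, D_obs = d_obs,
         n_arrangements = n_arr, exhaustive = TRUE)
  } else {
    list(p_left = (1 + le) / (n_arr + 1), p_right = (1 + ge) / (n_arr + 1),
         D_obs = d_obs, n_arrangements = n_arr, exhaustive = FALSE)
  }
}

# Label arrangements for a pooled sample of size N with n labelled "x".
# Rows index positions in the *sorted* pooled order, so a single
# arrangement set serves every CpG of a stratum. Returns position
# matrices for both samples plus precomputed inverse weights.
bws_arrangements <- function(N, n, n_perm, max_exhaustive = 10000) {
  m <- N - n
  n_total <- choose(N, n)
  exhaustive <- n_total <= max_exhaustive
  if (exhaustive) {
    px <- t(utils::combn(N, n))
  } else {
    px <- t(vapply(seq_len(n_perm),
                   function(i) sort.int(sample.int(N, n)),
                   integer(n)))
  }
  n_arr <- nrow(px)
  sel <- matrix(FALSE, n_arr, N)
  sel[cbind(rep(seq_len(n_arr), n), as.vector(px))] <- TRUE
  py <- matrix(which(t(!sel)) - rep((seq_len(n_arr) - 1L) * N, each = m),
               n_arr, m, byrow = TRUE)
  ix <- seq_len(n)
  iy <- seq_len(m)
  list(
    px = px, py = py, n = n, m = m, N = N,
    n_arrangements = n_arr, exhaustive = exhaustive,
    wx_inv = 1 / ((ix / (n + 1)) * (1 - ix / (n + 1)) * (m * N / n)),
    wy_inv = 1 / ((iy / (m + 1)) * (1 - iy / (m + 1)) * (n * N / m)),
    ex = (N / n) * ix, ey = (N / m) * iy
  )
}

# directional statistic D = (B~_Y - B~_X)/2 for every arrangement;
# s = sorted pooled mid-ranks of the CpG being tested
bws_directional <- function(s, arr) {
  rx <- matrix(s[arr$px], arr$n_arrangements, arr$n)
  ry <- matrix(s[arr$py], arr$n_arrangements, arr$m)
  dx <- rx - rep(arr$ex, each = arr$n_arrangements)
  dy <- ry - rep(arr$ey, each = arr$n_arrangements)
  bx <- as.vector((dx * abs(dx)) %*% arr$wx_inv) / arr$n
  by <- as.vector((dy * abs(dy)) %*% arr$wy_inv) / arr$m
  (by - bx) / 2
}

bws_directional_one <- function(s, pos_x, n, m, N) {
  pos_y <- setdiff(seq_len(N), pos_x)
  bx <- bws_component(s[pos_x], n, m, N, signed = TRUE)
  by <- bws_component(s[pos_y], m, n, N, signed = TRUE)
  (by - bx) / 2
}

with_local_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Assign patients to age strata
#'
#' Differential methylation is tested within three age strata to adjust
#' for the strong age dependence of the methylome: young (age < 55),
#' medium (55 to 65 inclusive), old (age > 65). Age 55 is assigned to the
#' medium stratum so the three groups partition all ages.
#'
#' @param age Numeric vector of ages in years; must be positive.
#' @return A factor with levels `young`, `medium`, `old`.
#' @examples
#' assign_age_group(c(50, 55, 60, 70))
#' @export
assign_age_group <- function(age) {
  if (any(!is.finite(age)) || any(age <= 0)) {
    stop_dmrlink("ages must be positive finite numbers",
                 "dmrlink_value_error")
  }
  factor(ifelse(age < 55, "young", ifelse(age <= 65, "medium", "old")),
         levels = c("young", "medium", "old"))
}

#' Combine per-stratum one-sided p-values into the T statistic
#'
#' Per-stratum one-sided BWS p-values are combined Fisher-style on the
#' log10 scale: \eqn{T_{side} = -2 \sum \log_{10} p_{side}} over strata,
#' and the final statistic is \eqn{T = \max(T_{left}, T_{right})}, large
#' when either direction of methylation shift is consistently supported
#' across strata.
#'
#' @param p_left,p_right Numeric vectors of per-stratum one-sided
#'   p-values, all in (0, 1].
#' @return A list with `T_left`, `T_right`, and `T`.
#' @examples
#' combined_bws(c(0.1, 0.01, 0.001), c(1, 1, 1))
#' @export
combined_bws <- function(p_left, p_right) {
  p <- c(p_left, p_right)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stop_dmrlink("all p-values must lie in (0, 1]", "dmrlink_value_error")
  }
  tl <- -2 * sum(log10(p_left))
  tr <- -2 * sum(log10(p_right))
  list(T_left = tl, T_right = tr, T = max(tl, tr))
}
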