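# Nonparametric group statistics. Implemented in-package because the exact
# permutation p-value is required also under ties (mid-ranks), which the
# usual exact routines decline; the stats:: versions serve as independent
# cross-checks in the test suite on tie-free inputs.

# exact permutation distribution of the rank sum of the first sample;
# mid-ranks doubled to integers, counted by a subset-sum dynamic program
rank_sum_distribution <- function(s2, n_a) {
  top <- sum(sort(s2, decreasing = TRUE)[seq_len(n_a)])
  f <- matrix(0, nrow = n_a + 1L, ncol = top + 1L)   # f[sz+1, t+1]
  f[1, 1] <- 1
  for (v in s2) {
    for (sz in rev(seq_len(n_a))) {
      idx <- seq_len(top + 1L - v)
      f[sz + 1L, idx + v] <- f[sz + 1L, idx + v] + f[sz, idx]
    }
  }
  f[n_a + 1L, ]   # counts over doubled rank sum t = 0..top
}

#' Mann-Whitney U test
#'
#' U is reported for the first sample. The two-tailed p doubles the exact
#' one-tailed permutation tail (capped at 1) whenever the number of group
#' assignments `choose(n_a + n_b, n_a)` is at most `max_exact`; ties are
#' handled exactly through mid-ranks. Beyond the cutoff a normal
#' approximation with tie correction is used. The complement identity
#' `U_a + U_b = n_a * n_b` always holds.
#'
#' @param a,b Numeric samples (non-empty).
#' @param method `"auto"` (default), `"exact"` or `"normal"`.
#' @param max_exact Assignment-count cutoff for the exact distribution.
#' @return List with `U`, `p`, `method` and a `ties` flag.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, p = 1/3
mann_whitney_u <- function(a, b, method = c("auto", "exact", "normal"),
                           max_exact = 1e7) {
  method <- match.arg(method)
  stopifnot(length(a) >= 1, length(b) >= 1, is.numeric(a), is.numeric(b))
  n_a <- length(a); n_b <- length(b); N <- n_a + n_b
  pooled <- c(a, b)
  r <- rank(pooled)
  ties <- anyDuplicated(pooled) > 0L
  R_a <- sum(r[seq_len(n_a)])
  U_a <- R_a - n_a * (n_a + 1) / 2

  if (length(unique(pooled)) == 1L) {
    return(list(U = U_a, p = 1, method = "degenerate", ties = TRUE))
  }
  if (method == "auto") {
    method <- if (choose(N, n_a) <= max_exact) "exact" else "normal"
  }
  if (method == "exact") {
    s2 <- as.integer(round(2 * r))
    cnt <- rank_sum_distribution(s2, n_a)
    t_obs <- as.integer(round(2 * R_a))
    tvals <- seq_along(cnt) - 1L
    total <- sum(cnt)
    lower <- sum(cnt[tvals <= t_obs]) / total
    upper <- sum(cnt[tvals >= t_obs]) / total
    p <- min(1, 2 * min(lower, upper))
  } else {
    mu <- n_a * n_b / 2
    tie_tab <- table(pooled)
    sigma2 <- n_a * n_b / 12 *
      ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- (U_a - mu) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = U_a, p = p, method = method, ties = ties)
}

permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L))
  p <- permutations_of(n - 1L)
  out <- matrix(0L, n * nrow(p), n)
  for (i in seq_len(n)) {
    rows <- ((i - 1L) * nrow(p) + 1L):(i * nrow(p))
    out[rows, 1] <- i
    rest <- seq_len(n)[-i]
    out[rows, -1] <- matrix(rest[p], nrow(p))
  }
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The two-tailed p is an
#' exact permutation p for `n <= exact_n` (full enumeration of rank
#' permutations) and a t-approximation with `n - 2` degrees of freedom
#' otherwise.
#'
#' @param x,y Numeric vectors of equal length >= 3; constant input is an
#'   error (the correlation is undefined).
#' @param exact_n Largest n for which the permutation distribution is
#'   enumerated.
#' @return List with `rho`, `p` and `method`.
#' @export
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))
spearman_rho <- function(x, y, exact_n = 8L) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("correlation undefined for constant input", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= exact_n) {
    pm <- permutations_of(n)
    R <- matrix(ry[pm], nrow(pm))
    cx <- rx - mean(rx)
    num <- as.numeric((R - mean(ry)) %*% cx)
    rho_perm <- num / ((n - 1) * stats::sd(rx) * stats::sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- min(1, 2 * stats::pt(-abs(tstat), df = n - 2))
    method <- "t-approximation"
  }
  list(rho = rho, p = p, method = method)
}
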