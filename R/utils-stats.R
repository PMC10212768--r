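#' Spearman rank correlation with exact small-sample p-value
#'
#' Computes Spearman's rank correlation between two vectors on
#' pairwise-complete observations. For `n <= exact_n` the two-sided p-value
#' is obtained by full enumeration of all `n!` permutations of one ranking
#' (the exact null distribution); for larger `n` the usual t approximation
#' `t = rho * sqrt((n-2)/(1-rho^2))` on `n - 2` degrees of freedom is used.
#' P-values are floored at 1e-300 so that signed log10 transforms stay finite.
#'
#' @param x,y Numeric vectors of equal length.
#' @param exact_n Largest sample size for which the permutation null is
#'   enumerated exactly (default 8; 8! = 40320 permutations).
#' @return A list with elements `rho`, `p`, `n` (complete pairs) and
#'   `signed_logp` = sign(rho) * (-log10 p).
#' @export
spearman_test <- function(x, y, exact_n = 8L) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) {
    return(list(rho = NA_real_, p = NA_real_, n = n, signed_logp = NA_real_))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (is.na(rho)) {
    return(list(rho = NA_real_, p = NA_real_, n = n, signed_logp = NA_real_))
  }
  if (n <= exact_n) {
    p <- spearman_perm_p(x, y, rho)
  } else {
    if (abs(rho) >= 1) {
      p <- 1e-300
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
    }
  }
  p <- max(p, 1e-300)
  list(rho = rho, p = p, n = n,
       signed_logp = sign(rho) * (-log10(p)))
}

# Exact two-sided permutation p-value for Spearman's rho: the fraction of
# the n! permutations of one ranking whose |rho| >= |observed| (within a
# numeric tolerance to keep ties on the discrete grid honest).
spearman_perm_p <- function(x, y, rho_obs) {
  rx <- rank(x)
  ry <- rank(y)
  perms <- all_permutations(length(y))
  denom_x <- stats::sd(rx)
  # rho for each permutation of the y-ranking against the fixed x-ranking
  rhos <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# All permutations of 1..n as an (n!) x n integer matrix; n <= 8 by contract.
all_permutations <- function(n) {
  stopifnot(n >= 1L, n <= 9L)
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (pos in seq_len(n)) {
    block <- matrix(0L, nrow(sub), n)
    block[, pos] <- n
    block[, -pos] <- sub
    out[[pos]] <- block
  }
  do.call(rbind, out)
}

#' Storey q-values
#'
#' False-discovery-rate q-values with a smoother-based estimate of the null
#' proportion pi0. pi0(lambda) = #\{p > lambda\} / (m (1 - lambda)) is
#' evaluated on the grid lambda = 0.05, 0.10, ..., 0.95 and smoothed with a
#' cubic smoothing spline (df = 3); the estimate at the largest lambda,
#' clipped to (0, 1], is used. q-values are the usual step-up minima and are
#' monotone in p.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NA allowed, propagated).
#' @param method `"storey"` (default) or `"bh"` for Benjamini-Hochberg.
#' @return Numeric vector of q-values, same length/order as `p`.
#' @export
storey_qvalue <- function(p, method = c("storey", "bh")) {
  method <- match.arg(method)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  pv <- p[ok]
  m <- length(pv)
  if (m == 0L) return(q)
  stopifnot(all(pv >= 0 & pv <= 1))
  if (method == "bh") {
    q[ok] <- stats::p.adjust(pv, method = "BH")
    return(q)
  }
  lam <- seq(0.05, 0.95, by = 0.05)
  pi0_lam <- vapply(lam, function(l) mean(pv > l) / (1 - l), numeric(1))
  if (m >= 10L && stats::var(pi0_lam) > 0) {
    fit <- stats::smooth.spline(lam, pi0_lam, df = 3)
    pi0 <- stats::predict(fit, x = max(lam))$y
  } else {
    pi0 <- min(pi0_lam[length(pi0_lam)], 1)
  }
  pi0 <- min(max(pi0, 1 / m), 1)  # guard degenerate estimates
  ord <- order(pv, decreasing = TRUE)
  qv <- numeric(m)
  running <- 1
  for (i in seq_along(ord)) {
    j <- ord[i]
    rank_j <- m - i + 1L
    running <- min(running, pi0 * m * pv[j] / rank_j)
    qv[j] <- running
  }
  q[ok] <- qv
  q
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions (up to label permutation), ~0 for independent
#' ones.
#'
#' @param a,b Vectors of cluster labels (any type), equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxidx <- (si + sj) / 2
  if (maxidx == expected) return(1)
  (sij - expected) / (maxidx - expected)
}

# Internal: seeded RNG scope. Runs `expr` under a local RNG state derived
# from `seed`, restoring the caller's RNG afterwards.
with_seed <- function(seed, expr) {
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
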