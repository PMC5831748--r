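# Gene-set overlap enrichment by Monte Carlo randomization.
#
# The expected seesaw overlap is estimated by drawing, in each replicate,
# two gene sets of the observed sizes uniformly without replacement from
# the universe and recording their intersection size. The closed-form
# hypergeometric mean/variance serve as an analytic oracle: the overlap of
# two independent uniform subsets of sizes n1, n2 from N genes is
# hypergeometric with mean n1*n2/N.

#' Simulated null distribution of the overlap of two random gene sets
#'
#' Each of `S` replicates draws two independent uniform subsets of sizes
#' `n1` and `n2` (without replacement) from an `N`-element universe and
#' records the size of their intersection.
#'
#' @param n1,n2 set sizes (0 <= n <= N).
#' @param N universe size (>= 1).
#' @param S number of simulations (default 10000).
#' @param seed integer seed for the simulation stream.
#' @return list with integer vector `overlaps` (length `S`), `null_mean`,
#'   `null_sd`, and the analytic `expected_mean`/`expected_var`.
#' @export
mc_overlap_null <- function(n1, n2, N, S = 10000, seed = 1) {
  if (n1 < 0 || n2 < 0 || n1 > N || n2 > N) {
    abort("set sizes must lie in [0, N]")
  }
  if (S < 1) abort("'S' must be >= 1")
  set.seed(seed)
  in_a <- logical(N)
  overlaps <- integer(S)
  for (s in seq_len(S)) {
    a <- sample.int(N, n1)
    in_a[a] <- TRUE
    overlaps[s] <- sum(in_a[sample.int(N, n2)])
    in_a[a] <- FALSE
  }
  exp_mv <- hypergeometric_expected(n1, n2, N)
  list(
    overlaps = overlaps,
    null_mean = mean(overlaps),
    null_sd = stats::sd(overlaps),
    expected_mean = exp_mv[["mean"]],
    expected_var = exp_mv[["variance"]]
  )
}

#' Closed-form mean and variance of the null overlap
#'
#' Mean `n1*n2/N` and hypergeometric variance
#' `n1*(n2/N)*(1-n2/N)*(N-n1)/(N-1)` of the intersection size of two
#' independent uniform subsets (variance 0 when N = 1).
#'
#' @inheritParams mc_overlap_null
#' @return named numeric vector `c(mean=, variance=)`.
#' @examples
#' hypergeometric_expected(5, 5, 10)  # mean 2.5, variance ~0.694
#' @export
hypergeometric_expected <- function(n1, n2, N) {
  if (N < 1) abort("'N' must be >= 1")
  if (n1 < 0 || n2 < 0 || n1 > N || n2 > N) {
    abort("set sizes must lie in [0, N]")
  }
  m <- n1 * n2 / N
  v <- if (N == 1) 0 else n1 * (n2 / N) * (1 - n2 / N) * (N - n1) / (N - 1)
  c(mean = m, variance = v)
}

#' Overlap enrichment of two gene sets against a randomization null
#'
#' Observed overlap `k_obs = |A intersect B|` compared with the Monte Carlo
#' null of [mc_overlap_null()]; fold enrichment is `k_obs / null_mean` and
#' the empirical p-value is the fraction of replicates with simulated
#' overlap >= `k_obs` (reported as "< 1/S" when no replicate reaches it).
#'
#' @param set_a,set_b character vectors of gene ids, subsets of `universe`.
#' @param universe character vector, the gene universe for the null.
#' @param S number of simulations (default 10000).
#' @param seed integer seed.
#' @return object of class `overlap_enrichment`: list with `n1`, `n2`, `N`,
#'   `k_obs`, `S`, `null_mean`, `null_sd`, `fold`, `p_value` (0 when no
#'   exceedances), `p_string` (e.g. `"< 1e-04"`), `seed`.
#' @export
overlap_enrichment <- function(set_a, set_b, universe, S = 10000, seed = 1) {
  if (length(universe) == 0L) abort("'universe' must be non-empty")
  universe <- unique(universe)
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("both sets must be subsets of the universe")
  }
  k_obs <- length(intersect(set_a, set_b))
  null <- mc_overlap_null(length(set_a), length(set_b), length(universe),
                          S = S, seed = seed)
  exceed <- sum(null$overlaps >= k_obs)
  fold <- if (null$null_mean > 0) k_obs / null$null_mean else NaN
  structure(
    list(
      n1 = length(set_a), n2 = length(set_b), N = length(universe),
      k_obs = k_obs, S = S,
      null_mean = null$null_mean, null_sd = null$null_sd,
      fold = fold,
      p_value = exceed / S,
      p_string = if (exceed == 0) {
        paste0("< ", format(1 / S, scientific = TRUE, digits = 3))
      } else {
        format(exceed / S, digits = 4)
      },
      seed = seed
    ),
    class = "overlap_enrichment"
  )
}

#' @export
print.overlap_enrichment <- function(x, ...) {
  cat("Overlap enrichment (Monte Carlo, S =", x$S, ")\n")
  cat("  |A| =", x$n1, " |B| =", x$n2, " N =", x$N, "\n")
  cat("  observed overlap:", x$k_obs, "\n")
  cat(sprintf("  null mean %.3f (sd %.3f)\n", x$null_mean, x$null_sd))
  cat(sprintf("  fold enrichment: %.2f, p %s\n", x$fold, x$p_string))
  invisible(x)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by hypergeometric enumeration: the sum of
#' probabilities of all tables with the observed margins whose point
#' probability does not exceed that of the observed table (up to a relative
#' tolerance of 1e-7, the standard convention).
#'
#' @param a,b,c,d the four cell counts, `matrix(c(a, c, b, d), 2)` layout
#'   `rbind(c(a, b), c(c, d))`; all >= 0, total > 0.
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisher_two_tailed(5, 5, 5, 5)   # 1
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    abort("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) abort("all-zero table")
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  k <- a + c          # column 1 margin
  lo <- max(0L, k - n)
  hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
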