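#' Hypergeometric set-overlap enrichment
#'
#' Upper-tail probability P(X >= k) that two gene sets of sizes K and n
#' drawn from a universe of N genes share at least k members, with X ~
#' Hypergeometric(N, K, n). Computed in log space so extreme tails
#' (e.g. p ~ 1e-46) are exact to machine precision. Also reports the
#' expected overlap n * K / N and the fold enrichment k / expected.
#'
#' @param N universe size.
#' @param K size of set A.
#' @param n size of set B.
#' @param k observed overlap |A intersect B|.
#' @return list: `p`, `log10_p`, `expected`, `fold_enrichment`.
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  for (nm in c("N", "K", "n", "k")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 ||
        v != round(v)) {
      stop("invalid count '", nm, "': must be a nonnegative integer")
    }
  }
  if (K > N) stop("invalid count 'K': exceeds universe size N")
  if (n > N) stop("invalid count 'n': exceeds universe size N")
  if (k > min(K, n)) stop("invalid count 'k': exceeds min(K, n)")
  logp <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE,
                        log.p = TRUE)
  expected <- n * K / N
  list(p = exp(logp), log10_p = logp / log(10), expected = expected,
       fold_enrichment = if (expected > 0) k / expected else NA_real_)
}

#' One-sided two-proportion test with continuity correction
#'
#' Pooled-variance chi-squared test of x1/n1 vs x2/n2 with the Yates
#' continuity correction c = min(0.5 * (1/n1 + 1/n2), |p1 - p2|), which
#' clamps the statistic to 0 at near-equal proportions. The one-sided
#' p-value is half the upper chi-squared(1) tail when the observed
#' direction matches the alternative, else 1 minus half the tail.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @param alternative "greater" (p1 > p2), "less", or "two.sided".
#' @param correct apply the continuity correction (default TRUE).
#' @return list: `chi_squared`, `df` (1), `p`, `p1`, `p2`, `degenerate`
#'   (TRUE when the pooled proportion is 0 or 1).
#' @export
two_proportion_test <- function(x1, n1, x2, n2,
                                alternative = c("greater", "less",
                                                "two.sided"),
                                correct = TRUE) {
  alternative <- match.arg(alternative)
  if (n1 <= 0 || n2 <= 0) stop("trial counts must be positive")
  if (x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2) {
    stop("successes must lie in [0, trials]")
  }
  p1 <- x1 / n1
  p2 <- x2 / n2
  pp <- (x1 + x2) / (n1 + n2)
  if (pp <= 0 || pp >= 1) {
    return(list(chi_squared = 0, df = 1, p = 1, p1 = p1, p2 = p2,
                degenerate = TRUE))
  }
  d <- abs(p1 - p2)
  cc <- if (correct) min(0.5 * (1 / n1 + 1 / n2), d) else 0
  chi <- (d - cc)^2 / (pp * (1 - pp) * (1 / n1 + 1 / n2))
  tail <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  p <- switch(alternative,
    two.sided = tail,
    greater = if (p1 >= p2) tail / 2 else 1 - tail / 2,
    less = if (p1 <= p2) tail / 2 else 1 - tail / 2)
  list(chi_squared = chi, df = 1, p = p, p1 = p1, p2 = p2,
       degenerate = FALSE)
}

#' Overlap bookkeeping percentages
#'
#' The percentage summaries used in reporting an overlap table: the
#' share of set B that falls in set A (k/n), the share of the universe
#' in set A (K/N), and the share of set A that falls in set B (k/K).
#' Values are returned unrounded; `round_pct()` applies the reporting
#' conventions (nearest integer for prose, one decimal for tables).
#'
#' @param N,K,n,k overlap counts as in [hypergeom_enrichment()].
#' @return list: `pct_B_in_A` (100 * k/n), `pct_A_in_universe`
#'   (100 * K/N), `pct_A_in_B` (100 * k/K), and `pct_B_in_universe`
#'   (100 * n/N).
#' @export
summarize_overlap <- function(N, K, n, k) {
  he <- hypergeom_enrichment(N, K, n, k)  # validates the counts
  list(pct_B_in_A = 100 * k / n,
       pct_A_in_universe = 100 * K / N,
       pct_A_in_B = 100 * k / K,
       pct_B_in_universe = 100 * n / N,
       enrichment = he)
}

#' Reporting rounding conventions for percentages
#'
#' @param x percentage values.
#' @param digits 0 for prose (nearest integer), 1 for tables.
#' @return rounded values.
#' @export
round_pct <- function(x, digits = 0) round(x, digits)
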