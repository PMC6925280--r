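#' Liability-scale conversion parameters
#'
#' @param K Population prevalence of the binary trait, in (0, 1).
#' @param P Case proportion in the analysed sample, in (0, 1); equals `K`
#'   for an unselected cohort.
#' @param h2_grid Plausible trait heritabilities for
#'   [explained_heritability()] (default 0.1 to 0.4).
#' @return A `liability_params` list.
#' @export
liability_params <- function(K, P = K, h2_grid = seq(0.1, 0.4, by = 0.1)) {
  assert_number(K, "K", 0, 1, open_lower = TRUE, open_upper = TRUE)
  assert_number(P, "P", 0, 1, open_lower = TRUE, open_upper = TRUE)
  if (any(h2_grid <= 0 | h2_grid >= 1)) {
    stop_validation("h2_grid values must lie in (0, 1)")
  }
  structure(list(K = K, P = P, h2_grid = h2_grid),
            class = "liability_params")
}

#' Multiplicative factor of the linear threshold-model transform
#'
#' `K(1-K)/z^2` for the population term, times `K(1-K)/(P(1-P))` for
#' case-control ascertainment; `z` is the standard-normal density at the
#' liability threshold.
#'
#' @param K Population prevalence in (0, 1).
#' @param P Sample case proportion in (0, 1).
#' @return The observed-to-liability multiplicative factor.
#' @export
liability_factor <- function(K, P) {
  t <- qnorm(1 - K)
  z <- dnorm(t)
  K * (1 - K) / z^2 * K * (1 - K) / (P * (1 - P))
}

#' Convert observed-scale variance explained to the liability scale
#'
#' Transforms an observed-scale (0/1 regression) R-squared to the
#' liability scale under the normal threshold model with population
#' prevalence `K` and sample case proportion `P`.
#'
#' `method = "linear"` applies the multiplicative factor
#' `K(1-K)/z^2 * K(1-K)/(P(1-P))` where `z` is the standard-normal
#' density at the liability threshold `qnorm(1 - K)`; with `P = K` it
#' reduces to the classic `K(1-K)/z^2` factor. `method = "corrected"`
#' additionally applies the ascertainment correction
#' `R2_l = C R2 / (1 + C theta R2)` with
#' `theta = i (P-K)/(1-K) (i (P-K)/(1-K) - t)` and mean case liability
#' `i = z/K`; the two methods coincide when `P = K`.
#'
#' @param r2_observed Observed-scale R-squared in \[0, 1).
#' @param params A [liability_params()].
#' @param method `"linear"` (default) or `"corrected"`.
#' @return Liability-scale R-squared.
#' @export
r2_to_liability <- function(r2_observed, params,
                            method = c("linear", "corrected")) {
  method <- match.arg(method)
  assert_number(r2_observed, "r2_observed", 0, 1, open_upper = TRUE)
  K <- params$K
  P <- params$P
  C <- liability_factor(K, P)
  if (method == "linear") {
    return(C * r2_observed)
  }
  t <- qnorm(1 - K)
  i <- dnorm(t) / K
  d <- i * (P - K) / (1 - K)
  theta <- d * (d - t)
  C * r2_observed / (1 + C * theta * r2_observed)
}

#' Fraction of heritability explained across a grid of h2 values
#'
#' Divides a liability-scale R-squared by each assumed trait heritability,
#' giving the fraction of heritable variance captured by the score;
#' monotone decreasing in h2.
#'
#' @param r2_liability Liability-scale R-squared.
#' @param h2_grid Heritability values in (0, 1).
#' @return Named vector of fractions (`r2_liability / h2`).
#' @export
explained_heritability <- function(r2_liability, h2_grid) {
  if (any(h2_grid <= 0 | h2_grid >= 1)) {
    stop_validation("h2 values must lie in (0, 1)")
  }
  assert_number(r2_liability, "r2_liability", 0, 1)
  setNames(r2_liability / h2_grid, sprintf("h2=%g", h2_grid))
}
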