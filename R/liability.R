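#' Liability-threshold model quantities
#'
#' For prevalence `K` the liability threshold is `t = qnorm(1 - K)`; with
#' `z = dnorm(t)` the mean liability of cases is `i = z/K` and of controls
#' `i2 = -z/(1 - K)`. `v` is the proportion of liability variance explained
#' by a risk score.
#'
#' @param K Disease prevalence in (0, 0.5).
#' @param v Liability variance explained by the score, in `[0, 1)`.
#' @return List of class `liability_spec` with `K`, `t`, `z`, `i`, `i2`, `v`.
#' @export
liability_spec <- function(K, v = NA_real_) {
  if (K <= 0 || K >= 0.5) stop("K must lie in (0, 0.5)")
  if (!is.na(v) && (v < 0 || v >= 1)) stop("v must lie in [0, 1)")
  t <- stats::qnorm(1 - K)
  z <- stats::dnorm(t)
  structure(list(K = K, t = t, z = z, i = z / K, i2 = -z / (1 - K), v = v),
            class = "liability_spec")
}

#' AUC implied by a score explaining liability variance v
#'
#' Under the liability-threshold model a score explaining a fraction `v` of
#' liability variance has case/control score means `v*i` and `v*i2` and
#' within-class variances `v(1 - v*i*(i - t))` and `v(1 - v*i2*(i2 - t))`;
#' the AUC is the normal orthant probability of a random case outscoring a
#' random control.
#'
#' @param v Liability variance explained, in `[0, 1)`.
#' @param K Prevalence.
#' @return The implied AUC in `[0.5, 1)`.
#' @export
liability_auc <- function(v, K) {
  s <- liability_spec(K)
  if (v == 0) return(0.5)
  num <- (s$i - s$i2) * v
  den <- sqrt(v * (1 - v * s$i * (s$i - s$t)) +
                v * (1 - v * s$i2 * (s$i2 - s$t)))
  stats::pnorm(num / den)
}

#' Liability variance explained implied by an observed AUC
#'
#' Inverts [liability_auc()] by bracketed root-finding on `v` in `[0, 1)`;
#' the relation is monotone in `v` at fixed prevalence.
#'
#' @param auc Observed AUC in `[0.5, 1)`.
#' @param K Prevalence.
#' @return A [liability_spec()] with `v` filled in.
#' @export
auc_to_liability_v <- function(auc, K) {
  if (auc < 0.5) stop("AUC below 0.5; fix score orientation upstream")
  if (auc >= 1) stop("AUC must be below 1")
  if (auc == 0.5) return(liability_spec(K, 0))
  f <- function(v) liability_auc(v, K) - auc
  v <- stats::uniroot(f, c(1e-12, 1 - 1e-9), tol = 1e-12)$root
  liability_spec(K, v)
}

#' Expected top-vs-bottom-decile odds ratio under the liability model
#'
#' Converts an observed AUC into the liability variance `v` explained by the
#' score, integrates the disease probability
#' `P(case | score z) = pnorm((sqrt(v) z - t)/sqrt(1 - v))` over each decile
#' of the standard-normal score distribution by adaptive quadrature, and
#' returns the odds ratio contrasting the top and bottom deciles. Two
#' Monte-Carlo cross-check modes are included: `"mc"` integrates the same
#' conditional risk over simulated scores (low variance, checks the
#' quadrature), `"liability_sim"` simulates the full bivariate
#' score/liability pair and thresholds it (fully generative, checks the
#' model; needs a prevalence large enough to populate the bottom decile
#' with cases).
#'
#' @param auc Observed AUC in `[0.5, 1)`.
#' @param K Prevalence.
#' @param deciles Pair of decile indices to contrast (default `c(10, 1)`).
#' @param method `"quadrature"` (default), `"mc"` or `"liability_sim"`.
#' @param n_mc Monte-Carlo draws for the stochastic modes.
#' @param seed Optional seed for the stochastic modes.
#' @return The expected odds ratio (1 when `auc = 0.5`).
#' @export
expected_decile_or <- function(auc, K, deciles = c(10, 1),
                               method = c("quadrature", "mc",
                                          "liability_sim"),
                               n_mc = 1e7, seed = NULL) {
  method <- match.arg(method)
  s <- auc_to_liability_v(auc, K)
  if (s$v == 0) return(1)
  if (method == "quadrature") {
    pd <- vapply(deciles, function(d) decile_risk(s, d), numeric(1))
    return((pd[1] / (1 - pd[1])) / (pd[2] / (1 - pd[2])))
  }
  if (!is.null(seed)) set.seed(seed)
  z <- stats::rnorm(n_mc)
  dec <- findInterval(stats::pnorm(z) * 10, 0:9)  # 1..10 by score decile
  if (method == "mc") {
    risk <- stats::pnorm((sqrt(s$v) * z - s$t) / sqrt(1 - s$v))
    p1 <- mean(risk[dec == deciles[2]])
    p10 <- mean(risk[dec == deciles[1]])
  } else {
    liab <- sqrt(s$v) * z + sqrt(1 - s$v) * stats::rnorm(n_mc)
    case <- liab > s$t
    p1 <- mean(case[dec == deciles[2]])
    p10 <- mean(case[dec == deciles[1]])
  }
  (p10 / (1 - p10)) / (p1 / (1 - p1))
}

# disease probability within decile d of the standard-normal score
decile_risk <- function(spec, d) {
  lo <- stats::qnorm((d - 1) / 10)
  hi <- stats::qnorm(d / 10)
  f <- function(z) {
    stats::pnorm((sqrt(spec$v) * z - spec$t) / sqrt(1 - spec$v)) *
      stats::dnorm(z)
  }
  val <- stats::integrate(f, lo, hi, rel.tol = 1e-10, abs.tol = 0)
  if (val$message != "OK") stop("quadrature failed: ", val$message)
  10 * val$value
}
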