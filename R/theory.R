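#' Asymptotic mean degree
#'
#' Balances edge gains and losses per unit time: each step adds one node
#' with `c` edges and `m` internal edges, removes on average
#' \eqn{r\langle k\rangle} edges with a deleted node and \eqn{q m} deleted
#' edges, while the node count grows by \eqn{1 - r}. Solving
#' \eqn{\langle k\rangle (1-r) = 2(c + m - r\langle k\rangle - q m)} gives
#' \deqn{\langle k \rangle = \frac{2\,(c + m(1-q))}{1 + r}.}
#'
#' @param params an `evo_params` object.
#' @return The asymptotic mean degree (positive real).
#' @examples
#' mean_degree(evo_params(c = 3, m = 2))                    # 10
#' mean_degree(evo_params(c = 3, m = 2, r = 0.2, q = 0.1))  # 8
#' @export
mean_degree <- function(params) {
  params <- validate_params(params)
  2 * (params$c + params$m * (1 - params$q)) / (1 + params$r)
}

#' Aggregate flow coefficients of the degree rate equation
#'
#' Assembles, at the analytic mean degree, the coefficients through which
#' the four processes enter the stationary rate equation:
#' \describe{
#'   \item{A, B}{kernel normalizations \eqn{A = (a + b\langle k\rangle)^{-1}},
#'     \eqn{B = (s + t\langle k\rangle)^{-1}}.}
#'   \item{phi}{total preferential inflow \eqn{\Phi = cAb + 2mBt}, the
#'     coefficient of the degree-proportional gain.}
#'   \item{psi}{total random inflow \eqn{\Psi = cAa + 2mBs}.}
#'   \item{dee}{per-degree loss rate from deletion,
#'     \eqn{D = r + 2qm/\langle k\rangle}.}
#' }
#'
#' @param params an `evo_params` object.
#' @return A list of class `aggregate_rates` with fields `A`, `B`, `phi`,
#'   `psi`, `dee`, `mean_degree`.
#' @export
aggregate_rates <- function(params) {
  params <- validate_params(params)
  kbar <- mean_degree(params)
  A <- 1 / (params$a + params$b * kbar)
  B <- if (params$m > 0) 1 / (params$s + params$t * kbar) else NA_real_
  int_pref <- if (params$m > 0) 2 * params$m * B * params$t else 0
  int_rand <- if (params$m > 0) 2 * params$m * B * params$s else 0
  structure(list(
    A = A, B = B,
    phi = params$c * A * params$b + int_pref,
    psi = params$c * A * params$a + int_rand,
    dee = params$r + if (kbar > 0) 2 * params$q * params$m / kbar else 0,
    mean_degree = kbar), class = "aggregate_rates")
}

#' @export
print.aggregate_rates <- function(x, ...) {
  cat(sprintf(
    "Rate-equation coefficients: <k> = %.4f, Phi = %.4f, Psi = %.4f, D = %.4f\n",
    x$mean_degree, x$phi, x$psi, x$dee))
  invisible(x)
}

#' Predicted degree exponent
#'
#' In the power-law regime (\eqn{\Phi > D}) the large-`k` expansion of the
#' stationary rate equation under the ansatz \eqn{p_k = C k^{-\gamma}\Omega^k}
#' with \eqn{\Omega = 1} gives
#' \deqn{\gamma = 1 + \frac{1}{\Phi - D}.}
#' Without deletion this is \eqn{1 + 1/\Phi}; pure external preferential
#' attachment (\eqn{\Phi = 1/2}) recovers \eqn{\gamma = 3}. With only
#' external preferential attachment and node deletion it reduces to
#' \eqn{1 + 2/(1-r)}, which diverges as \eqn{r \to 1}: the divergence is
#' returned as `Inf`, not an error, so phase grids can render it.
#'
#' @param params an `evo_params` object.
#' @return The degree exponent (possibly `Inf`); `Phi <= D` (the
#'   exponential phase, where no power-law exponent exists) signals an error.
#' @examples
#' predict_exponent(evo_params(c = 3, a = 0, b = 1))  # 3
#' @export
predict_exponent <- function(params) {
  ar <- aggregate_rates(params)
  gap <- ar$phi - ar$dee
  if (gap <= 0)
    stop("Phi <= D: exponential phase, no power-law exponent ",
         sprintf("(Phi = %.6g, D = %.6g)", ar$phi, ar$dee), call. = FALSE)
  1 + 1 / gap
}

#' Predicted small-degree shift of the pure-growth distribution
#'
#' For pure growth (`r = q = 0`) the stationary solution is a shifted power
#' law \eqn{p_k \sim (k + k_0)^{-\gamma}} with \eqn{k_0 = \Psi / \Phi}: the
#' shift that makes the exact recurrence ratio equal
#' \eqn{(k - 1 + k_0) / (k + k_0 + 1/\Phi)}. Pure preferential attachment
#' (\eqn{a = s = 0}) has \eqn{k_0 = 0}; the shift grows with the random
#' attachment strengths, producing the small-degree saturation seen in real
#' networks.
#'
#' @param params an `evo_params` object with `r = q = 0`.
#' @return The shift \eqn{k_0 \ge 0}.
#' @export
predict_shift <- function(params) {
  params <- validate_params(params)
  if (params$r != 0 || params$q != 0)
    stop("k0 is defined for pure growth only (r = q = 0); with deletion, ",
         "obtain a shift by fitting (see fit_tail)", call. = FALSE)
  ar <- aggregate_rates(params)
  ar$psi / ar$phi
}

#' Exact stationary degree distribution under pure growth
#'
#' For `r = q = 0` the stationary rate equation closes into a two-term
#' recurrence solvable exactly:
#' \deqn{p_k = 0 \ (k < c), \quad p_c = \frac{1}{1 + \Phi c + \Psi}, \quad
#'   p_k = \frac{\Phi (k-1) + \Psi}{1 + \Phi k + \Psi}\, p_{k-1} \ (k > c),}
#' the finite form of the Beta-function solution; its large-`k` ratio
#' matches \eqn{(k + k_0)^{-\gamma}} with \eqn{\gamma = 1 + 1/\Phi},
#' \eqn{k_0 = \Psi/\Phi}.
#'
#' @param params an `evo_params` object with `r = q = 0`.
#' @param k_max truncation degree.
#' @param normalize renormalize over the truncated support (default `TRUE`);
#'   with `FALSE` the raw recurrence values are kept, whose total mass
#'   approaches 1 as `k_max` grows.
#' @return A `degree_distribution` with source `"closed_form"`.
#' @examples
#' d <- exact_pure_growth_pk(evo_params(c = 3, a = 0, b = 1), k_max = 100)
#' d$prob[d$k == 3]  # 0.4
#' @export
exact_pure_growth_pk <- function(params, k_max = 10000, normalize = TRUE) {
  params <- validate_params(params)
  if (params$r != 0 || params$q != 0)
    stop("exact closed form requires pure growth (r = q = 0)", call. = FALSE)
  ar <- aggregate_rates(params)
  cc <- as.integer(params$c)
  stopifnot(k_max >= cc)
  p <- numeric(k_max + 1)
  p[cc + 1] <- 1 / (1 + ar$phi * cc + ar$psi)
  if (k_max > cc) {
    for (k in (cc + 1):k_max)
      p[k + 1] <- (ar$phi * (k - 1) + ar$psi) * p[k] /
        (1 + ar$phi * k + ar$psi)
  }
  d <- degree_distribution(0:k_max, p, source = "closed_form",
                           normalize = isTRUE(normalize))
  attr(d, "raw_mass") <- sum(p)
  d
}

#' Exponential correction factor of the degree tail
#'
#' Under deletion the tail ansatz \eqn{p_k = C k^{-\gamma} \Omega^k} admits
#' the nontrivial solution \eqn{\Omega = \Phi / D}. A ratio below 1 is
#' normalizable and yields an exponentially decaying tail; a ratio of 1 or
#' more is not a normalizable correction, so the valid solution is
#' \eqn{\Omega = 1} (pure power law). The returned value is clipped to 1
#' with the raw ratio reported alongside.
#'
#' @param params an `evo_params` object.
#' @return A number of class `omega_factor`: the clipped \eqn{\Omega}, with
#'   attribute `raw_ratio` (`Inf` when `D = 0`).
#' @export
omega_factor <- function(params) {
  ar <- aggregate_rates(params)
  raw <- if (ar$dee > 0) ar$phi / ar$dee else Inf
  structure(min(raw, 1), raw_ratio = raw, class = "omega_factor")
}

#' @export
print.omega_factor <- function(x, ...) {
  cat(sprintf("Omega = %.6g (raw ratio Phi/D = %.6g)\n",
              unclass(x), attr(x, "raw_ratio")))
  invisible(x)
}

#' Critical boundaries of the phase diagram
#'
#' In the regime where the boundaries are defined — `b = t = 1` with equal
#' random strengths `a = s` — the phase structure in `a` at fixed
#' `(c, m, r, q)` is governed by three critical values:
#' \describe{
#'   \item{a_c}{solves \eqn{\Omega(a) = 1}:
#'     \eqn{a_c = (c + 2m)/D - \langle k\rangle}. Above it the distribution
#'     is exponential, below it a power law; exactly at it, a stretched
#'     exponential.}
#'   \item{a_tilde_c}{solves \eqn{\gamma(a) = 3}:
#'     \eqn{\tilde a_c = (c + 2m)/(D + 1/2) - \langle k\rangle}. Below it
#'     \eqn{2 < \gamma \le 3} (infinite variance); it may be negative,
#'     meaning that phase is absent.}
#'   \item{r_c}{the node-deletion rate where \eqn{\tilde a_c = 0}, i.e.
#'     where deleted links (\eqn{r\langle k\rangle + 2mq}) match the
#'     internal links added (\eqn{2m}): \eqn{r_c = m(1-q)/c}.}
#' }
#'
#' @param params an `evo_params` object with `b = t = 1` (the values of
#'   `a`, `s` in `params` are ignored; boundaries are in the `a = s`
#'   convention).
#' @return A list with `a_c` (`Inf` when `r = q = 0`), `a_tilde_c`, `r_c`.
#' @examples
#' phase_boundaries(evo_params(c = 3, m = 2, r = 0.2, q = 0.1,
#'                             a = 0.5, b = 1, s = 0.5, t = 1))
#' @export
phase_boundaries <- function(params) {
  params <- validate_params(params)
  if (params$b != 1 || (params$m > 0 && params$t != 1))
    stop("phase boundaries are defined for b = t = 1", call. = FALSE)
  kbar <- mean_degree(params)  # independent of a, s
  D <- params$r + if (kbar > 0) 2 * params$q * params$m / kbar else 0
  a_c <- if (D > 0) (params$c + 2 * params$m) / D - kbar else Inf
  a_tilde_c <- (params$c + 2 * params$m) / (D + 0.5) - kbar
  r_c <- params$m * (1 - params$q) / params$c
  list(a_c = a_c, a_tilde_c = a_tilde_c, r_c = r_c)
}

#' Classify the degree-distribution phase
#'
#' In the `b = t = 1`, `a = s` regime, positions `a` relative to the
#' critical values of [phase_boundaries()]:
#' `a > a_c` exponential; `a = a_c` (within 1e-9) critical stretched
#' exponential; `a_tilde_c < a < a_c` power law with finite variance
#' (\eqn{\gamma > 3}); `a <= a_tilde_c` power law with infinite variance
#' (\eqn{2 < \gamma \le 3}).
#'
#' @param params an `evo_params` object with `b = t = 1` and `a = s`
#'   (for `m > 0`).
#' @return One of `"exponential"`, `"critical_stretched"`,
#'   `"powerlaw_finite_variance"`, `"powerlaw_infinite_variance"`.
#' @export
classify_phase <- function(params) {
  params <- validate_params(params)
  if (params$m > 0 && params$a != params$s)
    stop("phase classification assumes a = s", call. = FALSE)
  bd <- phase_boundaries(params)
  a <- params$a
  if (is.finite(bd$a_c) && abs(a - bd$a_c) < 1e-9) return("critical_stretched")
  if (a > bd$a_c) return("exponential")
  if (a > bd$a_tilde_c) return("powerlaw_finite_variance")
  "powerlaw_infinite_variance"
}

#' Phase diagram over a deletion-parameter grid
#'
#' Classifies every point of an `a` grid crossed with a grid in one deletion
#' parameter (`r` or `q`), holding the other fixed, and returns the critical
#' boundary curves alongside — the computation behind the three-phase
#' diagram (exponential / finite-variance power law / infinite-variance
#' power law).
#'
#' @param c,m integer structural parameters.
#' @param axis which deletion parameter spans the grid: `"r"` or `"q"`.
#' @param fixed_other the value of the other deletion parameter.
#' @param a_values numeric grid of random-attachment strengths (`a = s`).
#' @param axis_values numeric grid for the chosen deletion parameter.
#' @return A list with `grid` (data frame: `a`, `axis_value`, `phase`,
#'   `gamma`, `omega_raw`) and `boundaries` (data frame: `axis_value`,
#'   `a_c`, `a_tilde_c`).
#' @export
phase_grid <- function(c, m, axis = c("r", "q"), fixed_other = 0,
                       a_values, axis_values) {
  axis <- match.arg(axis)
  rows <- list(); brows <- list()
  for (x in axis_values) {
    r <- if (axis == "r") x else fixed_other
    q <- if (axis == "q") x else fixed_other
    p0 <- evo_params(c = c, m = m, r = r, q = q, a = 0, b = 1,
                     s = 0, t = if (m > 0) 1 else 0)
    bd <- phase_boundaries(p0)
    brows[[length(brows) + 1]] <- data.frame(
      axis_value = x, a_c = bd$a_c, a_tilde_c = bd$a_tilde_c)
    for (a in a_values) {
      pa <- evo_params(c = c, m = m, r = r, q = q, a = a, b = 1,
                       s = if (m > 0) a else 0, t = if (m > 0) 1 else 0)
      ph <- classify_phase(pa)
      om <- omega_factor(pa)
      gam <- if (ph %in% c("exponential", "critical_stretched")) NA_real_
             else predict_exponent(pa)
      rows[[length(rows) + 1]] <- data.frame(
        a = a, axis_value = x, phase = ph, gamma = gam,
        omega_raw = attr(om, "raw_ratio"))
    }
  }
  list(grid = do.call(rbind, rows), boundaries = do.call(rbind, brows))
}
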