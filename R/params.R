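#' Model parameters for the four-process network evolution model
#'
#' Bundles the eight parameters governing one evolution process:
#' \describe{
#'   \item{c}{number of external edges each new node arrives with (integer,
#'     \eqn{c \ge 1}).}
#'   \item{m}{number of internal edges added per step, and of edges removed
#'     per edge-deletion event (integer, \eqn{m \ge 0}).}
#'   \item{r}{probability per step of deleting one uniformly random node
#'     (\eqn{0 \le r < 1}; \eqn{r \ge 1} — the shrinking/steady regime —
#'     is excluded).}
#'   \item{q}{probability per step of deleting \eqn{m} uniformly random
#'     edges (\eqn{0 \le q \le 1}).}
#'   \item{a, b}{random and preferential strength of the external attachment
#'     kernel \eqn{\pi_k \propto a + b k}. \eqn{a} is the initial
#'     attractiveness letting degree-0 nodes acquire links.}
#'   \item{s, t}{random and preferential strength of the internal attachment
#'     kernel \eqn{f_k \propto s + t k}; the joint kernel for an internal
#'     edge factorizes as \eqn{(s + t k)(s + t k')}.}
#' }
#'
#' @param c positive integer, edges per new node.
#' @param m non-negative integer, internal edges per step.
#' @param r node-deletion probability in \[0, 1).
#' @param q edge-deletion probability in \[0, 1\].
#' @param a,b non-negative external kernel coefficients, `a + b > 0`.
#' @param s,t non-negative internal kernel coefficients; `s + t > 0`
#'   is required whenever `m > 0`.
#'
#' @return An object of class `evo_params` (a validated named list).
#' @examples
#' evo_params(c = 3, m = 2, r = 0.2, q = 0.1, a = 0.5, b = 1, s = 0.5, t = 1)
#' @export
evo_params <- function(c = 3, m = 0, r = 0, q = 0, a = 0, b = 1, s = 0, t = 1) {
  p <- list(c = c, m = m, r = r, q = q, a = a, b = b, s = s, t = t)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
    p[[nm]] <- as.numeric(v)
  }
  structure(p, class = "evo_params")
  validate_params(structure(p, class = "evo_params"))
}

#' Validate a model parameter set
#'
#' Checks the model invariants and returns the parameters unchanged when all
#' hold. Violations signal an error naming the offending field; `r >= 1`
#' reports the excluded shrinking/steady-size regime explicitly.
#'
#' @param params an `evo_params` object (or coercible named list).
#' @return The validated `evo_params` object, invisibly unchanged.
#' @export
validate_params <- function(params) {
  p <- unclass(params)
  need <- c("c", "m", "r", "q", "a", "b", "s", "t")
  if (!all(need %in% names(p)))
    stop("missing parameter field(s): ",
         paste(setdiff(need, names(p)), collapse = ", "), call. = FALSE)
  if (p$c < 1 || p$c != round(p$c))
    stop("parameter 'c' must be an integer >= 1 (each new node needs edges)",
         call. = FALSE)
  if (p$m < 0 || p$m != round(p$m))
    stop("parameter 'm' must be a non-negative integer", call. = FALSE)
  if (p$r < 0) stop("parameter 'r' must be >= 0", call. = FALSE)
  if (p$r >= 1)
    stop("parameter 'r' >= 1: shrinking or steady-size networks are outside ",
         "the model's growing-network regime", call. = FALSE)
  if (p$q < 0 || p$q > 1)
    stop("parameter 'q' must lie in [0, 1]", call. = FALSE)
  for (nm in c("a", "b", "s", "t"))
    if (p[[nm]] < 0)
      stop("parameter '", nm, "' must be >= 0 (negative attractiveness is ",
           "not admitted)", call. = FALSE)
  if (p$a + p$b <= 0)
    stop("parameters 'a' + 'b' must be > 0: external kernel undefined",
         call. = FALSE)
  if (p$m > 0 && p$s + p$t <= 0)
    stop("parameters 's' + 't' must be > 0 when m > 0: internal kernel ",
         "undefined", call. = FALSE)
  structure(p, class = "evo_params")
}

#' @export
print.evo_params <- function(x, ...) {
  cat("Network evolution parameters\n")
  cat(sprintf("  external: c = %g edges/node, kernel a + b k = %g + %g k\n",
              x$c, x$a, x$b))
  cat(sprintf("  internal: m = %g edges/step, kernel s + t k = %g + %g k\n",
              x$m, x$s, x$t))
  cat(sprintf("  deletion: node r = %g, edge q = %g\n", x$r, x$q))
  invisible(x)
}

#' Normalized attachment kernel value
#'
#' Evaluates the normalized attachment kernel at degree `k`:
#' \eqn{\pi_k = (a + b k)/(a + b \langle k \rangle)} for `kind = "external"`
#' and \eqn{f_k = (s + t k)/(s + t \langle k \rangle)} for
#' `kind = "internal"`, so that \eqn{\sum_k \pi_k p_k = 1} for any degree
#' distribution with the given mean. The joint kernel of an internal edge is
#' by contract the product of two internal factors.
#'
#' `mean_degree` is always passed explicitly (analytic or empirical), never
#' recomputed here, so simulator and solver agree on which mean they use.
#'
#' @param kind `"external"` or `"internal"`.
#' @param k non-negative integer degree (vectorized).
#' @param params an `evo_params` object.
#' @param mean_degree positive real, the \eqn{\langle k \rangle} entering the
#'   normalization.
#' @return Numeric vector of non-negative kernel values.
#' @examples
#' p <- evo_params(c = 3, a = 0.5, b = 1)
#' attachment_weight("external", 0, p, mean_degree = 10)  # 0.5 / 10.5
#' @export
attachment_weight <- function(kind = c("external", "internal"), k, params,
                              mean_degree) {
  kind <- match.arg(kind)
  params <- validate_params(params)
  stopifnot(is.numeric(mean_degree), length(mean_degree) == 1L,
            mean_degree > 0)
  if (any(k < 0)) stop("degree 'k' must be non-negative", call. = FALSE)
  if (kind == "external") {
    (params$a + params$b * k) / (params$a + params$b * mean_degree)
  } else {
    if (params$s + params$t <= 0)
      stop("internal kernel undefined: s = t = 0", call. = FALSE)
    (params$s + params$t * k) / (params$s + params$t * mean_degree)
  }
}
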