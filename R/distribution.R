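#' Construct a degree distribution object
#'
#' A `degree_distribution` is a normalized map from degree `k` to probability
#' `p_k`, optionally carrying the underlying sample counts. It is the common
#' currency between the simulator, the rate-equation solver, the closed-form
#' recurrence and the tail-fitting routines.
#'
#' @param k integer vector of degrees (non-negative, strictly increasing
#'   after sorting; duplicates are merged).
#' @param prob probabilities for each degree; normalized if `normalize`.
#' @param counts optional integer sample counts per degree (same length).
#' @param n_samples total sample size behind the distribution (defaults to
#'   `sum(counts)` when counts are given, else `NA`).
#' @param source one of `"simulation"`, `"solver"`, `"closed_form"`, `"file"`.
#' @param normalize divide `prob` by its sum (default `TRUE`).
#' @return An object of class `degree_distribution` with fields `k`, `prob`,
#'   `counts`, `n_samples`, `mean`, `source`.
#' @export
degree_distribution <- function(k, prob, counts = NULL, n_samples = NA_real_,
                                source = c("simulation", "solver",
                                           "closed_form", "file"),
                                normalize = TRUE) {
  source <- match.arg(source)
  stopifnot(length(k) == length(prob), all(k >= 0), all(k == round(k)))
  if (any(prob < -1e-12)) stop("negative probability", call. = FALSE)
  prob <- pmax(prob, 0)
  o <- order(k)
  k <- as.integer(k[o]); prob <- prob[o]
  if (!is.null(counts)) counts <- counts[o]
  if (anyDuplicated(k)) {
    agg <- rowsum(prob, k)
    if (!is.null(counts)) counts <- as.vector(rowsum(counts, k))
    k <- as.integer(rownames(agg)); prob <- as.vector(agg)
  }
  tot <- sum(prob)
  if (tot <= 0) stop("degree distribution has zero total mass", call. = FALSE)
  if (normalize) prob <- prob / tot
  if (is.na(n_samples) && !is.null(counts)) n_samples <- sum(counts)
  structure(
    list(k = k, prob = prob, counts = counts, n_samples = n_samples,
         mean = sum(k * prob), source = source),
    class = "degree_distribution")
}

#' @export
print.degree_distribution <- function(x, ...) {
  cat(sprintf(
    "Degree distribution (%s): %d degrees in [%d, %d], mean %.4f",
    x$source, length(x$k), min(x$k), max(x$k), x$mean))
  if (!is.na(x$n_samples)) cat(sprintf(", n = %g samples", x$n_samples))
  cat("\n")
  head_k <- utils::head(x$k, 6)
  cat("  p_k:", paste(sprintf("p[%d]=%.4g", head_k,
                              x$prob[match(head_k, x$k)]), collapse = " "),
      if (length(x$k) > 6) "..." else "", "\n")
  invisible(x)
}

#' @export
mean.degree_distribution <- function(x, ...) x$mean

#' Probability lookup on a dense grid
#'
#' Returns `p_k` for `k = 0, ..., k_max` with zeros where the distribution
#' has no mass.
#' @param dist a `degree_distribution`.
#' @param k_max maximum degree of the grid (default: max observed).
#' @return Numeric vector of length `k_max + 1`.
#' @export
dense_probs <- function(dist, k_max = max(dist$k)) {
  p <- numeric(k_max + 1)
  keep <- dist$k <= k_max
  p[dist$k[keep] + 1L] <- dist$prob[keep]
  p
}

#' Write / read a degree distribution as TSV
#'
#' Plain-text interchange format with header `k<TAB>count<TAB>probability`.
#' Distributions without counts write expected counts of `NA`.
#'
#' @param dist a `degree_distribution`.
#' @param path file path.
#' @return `write_degree_tsv` returns `path` invisibly;
#'   `read_degree_tsv` returns a `degree_distribution` with source `"file"`.
#' @export
write_degree_tsv <- function(dist, path) {
  df <- data.frame(k = dist$k,
                   count = if (is.null(dist$counts)) NA else dist$counts,
                   probability = dist$prob)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_degree_tsv
#' @export
read_degree_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE)
  if (!all(c("k", "probability") %in% names(df)))
    stop("degree TSV must have columns 'k' and 'probability': ", path,
         call. = FALSE)
  counts <- if ("count" %in% names(df) && !anyNA(df$count)) df$count else NULL
  degree_distribution(df$k, df$probability, counts = counts, source = "file")
}

#' Kolmogorov-Smirnov distance and per-decade comparison of two
#' degree distributions
#'
#' Computes the KS statistic (sup-norm distance between the two CDFs on the
#' union support) together with a per-decade relative-error table, the
#' quantitative version of overlaying a simulated and a theoretical curve.
#'
#' @param sim,theory `degree_distribution` objects (both normalized).
#' @return A list with `ks_stat` and a data frame `by_decade` holding, per
#'   degree decade, the probability mass under each input and the relative
#'   error of `sim` against `theory`.
#' @export
compare_distributions <- function(sim, theory) {
  k_max <- max(max(sim$k), max(theory$k))
  ps <- dense_probs(sim, k_max)
  pt <- dense_probs(theory, k_max)
  ks <- max(abs(cumsum(ps) - cumsum(pt)))
  dec <- pmax(floor(log10(pmax(0:k_max, 1))), 0)
  ms <- as.vector(rowsum(ps, dec))
  mt <- as.vector(rowsum(pt, dec))
  by_decade <- data.frame(
    decade = sort(unique(dec)),
    mass_sim = ms, mass_theory = mt,
    rel_err = ifelse(mt > 0, (ms - mt) / mt, NA_real_))
  list(ks_stat = ks, by_decade = by_decade)
}
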