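#' Permutation score of a gene between two library groups
#'
#' The constancy statistic at the heart of the package. The values of the two
#' groups (typically TPM-normalized counts from normal and cancer libraries)
#' are pooled; `m` random partitions of the pool into groups of the original
#' sizes are drawn without replacement, and the simulated mean difference
#' `v = mean(simulated group 2) - mean(simulated group 1)` is recorded for
#' each. With `mu` and `sigma` the mean and (population) standard deviation
#' of the `m` simulated differences, and `O = mean(group 2) - mean(group 1)`
#' the observed difference, the permutation score is
#'
#' \deqn{PS = |O - \mu| / \sigma}
#'
#' An ideal reference gene — identically distributed in both groups and
#' tightly so — has a score near 0; strongly differential genes score high.
#'
#' Degenerate case: if `sigma == 0` (all pooled values identical, so every
#' partition gives the same difference), the score is 0 when `|O - mu|` is
#' also 0 (a perfectly constant gene) and `Inf` otherwise; such genes are
#' flagged, never selectable.
#'
#' @param values_group1 numeric vector, group-1 (e.g. normal) values.
#' @param values_group2 numeric vector, group-2 (e.g. cancer) values.
#' @param m number of Monte-Carlo permutations (default 10,000).
#' @param seed optional integer seed set before drawing.
#' @param center_null subtract the simulated mean `mu` in the numerator
#'   (default `TRUE`); `FALSE` uses `|O|/sigma`. Since `mu` is near 0 the two
#'   are almost identical.
#' @param retain_draws keep the `m` simulated differences in the result.
#' @return a list of class `"permutation_result"` with elements `ps`,
#'   `observed_diff`, `null` (list `mu`, `sigma`, optionally `draws`), `n`,
#'   `c` and `m`.
#' @seealso [exact_permutation_score()] for the exhaustive-enumeration
#'   version, [neps()] to score a whole matrix.
#' @export
permutation_score <- function(values_group1, values_group2, m = 10000L,
                              seed = NULL, center_null = TRUE,
                              retain_draws = FALSE) {
  check_group_values(values_group1, values_group2)
  if (!is.null(seed)) set.seed(seed)
  x <- c(values_group1, values_group2)
  n <- length(values_group1)
  null <- mc_null_distribution(x, n, as.integer(m), retain_draws)
  if (!retain_draws) null$draws <- NULL
  O <- mean(values_group2) - mean(values_group1)
  build_perm_result(O, null, n, length(values_group2), m = as.integer(m),
                    center_null = center_null)
}

check_group_values <- function(g1, g2) {
  if (length(g1) < 1L || length(g2) < 1L || length(g1) + length(g2) < 2L)
    stop("each group needs at least one value and the pool at least two",
         call. = FALSE)
  if (any(!is.finite(c(g1, g2))) || any(c(g1, g2) < 0))
    stop("group values must be finite and non-negative", call. = FALSE)
}

build_perm_result <- function(O, null, n, c, m = NA_integer_,
                              center_null = TRUE, exact = FALSE) {
  dev <- if (center_null) abs(O - null$mu) else abs(O)
  scale0 <- max(1, abs(O), abs(null$mu))
  ps <- if (null$sigma == 0) {
    if (dev <= 1e-12 * scale0) 0 else Inf
  } else dev / null$sigma
  structure(list(ps = ps, observed_diff = O,
                 null = null, n = n, c = c, m = m, exact = exact),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation score: %.4g  (O = %.4g, null mu = %.4g, sigma = %.4g; %s)\n",
              x$ps, x$observed_diff, x$null$mu, x$null$sigma,
              if (isTRUE(x$exact)) sprintf("exact, %d partitions", x$n_partitions)
              else sprintf("m = %d", x$m)))
  invisible(x)
}

#' Exact permutation score by exhaustive enumeration
#'
#' Enumerates all `choose(n + c, n)` distinct partitions of the pooled values
#' and computes the null mean and (population) standard deviation exactly —
#' the independent oracle for [permutation_score()]. Limited to
#' `choose(n + c, n) <= 1e6`.
#'
#' @inheritParams permutation_score
#' @return a `"permutation_result"` with an additional `n_partitions`
#'   element; `null$draws` holds every enumerated difference.
#' @export
exact_permutation_score <- function(values_group1, values_group2,
                                    center_null = TRUE) {
  check_group_values(values_group1, values_group2)
  x <- c(values_group1, values_group2)
  n <- length(values_group1)
  c_ <- length(values_group2)
  n_part <- choose(n + c_, n)
  if (n_part > 1e6)
    stop("choose(n + c, n) exceeds 1e6; use the Monte-Carlo permutation_score()",
         call. = FALSE)
  S <- sum(x)
  # every subset of size n is the simulated group 1; v depends only on its sum
  sums1 <- utils::combn(x, n, FUN = sum)
  v <- (S - sums1) / c_ - sums1 / n
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))  # population sd over the full null
  O <- mean(values_group2) - mean(values_group1)
  res <- build_perm_result(O, list(mu = mu, sigma = sigma, draws = v),
                           n, c_, center_null = center_null, exact = TRUE)
  res$n_partitions <- n_part
  res
}

# Deterministic per-gene seed: a polynomial byte hash of the gene id folded
# with the run seed, kept inside 32-bit integer range. Ensures per-gene
# reproducibility independent of which other genes are present.
gene_seed <- function(seed, gene_id) {
  h <- 0
  for (b in utf8ToInt(gene_id)) h <- (h * 131 + b) %% 2147483647
  as.integer((h * 7919 + as.double(seed) %% 2147483647) %% 2147483647)
}
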