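#' Score every gene for expression constancy between two library groups
#'
#' The central fitting function. Raw counts are normalized to tags per
#' million (TPM), and each gene's TPM values are scored with the permutation
#' statistic of [permutation_score()]: the observed between-group mean
#' difference standardized against its null under random relabelling of the
#' libraries. Raw-count abundance summaries (mean across libraries, minimum
#' over libraries) are carried alongside for the selection step —
#' abundance criteria are deliberately applied to raw counts, not TPM.
#'
#' Each gene's random stream is seeded deterministically from `seed` and the
#' gene id, so results are reproducible and adding or removing genes leaves
#' other genes' scores untouched.
#'
#' @param counts a raw-unit [count_matrix()] (rows = genes after
#'   [collapse_tags()], columns = libraries), or a plain numeric matrix.
#' @param groups group labels; taken from `counts$groups` when omitted.
#'   Exactly two labels are required. Which label is "group 1" (the `n`
#'   normal-like group) is set by `group_order`; by default factor levels, or
#'   the sorted unique labels.
#' @param m Monte-Carlo permutations per gene (default 10,000).
#' @param seed integer run seed.
#' @param group_order optional length-2 character vector fixing (group 1,
#'   group 2); `observed_diff` is mean(group 2) - mean(group 1).
#' @param center_null passed to [permutation_score()].
#' @return an object of class `"neps"`: a list with `results` (a data.frame
#'   with columns `gene`, `ps`, `observed_diff`, `null_mu`, `null_sigma`,
#'   `avg_raw_count`, `min_library_count`, sorted by `ps` ascending, ties
#'   broken by higher `avg_raw_count` then gene id), `groups`,
#'   `group_levels`, `m`, `seed` and `call`. Methods: `print`, `summary`,
#'   `plot`, `coef`, `as.data.frame`.
#' @examples
#' sim <- simulate_sage(n_genes = 50, n_normal = 4, n_cancer = 4,
#'                      library_size = 2e4, n_stable = 3, n_fold = 5,
#'                      seed = 1)
#' fit <- neps(sim$counts, m = 500, seed = 1)
#' head(as.data.frame(fit))
#' select_reference_genes(fit, min_avg_count = 10)
#' @export
neps <- function(counts, groups = NULL, m = 10000L, seed = 1L,
                 group_order = NULL, center_null = TRUE) {
  cl <- match.call()
  if (!inherits(counts, "count_matrix")) {
    counts <- count_matrix(as.matrix(counts), unit = "raw", groups = groups)
  } else if (!is.null(groups)) {
    counts <- count_matrix(counts$counts, unit = counts$unit, groups = groups)
  }
  if (is.null(counts$groups))
    stop("group labels are required (via `groups` or the count matrix)",
         call. = FALSE)
  if (counts$unit != "raw")
    stop("`neps()` expects raw counts; TPM normalization is internal",
         call. = FALSE)
  grp <- counts$groups
  lev <- resolve_group_order(grp, group_order)
  tpm <- tpm_normalize(counts)
  raw <- counts$counts
  idx1 <- which(grp == lev[1])
  idx2 <- which(grp == lev[2])

  genes <- rownames(raw)
  res <- vapply(genes, function(g) {
    set.seed(gene_seed(seed, g))
    x1 <- tpm$counts[g, idx1]
    x2 <- tpm$counts[g, idx2]
    r <- permutation_score(x1, x2, m = m, center_null = center_null)
    c(ps = r$ps, observed_diff = r$observed_diff,
      null_mu = r$null$mu, null_sigma = r$null$sigma)
  }, numeric(4))

  results <- data.frame(gene = genes,
                        ps = res["ps", ],
                        observed_diff = res["observed_diff", ],
                        null_mu = res["null_mu", ],
                        null_sigma = res["null_sigma", ],
                        avg_raw_count = rowMeans(raw),
                        min_library_count = apply(raw, 1, min),
                        row.names = NULL)
  results <- results[order_results(results), , drop = FALSE]
  rownames(results) <- NULL
  structure(list(results = results, groups = grp, group_levels = lev,
                 m = as.integer(m), seed = as.integer(seed),
                 center_null = center_null, call = cl),
            class = "neps")
}

resolve_group_order <- function(grp, group_order) {
  lev <- if (is.factor(grp)) levels(grp) else sort(unique(as.character(grp)))
  if (!is.null(group_order)) {
    if (!setequal(group_order, lev) || length(group_order) != 2)
      stop("`group_order` must name the two group labels", call. = FALSE)
    lev <- group_order
  }
  if (length(lev) != 2)
    stop("exactly two group labels are required, got: ",
         paste(lev, collapse = ", "), call. = FALSE)
  lev
}

# sort by PS ascending; ties by higher abundance, then gene id
order_results <- function(df) {
  order(df$ps, -df$avg_raw_count, df$gene)
}

#' @export
print.neps <- function(x, n = 10L, ...) {
  cat(sprintf("Permutation constancy scores: %d genes, %d + %d libraries (%s vs %s), m = %d\n",
              nrow(x$results), sum(x$groups == x$group_levels[1]),
              sum(x$groups == x$group_levels[2]),
              x$group_levels[1], x$group_levels[2], x$m))
  cat("Most stable genes:\n")
  print(utils::head(x$results, n), digits = 4)
  invisible(x)
}

#' @export
summary.neps <- function(object, ps_max = 0.15, min_per_library = 2,
                         min_avg_count = 25, ...) {
  sel <- select_reference_genes(object, ps_max = ps_max,
                                min_per_library = min_per_library,
                                min_avg_count = min_avg_count)
  structure(list(fit = object, selected = sel, ps_max = ps_max,
                 min_per_library = min_per_library,
                 min_avg_count = min_avg_count),
            class = "summary.neps")
}

#' @export
print.summary.neps <- function(x, ...) {
  print(x$fit, n = 5L)
  cat(sprintf("\nSelection (PS <= %g, every library >= %g raw tags, avg raw count >= %g):\n",
              x$ps_max, x$min_per_library, x$min_avg_count))
  if (nrow(x$selected) == 0) cat("  no genes satisfy the criteria\n")
  else print(x$selected, digits = 4)
  invisible(x)
}

#' @export
coef.neps <- function(object, ...) {
  stats::setNames(object$results$ps, object$results$gene)
}

#' @export
as.data.frame.neps <- function(x, ...) x$results

#' Permutation score against raw abundance
#'
#' Scatter of each gene's average raw tag count (log scale) against its
#' permutation score; good reference candidates sit in the high-abundance,
#' near-zero-score corner. Genes passing the selection criteria are
#' highlighted.
#'
#' @param x a [neps()] fit.
#' @param ps_max,min_per_library,min_avg_count selection thresholds used for
#'   highlighting, as in [select_reference_genes()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.neps <- function(x, ps_max = 0.15, min_per_library = 2,
                      min_avg_count = 25, ...) {
  df <- x$results
  keep <- is.finite(df$ps)
  sel <- df$gene %in% select_reference_genes(x, ps_max, min_per_library,
                                             min_avg_count)$gene
  graphics::plot(pmax(df$ps[keep], 1e-4), pmax(df$avg_raw_count[keep], 0.1),
                 log = "xy",
                 col = ifelse(sel[keep], "red3", "grey40"),
                 pch = ifelse(sel[keep], 19, 1),
                 xlab = "permutation score",
                 ylab = "average raw tag count", ...)
  graphics::abline(v = ps_max, h = min_avg_count, lty = 2, col = "grey60")
  invisible(x)
}

#' Select reference genes by score and abundance criteria
#'
#' Applies the three inclusive selection criteria to a scored gene set:
#' permutation score at most `ps_max`, raw count of at least
#' `min_per_library` in *every* library, and an average raw count across all
#' libraries of at least `min_avg_count` (use 10 rather than the default 25
#' for shallower library sets).
#'
#' @param results a [neps()] fit or its `results` data.frame.
#' @param ps_max maximum permutation score (default 0.15).
#' @param min_per_library minimum raw count required in every library
#'   (default 2).
#' @param min_avg_count minimum average raw count (default 25).
#' @return the selected rows, sorted by `ps` ascending (empty data.frame if
#'   nothing qualifies).
#' @export
select_reference_genes <- function(results, ps_max = 0.15,
                                   min_per_library = 2, min_avg_count = 25) {
  if (inherits(results, "neps")) results <- results$results
  stopifnot(is.data.frame(results), nrow(results) >= 1)
  if (any(c(ps_max, min_per_library, min_avg_count) < 0))
    stop("selection thresholds must be non-negative", call. = FALSE)
  keep <- is.finite(results$ps) & results$ps <= ps_max &
    results$min_library_count >= min_per_library &
    results$avg_raw_count >= min_avg_count
  out <- results[keep, , drop = FALSE]
  out <- out[order_results(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}
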