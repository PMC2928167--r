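#' Construct a paired qPCR Ct dataset
#'
#' Cycle-threshold values for candidate reference genes across tumor samples
#' and their matched non-malignant counterparts, plus the pairing, group
#' labels and per-gene amplification efficiencies needed by the three
#' stability metrics.
#'
#' @param ct numeric matrix, genes x samples, finite Ct values (PCR cycles).
#' @param pairs data.frame (or 2-column matrix) with columns `tumor` and
#'   `normal` holding matched sample ids; each sample may appear in at most
#'   one pair.
#' @param groups optional named character vector sample -> group label;
#'   derived from `pairs` (labels `"tumor"` / `"normal"`) when omitted.
#' @param efficiency amplification efficiency E per gene (scalar recycled, or
#'   named vector); default 2 (perfect doubling per cycle). Must exceed 1.
#' @return an object of class `"qpcr_dataset"`.
#' @export
qpcr_dataset <- function(ct, pairs, groups = NULL, efficiency = 2) {
  if (!is.matrix(ct) || !is.numeric(ct))
    stop("`ct` must be a numeric matrix (genes x samples)", call. = FALSE)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    stop("`ct` must have gene and sample names", call. = FALSE)
  if (any(!is.finite(ct))) stop("Ct values must be finite", call. = FALSE)
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) != 2)
    stop("`pairs` must have two columns (tumor, normal)", call. = FALSE)
  colnames(pairs) <- c("tumor", "normal")
  ids <- c(pairs$tumor, pairs$normal)
  missing <- setdiff(ids, colnames(ct))
  if (length(missing))
    stop("paired samples absent from the Ct matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(ids))
    stop("a sample may belong to at most one pair", call. = FALSE)
  if (is.null(groups)) {
    groups <- stats::setNames(rep(c("tumor", "normal"), each = nrow(pairs)),
                              c(pairs$tumor, pairs$normal))
  }
  missing_g <- setdiff(colnames(ct), names(groups))
  if (length(missing_g))
    stop("samples without a group label: ",
         paste(missing_g, collapse = ", "), call. = FALSE)
  groups <- groups[colnames(ct)]
  if (length(efficiency) == 1)
    efficiency <- stats::setNames(rep(efficiency, nrow(ct)), rownames(ct))
  missing_e <- setdiff(rownames(ct), names(efficiency))
  if (length(missing_e))
    stop("genes without an efficiency: ", paste(missing_e, collapse = ", "),
         call. = FALSE)
  efficiency <- efficiency[rownames(ct)]
  if (any(efficiency <= 1))
    stop("amplification efficiencies must exceed 1", call. = FALSE)
  structure(list(ct = ct, pairs = pairs, groups = groups,
                 efficiency = efficiency),
            class = "qpcr_dataset")
}

#' @export
print.qpcr_dataset <- function(x, ...) {
  cat(sprintf("qpcr_dataset: %d genes x %d samples, %d matched pairs\n",
              nrow(x$ct), ncol(x$ct), nrow(x$pairs)))
  invisible(x)
}

#' Read a paired qPCR Ct dataset from TSV files
#'
#' @param ct_path Ct TSV (header of sample ids, first column gene ids).
#' @param pairs_path 2-column headerless TSV (tumor id, normal id).
#' @param groups_path optional 2-column headerless TSV (sample id, group).
#' @param efficiency_path optional 2-column headerless TSV (gene,
#'   efficiency).
#' @return a [qpcr_dataset()].
#' @export
read_qpcr_dataset <- function(ct_path, pairs_path, groups_path = NULL,
                              efficiency_path = NULL) {
  ct <- parse_numeric_table(read_tsv_table(ct_path), ct_path)
  pdf <- utils::read.delim(pairs_path, header = FALSE, sep = "\t",
                           quote = "", comment.char = "#",
                           colClasses = "character")
  groups <- if (!is.null(groups_path)) read_group_file(groups_path)
  eff <- 2
  if (!is.null(efficiency_path)) {
    edf <- utils::read.delim(efficiency_path, header = FALSE, sep = "\t",
                             quote = "", comment.char = "#",
                             colClasses = c("character", "numeric"))
    eff <- stats::setNames(edf[[2]], edf[[1]])
  }
  qpcr_dataset(ct, pairs = pdf, groups = groups, efficiency = eff)
}

#' Variance of the tumor/normal Ct difference
#'
#' For each gene, `dCt = Ct(tumor) - Ct(normal)` is computed within every
#' matched pair and its unbiased (n-1) sample variance across pairs is
#' returned. A gene whose tumor shift is the same in every pair — including
#' a shift of zero — has variance 0; pair-dependent shifts inflate it.
#' Note the metric is blind to a *constant* tumor/normal shift; that bias
#' axis is covered by the model-based stability metric.
#'
#' @param d a [qpcr_dataset()] with at least two pairs.
#' @return named numeric vector of per-gene dCt variances (squared cycles).
#' @export
dct_variance <- function(d) {
  stopifnot(inherits(d, "qpcr_dataset"))
  if (nrow(d$pairs) < 2)
    stop("at least two matched pairs are required for a variance",
         call. = FALSE)
  dct <- d$ct[, d$pairs$tumor, drop = FALSE] -
    d$ct[, d$pairs$normal, drop = FALSE]
  apply(dct, 1, stats::var)
}

#' Convert Ct values to relative quantities
#'
#' Per gene, `q = E ^ (min(Ct) - Ct)`: the sample with the lowest Ct gets
#' quantity 1 and each additional cycle divides the quantity by the
#' amplification efficiency E (E = 2 for perfect doubling). This is the
#' input scale expected by the geNorm and NormFinder-style metrics.
#'
#' @param d a [qpcr_dataset()].
#' @return gene x sample matrix of positive relative quantities.
#' @export
ct_to_quantity <- function(d) {
  stopifnot(inherits(d, "qpcr_dataset"))
  minct <- apply(d$ct, 1, min)
  d$efficiency ^ (minct - d$ct)
}

#' geNorm expression-stability measure M
#'
#' For every gene pair (j, k) the per-sample log2 ratio `log2(q_j / q_k)` is
#' formed and its sample standard deviation across samples is the pairwise
#' variation `V_jk`. A gene's M value is the mean of its pairwise variations
#' over all partner genes; genes with low M co-vary most consistently with
#' the rest of the panel and are the most stable. M is invariant to
#' rescaling any gene's quantities by a positive constant.
#'
#' @param quantities positive gene x sample matrix (e.g. from
#'   [ct_to_quantity()]); at least two genes.
#' @return named numeric vector of per-gene M values.
#' @export
genorm_m <- function(quantities) {
  check_quantities(quantities)
  L <- log2(quantities)
  G <- nrow(L)
  V <- matrix(0, G, G, dimnames = list(rownames(L), rownames(L)))
  for (j in seq_len(G - 1)) {
    for (k in (j + 1):G) {
      v <- stats::sd(L[j, ] - L[k, ])
      V[j, k] <- V[k, j] <- v
    }
  }
  rowSums(V) / (G - 1)
}

check_quantities <- function(quantities) {
  if (!is.matrix(quantities) || !is.numeric(quantities))
    stop("`quantities` must be a numeric matrix", call. = FALSE)
  if (nrow(quantities) < 2)
    stop("at least two genes are required", call. = FALSE)
  if (any(quantities <= 0))
    stop("quantities must be strictly positive (log undefined otherwise)",
         call. = FALSE)
}

#' Stepwise geNorm ranking by worst-gene elimination
#'
#' The optional iterative layer of the geNorm procedure: repeatedly drop the
#' gene with the highest M among the remaining panel, recomputing M each
#' round, until two genes remain. Returns the elimination order (least
#' stable first) and the final most-stable pair. The M value reported per
#' gene by [genorm_m()] and used for ranking is the full-panel M, without
#' elimination.
#'
#' @inheritParams genorm_m
#' @return list with `elimination_order` (character, least stable first) and
#'   `final_pair`.
#' @export
genorm_stepwise <- function(quantities) {
  check_quantities(quantities)
  out <- character(0)
  q <- quantities
  while (nrow(q) > 2) {
    m <- genorm_m(q)
    worst <- names(m)[order(-m, names(m))][1]
    out <- c(out, worst)
    q <- q[setdiff(rownames(q), worst), , drop = FALSE]
  }
  list(elimination_order = out, final_pair = rownames(q))
}

#' Model-based (NormFinder-style) stability value
#'
#' Decomposes each gene's log quantities within each sample group into gene
#' and sample effects plus a gene-by-group effect `d` and residual noise.
#' The intragroup variance is estimated with a small-sample bias correction
#' accounting for the gene-averaged sample effect
#' (`sigma2 = k/(k-2) * (z - mean(z)/(k-1))`, `z` the per-gene mean squared
#' two-way residual, `k` the number of genes, clamped at 0), the group
#' effect `d` is shrunk toward zero in proportion to its sampling variance,
#' and a gene's stability value is the mean over groups of
#' `|d_shrunk| + sqrt(sigma2 / n_g)` — combining systematic between-group
#' shift with intragroup noise. Lower is more stable. With a single group
#' the value reduces to the within-group term `sqrt(sigma2 / n)`.
#'
#' @param log_quantities gene x sample matrix of log-scale quantities (any
#'   log base; e.g. `log2(ct_to_quantity(d))`); at least 3 genes.
#' @param groups named character vector sample -> group label covering every
#'   sample; every group needs at least 2 samples.
#' @return named numeric vector of per-gene stability values.
#' @export
normfinder_stability <- function(log_quantities, groups) {
  if (!is.matrix(log_quantities) || !is.numeric(log_quantities))
    stop("`log_quantities` must be a numeric matrix", call. = FALSE)
  k <- nrow(log_quantities)
  if (k < 3)
    stop("the model needs at least 3 genes", call. = FALSE)
  samples <- colnames(log_quantities)
  missing <- setdiff(samples, names(groups))
  if (length(missing))
    stop("samples without a group label: ", paste(missing, collapse = ", "),
         call. = FALSE)
  grp <- as.character(groups[samples])
  levs <- unique(grp)
  n_g <- table(factor(grp, levels = levs))
  if (any(n_g < 2))
    stop("every group needs at least two samples; offending group(s): ",
         paste(names(n_g)[n_g < 2], collapse = ", "), call. = FALSE)
  G <- length(levs)

  sigma2 <- matrix(NA_real_, k, G, dimnames = list(rownames(log_quantities),
                                                   levs))
  gmeans <- sigma2
  for (gi in seq_along(levs)) {
    Y <- log_quantities[, grp == levs[gi], drop = FALSE]
    n <- ncol(Y)
    rm_ <- rowMeans(Y)
    cm_ <- colMeans(Y)
    R <- Y - outer(rm_, rep(1, n)) - outer(rep(1, k), cm_) + mean(Y)
    z <- rowSums(R^2) / (n - 1)
    sigma2[, gi] <- pmax(0, (z - mean(z) / (k - 1)) * k / (k - 2))
    gmeans[, gi] <- rm_
  }
  if (G == 1) {
    return(sqrt(sigma2[, 1] / as.integer(n_g[1])))
  }
  # gene-by-group effect: double-centered matrix of group means
  d <- gmeans - rowMeans(gmeans) -
    matrix(colMeans(gmeans) - mean(gmeans), k, G, byrow = TRUE)
  vard <- sweep(sigma2, 2, as.integer(n_g), `/`)
  gamma2 <- max(0, sum(d^2) / ((k - 1) * (G - 1)) - mean(vard))
  d_shrunk <- d * gamma2 / (gamma2 + vard)
  d_shrunk[vard == 0 & gamma2 == 0] <- 0
  rowMeans(abs(d_shrunk) + sqrt(vard))
}

#' Competition ranks for a stability metric
#'
#' Rank 1 is the best value (the smallest when `lower_is_better`). Ties
#' share the minimum rank and the next distinct value skips accordingly
#' (competition ranking).
#'
#' @param values named numeric vector of finite metric values.
#' @param lower_is_better is a smaller value better (default `TRUE`)?
#' @return named integer vector of ranks.
#' @export
rank_metric <- function(values, lower_is_better = TRUE) {
  if (any(!is.finite(values))) stop("metric values must be finite",
                                    call. = FALSE)
  v <- if (lower_is_better) values else -values
  r <- rank(v, ties.method = "min")
  stats::setNames(as.integer(r), names(values))
}

#' Aggregate per-metric ranks into a cumulative ranking
#'
#' A gene's cumulative rank is the sum of its ranks under each metric; the
#' consensus ordering sorts cumulative rank ascending, with tied genes
#' displayed in gene-id order.
#'
#' @param ranks named list of two or more integer rank vectors over an
#'   identical gene set (names are metric labels).
#' @return data.frame with one column per metric rank plus
#'   `cumulative_rank`, sorted by cumulative rank then gene id.
#' @export
cumulative_ranking <- function(ranks) {
  stopifnot(is.list(ranks), length(ranks) >= 2)
  genes <- names(ranks[[1]])
  for (r in ranks) {
    if (is.null(names(r)) || !setequal(names(r), genes))
      stop("rank vectors must cover identical gene sets", call. = FALSE)
  }
  df <- data.frame(gene = genes, row.names = NULL)
  for (nm in names(ranks)) df[[nm]] <- as.integer(ranks[[nm]][genes])
  df$cumulative_rank <- as.integer(rowSums(as.matrix(df[, names(ranks)])))
  df <- df[order(df$cumulative_rank, df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Build a stability report from the three metric values
#'
#' Ranks each metric (lower = more stable, competition ranks), sums the
#' three ranks per gene into a cumulative rank, and orders genes by it.
#'
#' @param dct_variance,normfinder,genorm_m named numeric vectors of metric
#'   values over an identical gene set.
#' @return an object of class `"stability_report"`: a data.frame with
#'   columns `gene`, `cumulative_rank`, `dct_variance`, `dct_rank`,
#'   `normfinder_stability`, `normfinder_rank`, `genorm_m`, `genorm_rank`.
#' @seealso [qpcr_stability()] to compute the metrics from Ct data.
#' @export
stability_report <- function(dct_variance, normfinder, genorm_m) {
  genes <- names(dct_variance)
  if (is.null(genes) || !setequal(genes, names(normfinder)) ||
      !setequal(genes, names(genorm_m)))
    stop("the three metric vectors must cover identical gene sets",
         call. = FALSE)
  normfinder <- normfinder[genes]
  genorm_m <- genorm_m[genes]
  ranks <- list(dct_rank = rank_metric(dct_variance),
                normfinder_rank = rank_metric(normfinder),
                genorm_rank = rank_metric(genorm_m))
  agg <- cumulative_ranking(ranks)
  df <- data.frame(gene = agg$gene,
                   cumulative_rank = agg$cumulative_rank,
                   dct_variance = dct_variance[agg$gene],
                   dct_rank = agg$dct_rank,
                   normfinder_stability = normfinder[agg$gene],
                   normfinder_rank = agg$normfinder_rank,
                   genorm_m = genorm_m[agg$gene],
                   genorm_rank = agg$genorm_rank,
                   row.names = NULL)
  class(df) <- c("stability_report", "data.frame")
  df
}

#' Rank candidate reference genes from paired qPCR Ct data
#'
#' Computes the three stability metrics from a Ct dataset — dCt variance
#' across matched pairs ([dct_variance()]), geNorm M ([genorm_m()]) and the
#' model-based NormFinder-style stability value ([normfinder_stability()])
#' — ranks genes within each (1 = most stable) and aggregates by cumulative
#' rank.
#'
#' @param d a [qpcr_dataset()].
#' @return a [stability_report()].
#' @examples
#' sim <- simulate_qpcr(n_genes = 8, n_pairs = 6, seed = 1)
#' qpcr_stability(sim$data)
#' @export
qpcr_stability <- function(d) {
  stopifnot(inherits(d, "qpcr_dataset"))
  q <- ct_to_quantity(d)
  stability_report(dct_variance = dct_variance(d),
                   normfinder = normfinder_stability(log2(q), d$groups),
                   genorm_m = genorm_m(q))
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Reference-gene stability ranking (1 = most stable):\n")
  df <- as.data.frame(unclass(x))
  df$dct_variance <- round(df$dct_variance, 4)
  df$normfinder_stability <- round(df$normfinder_stability, 4)
  df$genorm_m <- round(df$genorm_m, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
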