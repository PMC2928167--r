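#' Simulate grouped SAGE-like tag-count libraries with planted truth
#'
#' Each library is a multinomial draw of `library_size` tags from its
#' group's relative-abundance vector — the digital, fixed-depth sampling
#' premise of SAGE. Three planted gene classes define the ground truth:
#' `n_stable` stable genes with identical (and selection-grade high)
#' abundance in both groups, `n_fold` differential genes whose abundance is
#' multiplied by `fold` in the cancer group, and an unconstrained
#' background. Group abundance vectors are renormalized to sum to one, so
#' planting fold changes induces the (realistic) compositional shift on all
#' other genes.
#'
#' @param n_genes total genes (default 2,000).
#' @param n_normal,n_cancer libraries per group (default 12 + 12).
#' @param library_size total tags per library: scalar or per-library vector
#'   (default 100,000). See [draw_library_sizes()] for heterogeneous depths.
#' @param n_stable planted stable genes (default 10), abundance log-uniform
#'   over `stable_abundance`.
#' @param n_fold planted differential genes (default 100) at fold change
#'   `fold` in the cancer group, baseline abundance log-uniform over
#'   `fold_abundance`.
#' @param fold multiplicative cancer-group change for planted differential
#'   genes (default 4).
#' @param stable_abundance,fold_abundance,background_abundance length-2
#'   ranges for log-uniform baseline abundance draws. The stable default
#'   starts at 2.5e-4, i.e. an expected raw count of 25 at 100k tags — the
#'   selection abundance threshold.
#' @param dispersion negative-binomial overdispersion for robustness
#'   testing: each library's abundance vector is jittered by independent
#'   Gamma(1/dispersion) factors before the multinomial draw; 0 (default)
#'   gives pure multinomial sampling.
#' @param seed integer seed; identical seeds give identical output.
#' @return list of class `"sage_sim"`: `counts` (a raw [count_matrix()] with
#'   groups `"normal"`/`"cancer"`) and `truth` (list with `stable` gene ids
#'   and named `fold_changes`).
#' @export
simulate_sage <- function(n_genes = 2000, n_normal = 12, n_cancer = 12,
                          library_size = 1e5,
                          n_stable = 10, n_fold = 100, fold = 4,
                          stable_abundance = c(2.5e-4, 1e-3),
                          fold_abundance = c(2e-5, 2e-4),
                          background_abundance = c(2e-5, 1e-3),
                          dispersion = 0, seed = 1L) {
  stopifnot(n_genes >= n_stable + n_fold, n_normal >= 1, n_cancer >= 1)
  set.seed(as.integer(seed))
  n_lib <- n_normal + n_cancer
  sizes <- rep_len(library_size, n_lib)
  genes <- sprintf("g%04d", seq_len(n_genes))
  stable <- genes[seq_len(n_stable)]
  fold_genes <- genes[n_stable + seq_len(n_fold)]

  logu <- function(n, range) exp(stats::runif(n, log(range[1]), log(range[2])))
  base <- logu(n_genes, background_abundance)
  names(base) <- genes
  base[stable] <- logu(n_stable, stable_abundance)
  base[fold_genes] <- logu(n_fold, fold_abundance)

  ab_normal <- base / sum(base)
  cancer <- base
  cancer[fold_genes] <- cancer[fold_genes] * fold
  ab_cancer <- cancer / sum(cancer)
  if (sum(base) <= 0) stop("abundance vector sums to zero", call. = FALSE)

  draw <- function(p, size) {
    if (dispersion > 0) {
      p <- p * stats::rgamma(length(p), shape = 1 / dispersion,
                             rate = 1 / dispersion)
      p <- p / sum(p)
    }
    stats::rmultinom(1, size = size, prob = p)[, 1]
  }
  counts <- matrix(0L, n_genes, n_lib,
                   dimnames = list(genes,
                                   c(sprintf("N%02d", seq_len(n_normal)),
                                     sprintf("C%02d", seq_len(n_cancer)))))
  for (j in seq_len(n_lib)) {
    p <- if (j <= n_normal) ab_normal else ab_cancer
    counts[, j] <- draw(p, sizes[j])
  }
  groups <- stats::setNames(rep(c("normal", "cancer"), c(n_normal, n_cancer)),
                            colnames(counts))
  structure(list(counts = count_matrix(counts, unit = "raw", groups = groups),
                 truth = list(stable = stable,
                              fold_changes = stats::setNames(
                                rep(fold, n_fold), fold_genes))),
            class = "sage_sim")
}

#' Draw heterogeneous library depths
#'
#' Log-uniform library sizes over `range`, mimicking the mixed sequencing
#' depths of real SAGE library collections.
#'
#' @param n number of libraries.
#' @param range length-2 depth range (default 30,000-150,000 tags).
#' @param seed optional integer seed.
#' @return integer vector of depths.
#' @export
draw_library_sizes <- function(n, range = c(3e4, 1.5e5), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  as.integer(round(exp(stats::runif(n, log(range[1]), log(range[2])))))
}

#' Simulate paired tumor/normal qPCR Ct data with planted truth
#'
#' Cycle thresholds follow
#' `Ct = ct_offset - base_log2 - shift * tumor - pair_effect + noise`, with
#' a shared per-pair effect (biological pairing correlation, sd `pair_sd`
#' cycles) and independent per-measurement Gaussian noise. Planted stable
#' genes have zero tumor shift and low noise; the remaining genes get
#' gene-specific shifts and noisier measurements, so the three stability
#' metrics have real structure to discriminate.
#'
#' @param n_genes genes assayed (default 21).
#' @param n_pairs matched tumor/normal pairs (default 15).
#' @param n_stable planted stable genes (zero shift, noise sd
#'   `stable_noise_sd`; default 3).
#' @param base_log2_range range of per-gene baseline log2 expression
#'   (default 3-12, giving Ct roughly 16-27 at the default offset).
#' @param shift_range magnitude range of tumor shifts (log2 units = cycles)
#'   for non-stable genes; signs alternate. Default 0.5-2.
#' @param noise_range per-measurement noise sd range (cycles) for non-stable
#'   genes (default 0.7-1.5).
#' @param stable_noise_sd noise sd of planted stable genes (default 0.25).
#' @param pair_sd sd of the shared per-pair effect (default 1); set 0 to
#'   remove pairing correlation.
#' @param ct_offset intercept converting log2 expression to Ct (default 30).
#' @param efficiency amplification efficiency passed to the dataset
#'   (default 2).
#' @param seed integer seed.
#' @return list of class `"qpcr_sim"`: `data` (a [qpcr_dataset()] with
#'   samples `T01..`/`N01..`) and `truth` (list `stable`, `shift`,
#'   `noise_sd`).
#' @export
simulate_qpcr <- function(n_genes = 21, n_pairs = 15, n_stable = 3,
                          base_log2_range = c(3, 12),
                          shift_range = c(0.5, 2),
                          noise_range = c(0.7, 1.5),
                          stable_noise_sd = 0.25, pair_sd = 1,
                          ct_offset = 30, efficiency = 2, seed = 1L) {
  stopifnot(n_pairs >= 2, n_genes >= n_stable, stable_noise_sd >= 0)
  set.seed(as.integer(seed))
  genes <- sprintf("gene%02d", seq_len(n_genes))
  stable <- genes[seq_len(n_stable)]
  base <- stats::runif(n_genes, base_log2_range[1], base_log2_range[2])
  shift <- stats::runif(n_genes, shift_range[1], shift_range[2]) *
    rep_len(c(1, -1), n_genes)
  noise <- stats::runif(n_genes, noise_range[1], noise_range[2])
  names(base) <- names(shift) <- names(noise) <- genes
  shift[stable] <- 0
  noise[stable] <- stable_noise_sd

  tumor_ids <- sprintf("T%02d", seq_len(n_pairs))
  normal_ids <- sprintf("N%02d", seq_len(n_pairs))
  pair_eff <- stats::rnorm(n_pairs, 0, pair_sd)
  ct <- matrix(NA_real_, n_genes, 2 * n_pairs,
               dimnames = list(genes, c(tumor_ids, normal_ids)))
  for (p in seq_len(n_pairs)) {
    ct[, tumor_ids[p]] <- ct_offset - base - shift - pair_eff[p] +
      stats::rnorm(n_genes, 0, noise)
    ct[, normal_ids[p]] <- ct_offset - base - pair_eff[p] +
      stats::rnorm(n_genes, 0, noise)
  }
  d <- qpcr_dataset(ct, pairs = data.frame(tumor = tumor_ids,
                                           normal = normal_ids),
                    efficiency = efficiency)
  structure(list(data = d,
                 truth = list(stable = stable, shift = shift,
                              noise_sd = noise)),
            class = "qpcr_sim")
}
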