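#' Construct an expression matrix with optional detection calls
#'
#' Container for summarized microarray (or comparable) intensities: probes by
#' samples, optionally carrying a same-shaped matrix of detection calls
#' (P/M/A: present, marginal, absent) and a probe-to-gene map.
#'
#' @param values numeric matrix, probes x samples, finite.
#' @param calls optional character matrix of `"P"`, `"M"`, `"A"` with the
#'   same dimensions and dimnames as `values`.
#' @param probe_to_gene optional named character vector (probe id -> gene
#'   symbol).
#' @return an object of class `"expr_matrix"`.
#' @export
expr_matrix <- function(values, calls = NULL, probe_to_gene = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have probe and sample names", call. = FALSE)
  if (any(!is.finite(values)))
    stop("expression values must be finite", call. = FALSE)
  if (!is.null(calls)) {
    if (!identical(dim(calls), dim(values)))
      stop("`calls` must have the same shape as `values`", call. = FALSE)
    if (!all(calls %in% c("P", "M", "A")))
      stop("detection calls must be 'P', 'M' or 'A'", call. = FALSE)
    dimnames(calls) <- dimnames(values)
  }
  structure(list(values = values, calls = calls,
                 probe_to_gene = probe_to_gene),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d probes x %d samples%s%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$calls)) " [with P/M/A calls]" else "",
              if (!is.null(x$probe_to_gene)) " [with probe->gene map]" else ""))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix (with optional calls and probe map) from TSV
#'
#' @param path expression TSV: header of sample ids, first column probe ids.
#' @param calls_path optional P/M/A call matrix TSV with identical layout.
#' @param probe_map_path optional 2-column headerless TSV (probe id, gene
#'   symbol).
#' @return an [expr_matrix()].
#' @export
read_expr_matrix <- function(path, calls_path = NULL, probe_map_path = NULL) {
  vals <- parse_numeric_table(read_tsv_table(path), path)
  calls <- NULL
  if (!is.null(calls_path)) {
    df <- read_tsv_table(calls_path)
    calls <- as.matrix(df[, -1, drop = FALSE])
    rownames(calls) <- df[[1]]
    if (!identical(rownames(calls), rownames(vals)) ||
        !identical(colnames(calls), colnames(vals)))
      stop("call matrix layout does not match the expression matrix",
           call. = FALSE)
  }
  p2g <- NULL
  if (!is.null(probe_map_path)) {
    df <- utils::read.delim(probe_map_path, header = FALSE, sep = "\t",
                            quote = "", comment.char = "#",
                            colClasses = "character")
    p2g <- stats::setNames(df[[2]], df[[1]])
  }
  expr_matrix(vals, calls = calls, probe_to_gene = p2g)
}

#' Filter probes on detection calls
#'
#' Retains probes detected (call `"P"` or `"M"`) in at least
#' `min_fraction_present` of samples (inclusive boundary; the conventional
#' cut is 50%).
#'
#' @param m an [expr_matrix()] with calls.
#' @param min_fraction_present minimum fraction of samples with a P or M
#'   call (default 0.5).
#' @return the filtered [expr_matrix()].
#' @export
filter_probes_by_calls <- function(m, min_fraction_present = 0.5) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(m$calls))
    stop("detection calls are required for call-based filtering",
         call. = FALSE)
  frac <- rowMeans(m$calls == "P" | m$calls == "M")
  keep <- frac >= min_fraction_present
  expr_matrix(m$values[keep, , drop = FALSE],
              calls = m$calls[keep, , drop = FALSE],
              probe_to_gene = m$probe_to_gene)
}

#' Choose one probe per reference gene (100%-present rule)
#'
#' For each reference gene, among its probes with a `"P"` call in *all*
#' samples, the probe with the highest mean intensity is chosen; one probe
#' per gene. Genes with no qualifying probe are omitted and reported via the
#' `"omitted_genes"` attribute.
#'
#' @param m an [expr_matrix()] with calls and a probe-to-gene map.
#' @param ref_genes character vector of reference gene symbols.
#' @return character vector of chosen probe ids, in `ref_genes` order, with
#'   attribute `omitted_genes`.
#' @export
choose_reference_probes <- function(m, ref_genes) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(m$probe_to_gene))
    stop("a probe-to-gene map is required", call. = FALSE)
  if (is.null(m$calls))
    stop("detection calls are required for the all-present rule",
         call. = FALSE)
  all_p <- rowMeans(m$calls == "P") == 1
  pick_probe_per_gene(m, ref_genes, eligible = all_p,
                      require_some = TRUE)
}

#' Choose one probe per reference gene by maximum mean intensity
#'
#' Platform path without detection calls: for each reference gene the probe
#' with the highest mean intensity across the dataset is chosen. Ties go to
#' the lexicographically smallest probe id.
#'
#' @inheritParams choose_reference_probes
#' @return character vector of chosen probe ids with attribute
#'   `omitted_genes` (genes with no probe on the platform).
#' @export
choose_probe_by_max_intensity <- function(m, ref_genes) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(m$probe_to_gene))
    stop("a probe-to-gene map is required", call. = FALSE)
  pick_probe_per_gene(m, ref_genes,
                      eligible = rep(TRUE, nrow(m$values)),
                      require_some = FALSE)
}

pick_probe_per_gene <- function(m, ref_genes, eligible, require_some) {
  probes <- rownames(m$values)
  means <- rowMeans(m$values)
  genes_of <- m$probe_to_gene[probes]
  chosen <- character(0)
  omitted <- character(0)
  for (g in ref_genes) {
    cand <- probes[!is.na(genes_of) & genes_of == g & eligible]
    if (!length(cand)) {
      omitted <- c(omitted, g)
      next
    }
    cand <- sort(cand)                       # lexicographic tie-break
    chosen <- c(chosen, cand[which.max(means[cand])])
  }
  if (require_some && !length(chosen))
    stop("no reference gene has a qualifying probe; scaling impossible",
         call. = FALSE)
  if (length(omitted))
    message("reference gene(s) without a qualifying probe omitted: ",
            paste(omitted, collapse = ", "))
  attr(chosen, "omitted_genes") <- omitted
  chosen
}

#' Average replicate experiments
#'
#' Collapses replicate samples of the same experiment to their per-probe
#' arithmetic mean. Detection calls (if any) are dropped, as calls cannot be
#' averaged.
#'
#' @param m an [expr_matrix()].
#' @param replicate_groups named character vector mapping every sample id to
#'   an experiment id.
#' @return an [expr_matrix()] with one column per experiment, in order of
#'   first appearance.
#' @export
collapse_replicates <- function(m, replicate_groups) {
  stopifnot(inherits(m, "expr_matrix"))
  samples <- colnames(m$values)
  missing <- setdiff(samples, names(replicate_groups))
  if (length(missing))
    stop("samples without a replicate-group assignment: ",
         paste(missing, collapse = ", "), call. = FALSE)
  grp <- replicate_groups[samples]
  exps <- unique(grp)
  out <- vapply(exps, function(e)
    rowMeans(m$values[, grp == e, drop = FALSE]), numeric(nrow(m$values)))
  out <- matrix(out, nrow = nrow(m$values),
                dimnames = list(rownames(m$values), exps))
  expr_matrix(out, probe_to_gene = m$probe_to_gene)
}

#' Fit per-sample reference-gene scaling factors
#'
#' For each reference probe the mean intensity across all samples forms the
#' target profile `y`. For every sample, with `x` its own reference-probe
#' values, the least-squares slope of `y` on `x` is the sample's scaling
#' factor. By default the regression runs through the origin
#' (`slope = sum(x*y)/sum(x^2)`), the only form that acts coherently as a
#' multiplicative correction; `intercept = TRUE` fits an ordinary regression
#' and uses its slope alone.
#'
#' @param m an [expr_matrix()].
#' @param reference_probes character vector of probe ids (at least 2) present
#'   in `m`.
#' @param intercept include an intercept in the per-sample fit (default
#'   `FALSE`).
#' @return an object of class `"ref_scaling"`: list with `reference_probes`,
#'   `mean_profile`, `slopes` (named per sample) and `intercept`. Methods:
#'   `print`, `coef` (the slopes), `predict` (apply to a matrix).
#' @seealso [apply_scaling()]
#' @export
fit_ref_scaling <- function(m, reference_probes, intercept = FALSE) {
  stopifnot(inherits(m, "expr_matrix"))
  if (length(reference_probes) < 2)
    stop("at least two reference probes are required", call. = FALSE)
  missing <- setdiff(reference_probes, rownames(m$values))
  if (length(missing))
    stop("reference probes absent from the matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ref <- m$values[reference_probes, , drop = FALSE]
  y <- rowMeans(ref)
  slopes <- vapply(colnames(ref), function(s) {
    x <- ref[, s]
    if (all(x == 0))
      stop("sample '", s, "' has all-zero reference values", call. = FALSE)
    if (intercept) {
      xc <- x - mean(x); yc <- y - mean(y)
      sum(xc * yc) / sum(xc * xc)
    } else {
      sum(x * y) / sum(x * x)
    }
  }, numeric(1))
  if (any(slopes <= 0))
    warning("non-positive scaling slope for sample(s): ",
            paste(names(slopes)[slopes <= 0], collapse = ", "))
  structure(list(reference_probes = reference_probes, mean_profile = y,
                 slopes = slopes, intercept = intercept),
            class = "ref_scaling")
}

#' @export
print.ref_scaling <- function(x, ...) {
  cat(sprintf("reference-gene scaling model: %d probes, %d samples (%s fit)\n",
              length(x$reference_probes), length(x$slopes),
              if (x$intercept) "with-intercept" else "through-origin"))
  cat("slopes:\n")
  print(round(x$slopes, 4))
  invisible(x)
}

#' @export
coef.ref_scaling <- function(object, ...) object$slopes

#' @export
predict.ref_scaling <- function(object, newdata, ...) {
  apply_scaling(newdata, object)
}

#' Apply per-sample scaling factors to an expression matrix
#'
#' Every value of sample `s` is multiplied by `model$slopes[s]`; detection
#' calls and the probe map are carried through unchanged.
#'
#' @param m an [expr_matrix()] whose samples are all covered by the model.
#' @param model a [fit_ref_scaling()] model.
#' @return the scaled [expr_matrix()].
#' @export
apply_scaling <- function(m, model) {
  stopifnot(inherits(m, "expr_matrix"), inherits(model, "ref_scaling"))
  samples <- colnames(m$values)
  missing <- setdiff(samples, names(model$slopes))
  if (length(missing))
    stop("samples missing from the scaling model: ",
         paste(missing, collapse = ", "), call. = FALSE)
  scaled <- sweep(m$values, 2, model$slopes[samples], `*`)
  expr_matrix(scaled, calls = m$calls, probe_to_gene = m$probe_to_gene)
}
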