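test_that("call filtering keeps probes detected in >= half the samples", {
  n <- 12
  calls <- rbind(boundary = rep(c("P", "A"), each = 6),
                 allA = rep("A", n),
                 marginal = rep(c("M", "A"), c(6, 6)),
                 allP = rep("P", n))
  vals <- matrix(100, nrow(calls), n,
                 dimnames = list(rownames(calls), paste0("s", 1:n)))
  colnames(calls) <- colnames(vals)
  em <- expr_matrix(vals, calls = calls)
  kept <- rownames(filter_probes_by_calls(em)$values)
  expect_setequal(kept, c("boundary", "marginal", "allP"))  # 0.5 inclusive

  expect_error(filter_probes_by_calls(expr_matrix(vals)), "calls")
})

test_that("a constructed 20-probe matrix retains exactly the passing 11", {
  n <- 10
  # probes 1..11 get P in >= 5/10 samples, probes 12..20 in <= 4/10
  present <- c(rep(5:10, length.out = 11), rep(0:4, length.out = 9))
  calls <- t(vapply(present,
                    function(k) c(rep("P", k), rep("A", n - k)),
                    character(n)))
  dimnames(calls) <- list(sprintf("pr%02d", 1:20), paste0("s", 1:n))
  vals <- matrix(1, 20, n, dimnames = dimnames(calls))
  out <- filter_probes_by_calls(expr_matrix(vals, calls = calls))
  expect_equal(nrow(out$values), 11)
  expect_setequal(rownames(out$values), sprintf("pr%02d", 1:11))
})

test_that("reference probes need all-present calls, one per gene by mean", {
  em <- toy_expr()   # GB has probes p2 (mean 912.5) and p3 (mean 1210)
  probes <- choose_reference_probes(em, c("GA", "GB", "GC"))
  expect_identical(unclass(probes)[1:3], c("p1", "p3", "p4"))

  # a single M call disqualifies a probe; its gene is omitted with a report
  em$calls["p1", "s2"] <- "M"
  probes2 <- suppressMessages(choose_reference_probes(em, c("GA", "GB")))
  expect_identical(unclass(probes2)[1], "p3")
  expect_identical(attr(probes2, "omitted_genes"), "GA")

  em$calls[] <- "M"
  expect_error(choose_reference_probes(em, c("GA", "GB")),
               "scaling impossible")
})

test_that("12 reference genes with 8 qualifying probes yield 8 probes", {
  set.seed(5)
  genes <- sprintf("G%02d", 1:12)
  probes <- sprintf("af%02d", 1:12)
  vals <- matrix(runif(12 * 6, 50, 500), 12,
                 dimnames = list(probes, paste0("s", 1:6)))
  calls <- matrix("P", 12, 6, dimnames = dimnames(vals))
  calls[9:12, 1] <- "A"          # four genes lose their only probe
  em <- expr_matrix(vals, calls = calls, probe_to_gene = setNames(genes,
                                                                  probes))
  got <- suppressMessages(choose_reference_probes(em, genes))
  expect_length(unclass(got), 8)
  expect_length(attr(got, "omitted_genes"), 4)
})

test_that("call-free probe choice takes the max-mean probe, ties by id", {
  vals <- rbind(pA = rep(100, 4), pB = rep(250, 4), pC = rep(250, 4))
  colnames(vals) <- paste0("s", 1:4)
  em <- expr_matrix(vals, probe_to_gene = c(pA = "G1", pB = "G1", pC = "G1"))
  expect_identical(unclass(choose_probe_by_max_intensity(em, "G1"))[1],
                   "pB")

  em2 <- expr_matrix(vals[2:3, ],
                     probe_to_gene = c(pB = "G1", pC = "G1"))
  expect_identical(unclass(choose_probe_by_max_intensity(em2, "G1"))[1],
                   "pB")

  # every listed gene represented -> one probe per gene
  vals3 <- matrix(runif(15 * 3, 10, 100), 15,
                  dimnames = list(sprintf("ag%02d", 1:15), paste0("s", 1:3)))
  em3 <- expr_matrix(vals3, probe_to_gene = setNames(sprintf("R%02d", 1:15),
                                                     rownames(vals3)))
  expect_length(unclass(choose_probe_by_max_intensity(em3,
                                                      sprintf("R%02d", 1:15))),
                15)
})

test_that("through-origin scaling slopes match closed-form least squares", {
  # sample s1 holds the hand case x = (1,2,3); s2 completes the mean
  # profile y = rowMeans = (2,3,5), so slope_s1 = 23/14 exactly
  vals <- cbind(s1 = c(1, 2, 3), s2 = c(3, 4, 7))
  rownames(vals) <- paste0("p", 1:3)
  em <- expr_matrix(vals)
  model <- fit_ref_scaling(em, paste0("p", 1:3))
  expect_equal(model$mean_profile, c(p1 = 2, p2 = 3, p3 = 5))
  expect_equal(unname(model$slopes["s1"]), 23 / 14)
  expect_equal(unname(model$slopes["s2"]), (6 + 12 + 35) / (9 + 16 + 49))

  # a sample at exactly half the mean profile gets slope 2, one matching
  # the profile gets slope 1 (mean profile includes the sample itself, so
  # the other samples are arranged to keep it at (2, 3, 5))
  y <- c(2, 3, 5)
  vals2 <- cbind(half = y / 2, f1 = y * 1.25, f2 = y * 1.25)
  rownames(vals2) <- paste0("p", 1:3)
  m2 <- fit_ref_scaling(expr_matrix(vals2), paste0("p", 1:3))
  expect_equal(unname(m2$mean_profile), y)
  expect_equal(unname(m2$slopes["half"]), 2)
  expect_equal(unname(m2$slopes["f1"]), 1 / 1.25)

  expect_error(fit_ref_scaling(em, "p1"), "at least two")
  vals3 <- cbind(s1 = c(1, 2), s2 = c(0, 0))
  rownames(vals3) <- c("p1", "p2")
  expect_error(fit_ref_scaling(expr_matrix(vals3), c("p1", "p2")),
               "'s2' has all-zero reference values")
})

test_that("applying the fit aligns every sample with the mean profile", {
  set.seed(13)
  vals <- matrix(runif(6 * 5, 10, 1000), 6,
                 dimnames = list(paste0("p", 1:6), paste0("s", 1:5)))
  em <- expr_matrix(vals)
  refs <- paste0("p", 1:4)
  model <- fit_ref_scaling(em, refs)
  scaled <- apply_scaling(em, model)

  # refitting the original mean profile on the scaled data gives slope 1
  refit <- vapply(colnames(vals), function(s) {
    x <- scaled$values[refs, s]
    sum(x * model$mean_profile) / sum(x * x)
  }, numeric(1))
  expect_equal(unname(refit), rep(1, 5), tolerance = 1e-9)

  # within-sample ratios are untouched (per-sample scalar)
  expect_equal(scaled$values[1, ] / scaled$values[2, ],
               vals[1, ] / vals[2, ])

  # slopes are strictly positive for strictly positive reference values
  expect_true(all(model$slopes > 0))

  # a matrix already matching the mean profile is a fixed point
  fp <- matrix(rep(c(3, 7, 11), 3), 3,
               dimnames = list(paste0("p", 1:3), paste0("s", 1:3)))
  mf <- fit_ref_scaling(expr_matrix(fp), paste0("p", 1:3))
  expect_equal(apply_scaling(expr_matrix(fp), mf)$values, fp)

  expect_error(apply_scaling(expr_matrix(vals), fit_ref_scaling(
    expr_matrix(vals[, 1:3]), refs)), "missing from the scaling model")
})

test_that("intercept-variant slope matches ordinary regression", {
  vals <- cbind(s1 = c(1, 2, 3, 5), s2 = c(2, 2, 4, 6))
  rownames(vals) <- paste0("p", 1:4)
  em <- expr_matrix(vals)
  model <- fit_ref_scaling(em, paste0("p", 1:4), intercept = TRUE)
  y <- rowMeans(vals)
  for (s in colnames(vals)) {
    expect_equal(unname(model$slopes[s]),
                 unname(coef(lm(y ~ vals[, s]))[2]))
  }
})

test_that("replicate collapse averages per experiment", {
  vals <- matrix(c(4, 6, 2, 8, 1, 3,
                   10, 10, 5, 7, 0, 6,
                   1, 2, 3, 4, 5, 6,
                   9, 9, 9, 9, 9, 9), nrow = 4, byrow = TRUE,
                 dimnames = list(paste0("p", 1:4), paste0("s", 1:6)))
  reps <- setNames(rep(c("e1", "e2", "e3"), each = 2), paste0("s", 1:6))
  out <- collapse_replicates(expr_matrix(vals), reps)
  expect_equal(dim(out$values), c(4L, 3L))
  # brute-force cell-by-cell expectation
  expected <- cbind(e1 = rowMeans(vals[, 1:2]),
                    e2 = rowMeans(vals[, 3:4]),
                    e3 = rowMeans(vals[, 5:6]))
  expect_equal(out$values, expected)
  expect_equal(out$values["p1", "e1"], 5)   # mean of (4, 6)

  # single-replicate experiments pass through unchanged
  solo <- collapse_replicates(expr_matrix(vals[, 1, drop = FALSE]),
                              c(s1 = "e1"))
  expect_equal(unname(solo$values), unname(vals[, 1, drop = FALSE]))

  expect_error(collapse_replicates(expr_matrix(vals), reps[-1]),
               "without a replicate-group")
})
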