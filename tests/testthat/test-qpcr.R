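test_that("dCt variance is the unbiased variance of paired Ct differences", {
  d <- toy_qpcr()
  v <- dct_variance(d)
  expect_equal(unname(v["hk"]), 0)      # identical Ct in tumor and normal
  expect_equal(unname(v["up"]), 1)      # dCt = (-1, -2, -3), var = 1
  expect_equal(unname(v["dn"]), 0)      # constant +1 shift: variance-blind

  one_pair <- qpcr_dataset(d$ct[, c("T1", "N1")],
                           pairs = data.frame(tumor = "T1", normal = "N1"))
  expect_error(dct_variance(one_pair), "at least two")
})

test_that("Ct converts to relative quantities anchored at the minimum", {
  d <- toy_qpcr()
  q <- ct_to_quantity(d)
  expect_equal(unname(q["hk", c("T1", "T2", "T3")]), c(1, 0.5, 0.125))
  expect_true(all(q > 0))
  expect_equal(max(q["dn", ]), 1)

  # efficiency other than 2 changes the decay per cycle
  d3 <- qpcr_dataset(d$ct, d$pairs, efficiency = 1.9)
  expect_equal(unname(ct_to_quantity(d3)["hk", "T2"]), 1 / 1.9)
  expect_error(qpcr_dataset(d$ct, d$pairs, efficiency = 1), "exceed 1")
})

test_that("geNorm M equals the mean pairwise log-ratio SD (hand oracle)", {
  # 3 genes x 4 samples, chosen on the log2 scale; pairwise SDs computed
  # explicitly below, independent of the implementation
  L <- rbind(g1 = c(0, 1, 2, 3),
             g2 = c(0.2, 1.1, 2.4, 2.9),
             g3 = c(2, 1, 0, 1))
  colnames(L) <- paste0("s", 1:4)
  q <- 2^L
  v12 <- sd(L["g1", ] - L["g2", ])
  v13 <- sd(L["g1", ] - L["g3", ])
  v23 <- sd(L["g2", ] - L["g3", ])
  m <- genorm_m(q)
  expect_equal(unname(m), c((v12 + v13) / 2, (v12 + v23) / 2,
                            (v13 + v23) / 2))

  # proportional genes have zero pairwise variation
  qp <- rbind(a = c(1, 2, 4), b = c(3, 6, 12))
  colnames(qp) <- paste0("s", 1:3)
  expect_equal(unname(genorm_m(qp)), c(0, 0))

  # with exactly two genes M_1 = M_2 = V_12 structurally
  q2 <- q[1:2, ]
  expect_equal(unname(genorm_m(q2)), rep(v12, 2))

  expect_error(genorm_m(rbind(a = c(1, 0), b = c(1, 1))), "positive")
})

test_that("geNorm M is exactly invariant to per-gene rescaling", {
  set.seed(31)
  q <- matrix(2^rnorm(5 * 8), 5, dimnames = list(paste0("g", 1:5),
                                                 paste0("s", 1:8)))
  m0 <- genorm_m(q)
  q2 <- q * c(1000, 0.001, 7, 1, 42)   # recycled down columns: per gene
  expect_equal(genorm_m(q2), m0, tolerance = 1e-12)
})

test_that("stepwise geNorm eliminates the least stable gene first", {
  set.seed(7)
  base <- rnorm(6)
  q <- rbind(stable1 = 2^(base + rnorm(6, 0, 0.05)),
             stable2 = 2^(base + rnorm(6, 0, 0.05)),
             stable3 = 2^(base + rnorm(6, 0, 0.08)),
             wild = 2^rnorm(6, 0, 3))
  colnames(q) <- paste0("s", 1:6)
  sw <- genorm_stepwise(q)
  expect_identical(sw$elimination_order[1], "wild")
  expect_setequal(sw$final_pair, c("stable1", "stable2"))
})

test_that("model-based stability favours constant genes, penalizes shifts", {
  set.seed(17)
  n <- 8
  groups <- setNames(rep(c("t", "n"), each = n / 2), paste0("s", 1:n))
  L <- rbind(const = rep(1.5, n),
             noisy1 = rnorm(n, 5, 1),
             noisy2 = rnorm(n, 2, 1),
             noisy3 = rnorm(n, 8, 1))
  colnames(L) <- names(groups)
  rho <- normfinder_stability(L, groups)
  expect_equal(names(which.min(rho)), "const")

  # planted group shift: same noise, stability strictly worse (many seeds)
  n2 <- 16
  groups2 <- setNames(rep(c("t", "n"), each = n2 / 2), paste0("s", 1:n2))
  worse <- vapply(1:30, function(s) {
    set.seed(s)
    A <- rnorm(n2, 5, 1)
    B <- rnorm(n2, 5, 1) + ifelse(groups2 == "t", 2, 0)
    L2 <- rbind(A = A, B = B,
                f1 = rnorm(n2, 3, 1), f2 = rnorm(n2, 6, 1),
                f3 = rnorm(n2, 4, 1), f4 = rnorm(n2, 5, 1))
    colnames(L2) <- names(groups2)
    r <- normfinder_stability(L2, groups2)
    r["A"] < r["B"]
  }, logical(1))
  expect_gte(mean(worse), 0.95)

  # permuting sample order changes nothing
  set.seed(2)
  L3 <- matrix(rnorm(4 * n), 4, dimnames = list(paste0("g", 1:4),
                                                names(groups)))
  perm <- sample(colnames(L3))
  expect_equal(normfinder_stability(L3[, perm], groups),
               normfinder_stability(L3, groups))

  expect_error(normfinder_stability(L[, 1:5],
                                    setNames(c(rep("t", 4), "n"),
                                             paste0("s", 1:5))),
               "at least two samples")
  expect_error(normfinder_stability(L[1:2, ], groups), "at least 3 genes")

  # single-group variant: within-group variability only
  rho1 <- normfinder_stability(L, setNames(rep("all", n), names(groups)))
  expect_equal(names(which.min(rho1)), "const")
})

test_that("competition ranking assigns shared minimum ranks", {
  expect_equal(unname(rank_metric(c(0.011, 2.011, 1.517))), c(1L, 3L, 2L))
  r <- rank_metric(c(a = 1, b = 1, c = 5))
  expect_equal(unname(r), c(1L, 1L, 3L))
  expect_named(r, c("a", "b", "c"))
  expect_equal(unname(rank_metric(c(3, 9, 1), lower_is_better = FALSE)),
               c(2L, 1L, 3L))
  # validity: min rank 1; every rank r has all better values ranked below r
  set.seed(12)
  for (i in 1:20) {
    v <- sample(1:6, 8, replace = TRUE)
    r <- rank_metric(setNames(v, letters[1:8]))
    expect_equal(min(r), 1L)
    for (j in seq_along(v)) expect_equal(unname(r[j]), sum(v < v[j]) + 1L)
  }
  expect_error(rank_metric(c(1, NA)), "finite")
})

test_that("cumulative ranks sum the per-metric ranks", {
  ranks <- list(dct = c(NDUFA1 = 4L, x = 1L, y = 2L),
                nf = c(NDUFA1 = 2L, x = 3L, y = 1L),
                gm = c(NDUFA1 = 5L, x = 2L, y = 1L))
  agg <- cumulative_ranking(ranks)
  expect_equal(agg$cumulative_rank[agg$gene == "NDUFA1"], 11L)

  # full consensus: cumulative = 3 * rank, order preserved
  cons <- lapply(1:3, function(i) setNames(1:4, letters[1:4]))
  names(cons) <- c("a1", "a2", "a3")
  agg2 <- cumulative_ranking(cons)
  expect_equal(agg2$cumulative_rank, c(3L, 6L, 9L, 12L))
  expect_identical(agg2$gene, letters[1:4])

  ranks$gm <- c(NDUFA1 = 5L, x = 2L, z = 1L)
  expect_error(cumulative_ranking(ranks), "identical gene sets")
})

test_that("the full Ct pipeline produces a coherent report", {
  sim <- simulate_qpcr(n_genes = 10, n_pairs = 8, seed = 6)
  rep <- qpcr_stability(sim$data)
  expect_s3_class(rep, "stability_report")
  expect_equal(nrow(rep), 10)
  expect_equal(rep$cumulative_rank,
               rep$dct_rank + rep$normfinder_rank + rep$genorm_rank)
  expect_false(is.unsorted(rep$cumulative_rank))
  expect_output(print(rep), "stability ranking")
})
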