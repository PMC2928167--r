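# fixtures are built in code; no binary data anywhere

toy_counts <- function() {
  m <- matrix(c(5, 0, 2, 7, 0, 1), nrow = 3, byrow = TRUE,
              dimnames = list(c("t1", "t2", "t3"), c("lib1", "lib2")))
  count_matrix(m, unit = "raw")
}

write_toy_tsv <- function(mat, path = tempfile(fileext = ".tsv"),
                          id_col = "id") {
  lines <- c(paste(c(id_col, colnames(mat)), collapse = "\t"),
             vapply(seq_len(nrow(mat)),
                    function(i) paste(c(rownames(mat)[i], mat[i, ]),
                                      collapse = "\t"),
                    character(1)))
  writeLines(lines, path)
  path
}

# expression fixture: 4 probes x 4 samples with a probe->gene map and calls
toy_expr <- function() {
  v <- matrix(c(100, 110, 90, 95,
                900, 950, 880, 920,
                1200, 1250, 1180, 1210,
                50, 55, 45, 52),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("p", 1:4), paste0("s", 1:4)))
  calls <- matrix("P", 4, 4, dimnames = dimnames(v))
  p2g <- c(p1 = "GA", p2 = "GB", p3 = "GB", p4 = "GC")
  expr_matrix(v, calls = calls, probe_to_gene = p2g)
}

# delta-method Monte-Carlo standard error of the permutation score,
# from the retained null draws and the observed difference
mc_ps_se <- function(draws, O) {
  m <- length(draws)
  mu <- mean(draws)
  s2 <- mean((draws - mu)^2)
  s <- sqrt(s2)
  D <- O - mu
  ps <- abs(D) / s
  m3 <- mean((draws - mu)^3)
  m4 <- mean((draws - mu)^4)
  v <- 1 / m + ps^2 * (m4 / s2^2 - 1) / (4 * m) +
    sign(D) * ps * m3 / (s^3 * m)
  sqrt(max(v, 1 / m))
}

# hand-computable paired Ct dataset: 3 genes, 3 pairs
toy_qpcr <- function() {
  ct <- rbind(hk = c(20, 21, 23, 20, 21, 23),       # identical dCt = 0
              up = c(18, 19, 20, 19, 21, 23),       # dCt = -1, -2, -3
              dn = c(25, 25, 25, 24, 24, 24))       # dCt = +1 everywhere
  colnames(ct) <- c("T1", "T2", "T3", "N1", "N2", "N3")
  qpcr_dataset(ct, pairs = data.frame(tumor = c("T1", "T2", "T3"),
                                      normal = c("N1", "N2", "N3")))
}
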