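test_that("median polish fits additive structure exactly", {
  # purely additive matrix: residuals vanish, effects recovered up to the
  # centering convention
  c_s <- c(7, 8, 9.5)
  p_k <- c(-0.4, 0.1, 0.3, 0)
  x <- outer(p_k, c_s, "+")
  dimnames(x) <- list(paste0("p", 1:4), paste0("s", 1:3))
  fit <- fit_gene_model(x)
  expect_lt(max(abs(fit$residuals)), 1e-9)
  expect_equal(median(fit$probe_effects), 0, tolerance = 1e-9)
  expect_equal(unname(fit$chip_effects - c_s),
               rep(unname(fit$chip_effects - c_s)[1], 3), tolerance = 1e-9)
  # reconstruction identity
  recon <- outer(fit$probe_effects, rep(1, 3)) +
    rep(fit$chip_effects, each = 4) + fit$residuals
  expect_equal(unname(recon), unname(x), tolerance = 1e-12)

  # constant matrix
  cm <- matrix(5, 3, 4, dimnames = list(paste0("p", 1:3), paste0("s", 1:4)))
  fitc <- fit_gene_model(cm)
  expect_equal(unname(fitc$chip_effects), rep(5, 4))
  expect_equal(unname(fitc$probe_effects), rep(0, 3))
  expect_equal(unname(fitc$residuals), matrix(0, 3, 4))

  # degenerate 1x1
  one <- matrix(3.5, 1, 1, dimnames = list("p", "s"))
  fit1 <- fit_gene_model(one)
  expect_equal(unname(fit1$chip_effects), 3.5)
  expect_equal(unname(fit1$residuals), matrix(0, 1, 1))
})

test_that("median polish agrees with the independent sweep oracle on random matrices", {
  set.seed(101)
  for (i in 1:25) {
    nr <- sample(2:8, 1); nc <- sample(2:8, 1)
    x <- matrix(rnorm(nr * nc, 8, 2), nr, nc,
                dimnames = list(paste0("p", 1:nr), paste0("s", 1:nc)))
    fit <- fit_gene_model(x)
    ref <- oracle_median_polish(x)
    expect_equal(unname(fit$residuals), unname(ref$residuals), tolerance = 1e-9)
    expect_equal(unname(fit$probe_effects), ref$row_eff, tolerance = 1e-9)
    expect_equal(unname(fit$chip_effects), ref$col_eff, tolerance = 1e-9)
    # reconstruction to 1e-9 and near-zero residual medians at convergence
    recon <- outer(fit$probe_effects, rep(1, nc)) +
      rep(fit$chip_effects, each = nr) + fit$residuals
    expect_lt(max(abs(recon - x)), 1e-9)
  }
})

test_that("FIRMA scores localize a constructed exon-level perturbation", {
  set.seed(5)
  cd <- toy_chipdef()
  c_s <- rnorm(6, 8, 1)
  samples <- paste0("s", 1:6)
  # gene GA: probes P1..P4, sets E1 (P1,P2) and E2 (P3,P4)
  p_k <- rnorm(4, 0, 0.5)
  x <- outer(p_k, c_s, "+")
  dimnames(x) <- list(c("P1", "P2", "P3", "P4"), samples)
  # (near-)zero residuals -> all scores zero, with the floor-rule warning
  fit0 <- fit_gene_model(x)
  expect_warning(sc0 <- firma_score(fit0, c("E1", "E1", "E2", "E2")),
                 "floored")
  expect_equal(unname(sc0), matrix(0, 2, 6), tolerance = 1e-12)

  # shift E2's probes by +delta in sample 3 on otherwise additive data
  delta <- 1.5
  x2 <- x + matrix(rnorm(24, 0, 0.05), 4, 6)
  x2[c("P3", "P4"), 3] <- x2[c("P3", "P4"), 3] + delta
  fit2 <- fit_gene_model(x2)
  sc2 <- firma_score(fit2, c("E1", "E1", "E2", "E2"))
  expect_equal(unname(which(abs(sc2) == max(abs(sc2)), arr.ind = TRUE)[1, ]),
               c(2, 3))
  expect_gt(sc2["E2", 3], 0)
})

test_that("FIRMA scores are invariant to sample-wise expression shifts", {
  set.seed(6)
  x <- matrix(rnorm(8 * 5, 8, 1), 8, 5,
              dimnames = list(paste0("P", 1:8), paste0("s", 1:5)))
  sets <- rep(c("E1", "E2"), each = 4)
  sc1 <- firma_score(fit_gene_model(x), sets)
  shift <- rnorm(5, 0, 2)
  x2 <- x + rep(shift, each = 8)
  sc2 <- firma_score(fit_gene_model(x2), sets)
  expect_equal(sc1, sc2, tolerance = 1e-9)
})

test_that("whole-series FIRMA matches the per-gene oracle", {
  set.seed(7)
  cd <- toy_chipdef()
  lin <- matrix(2^rnorm(8 * 5, 8, 1), 8, 5,
                dimnames = list(cd$probe_id, paste0("s", 1:5)))
  ff <- quiet(firma(lin, cd, bg_correct = FALSE))
  lognorm <- log2(quantile_normalize(lin))
  for (g in c("GA", "GB")) {
    rows <- cd$probe_id[cd$gene_id == g]
    ref <- oracle_firma_gene(lognorm[rows, ], cd$probe_set_id[cd$gene_id == g])
    expect_equal(ff$scores[rownames(ref), ], ref, tolerance = 1e-9)
  }
})

test_that("gene expression summarization equals polish chip effects", {
  set.seed(8)
  cd <- toy_chipdef()
  # single-probe gene appended
  cd2 <- new_chipdef(rbind(tibble::as_tibble(unclass(cd)),
                           tibble::tibble(probe_id = "P9", probe_set_id = "E5",
                                          gene_id = "GC")))
  m <- matrix(rnorm(9 * 4, 8, 1), 9, 4,
              dimnames = list(cd2$probe_id, paste0("s", 1:4)))
  expr <- summarize_gene_expression(m, cd2)
  expect_equal(dim(expr), c(3L, 4L))
  # single-probe gene: expression equals that probe's values
  expect_equal(expr["GC", ], m["P9", ], tolerance = 1e-12)
  # matches the sweep oracle per gene
  for (g in c("GA", "GB")) {
    rows <- cd2$probe_id[cd2$gene_id == g]
    ref <- oracle_median_polish(m[rows, ])
    expect_equal(unname(expr[g, ]), ref$col_eff, tolerance = 1e-9)
  }
  # additive synthetic gene recovers chip effects up to a shared constant
  c_s <- c(5, 6, 9, 7)
  add <- outer(c(-0.2, 0.4, 0.1, 0, -0.1, 0.2, 0.3, -0.3, 0), c_s, "+")
  dimnames(add) <- dimnames(m)
  expr2 <- summarize_gene_expression(add, cd2)
  d <- expr2["GA", ] - c_s
  expect_equal(unname(d), rep(unname(d)[1], 4), tolerance = 1e-9)
})

test_that("identifier mismatches are rejected unless subsetting is requested", {
  cd <- toy_chipdef()
  m <- matrix(2^rnorm(7 * 3, 8, 1), 7, 3,
              dimnames = list(cd$probe_id[1:7], paste0("s", 1:3)))
  expect_error(quiet(firma(m, cd, bg_correct = FALSE)), "absent from the intensity matrix")
  ff <- quiet(firma(m, cd, bg_correct = FALSE, allow_subset = TRUE))
  expect_equal(nrow(ff$expression), 2)
})
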