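test_that("Z-scoring standardizes every retained gene", {
  m <- matrix(c(1, 2, 3, 5, 5, 5, 2, 4, 9), 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("a", "b", "c")))
  expect_message(z <- zscore_matrix(m), "zero-variance")
  expect_false("g2" %in% rownames(z))
  expect_equal(unname(z["g1", ]), c(-1, 0, 1))
  expect_true(all(abs(rowMeans(z)) < 1e-12))
  expect_true(all(abs(apply(z, 1, sd) - 1) < 1e-12))
  expect_error(zscore_matrix(m[, 1:2]), "3 subjects")
})

test_that("summed Z-scores match their definition and a loop oracle", {
  z <- rbind(g1 = c(-1, 0, 1), g2 = c(-1, 0, 1), g3 = c(2, -1, 0))
  colnames(z) <- c("a", "b", "c")
  s <- summed_zscore(z, sig("s", up = c("g1", "g2")))
  expect_equal(unname(s), c(-2, 0, 2), ignore_attr = TRUE)
  expect_equal(attr(s, "coverage"), 1)
  # identical up and down rows cancel
  s0 <- summed_zscore(z, sig("m", up = "g1", down = "g2"))
  expect_equal(unname(s0), c(0, 0, 0), ignore_attr = TRUE)
  # loop oracle on random input
  set.seed(31)
  zz <- matrix(rnorm(50 * 20), 50,
               dimnames = list(sprintf("g%02d", 1:50), sprintf("c%02d", 1:20)))
  for (k in 1:10) {
    ss <- random_signature(paste0("r", k), rownames(zz), n_max = 20L)
    if (length(signature_genes(ss)) == 0) next
    got <- summed_zscore(zz, ss)
    want <- vapply(colnames(zz), function(j) {
      tot <- 0
      for (g in ss$up) tot <- tot + zz[g, j]
      for (g in ss$down) tot <- tot - zz[g, j]
      tot
    }, numeric(1))
    expect_equal(unname(got), unname(want), tolerance = 1e-10, ignore_attr = TRUE)
  }
  # missing genes: coverage reported, zero coverage is an error
  expect_warning(s2 <- summed_zscore(z, sig("p", up = c("g1", "zz", "yy"))),
                 "coverage")
  expect_equal(attr(s2, "coverage"), 1 / 3)
  expect_error(summed_zscore(z, sig("q", up = "zz")), "zero coverage")
  # normalization divides by contributing genes
  sn <- summed_zscore(z, sig("s", up = c("g1", "g2")), normalize = TRUE)
  expect_equal(unname(sn), c(-1, 0, 1), ignore_attr = TRUE)
  # separate mode scores the two directions independently
  sp <- summed_zscore(z, sig("m", up = "g1", down = "g3"), mode = "separate")
  expect_equal(unname(sp["up", ]), unname(z["g1", ]), ignore_attr = TRUE)
  expect_equal(unname(sp["down", ]), unname(z["g3", ]), ignore_attr = TRUE)
})

test_that("score_all matches one-by-one calls and drops dead signatures", {
  set.seed(8)
  z <- matrix(rnorm(30 * 6), 30,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("c%d", 1:6)))
  sl <- list(sig("one", up = rownames(z)[1:5]),
             sig("two", down = rownames(z)[6:9]))
  sm <- score_all(z, sl)
  expect_identical(rownames(sm), c("one", "two"))
  expect_equal(sm["one", ], summed_zscore(z, sl[[1]])[colnames(z)],
               ignore_attr = TRUE)
  expect_identical(sm, score_all(z, sl))
  expect_warning(sm2 <- score_all(z, c(sl, list(sig("dead", up = "nope")))),
                 "dead")
  expect_identical(nrow(sm2), 2L)
})

test_that("intersignature correlation behaves like Pearson", {
  sm <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8), c = c(4, 3, 2, 1))
  r <- intersignature_correlation(sm)
  expect_equal(r["a", "b"], 1)
  expect_equal(r["a", "c"], -1)
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  # affine rescaling leaves the matrix unchanged
  sm2 <- sm; sm2["a", ] <- sm["a", ] * 10 + 5
  expect_equal(intersignature_correlation(sm2), r)
  expect_warning(rc <- intersignature_correlation(rbind(sm, d = rep(1, 4))),
                 "constant")
  expect_true(all(is.na(rc["d", c("a", "b", "c")])))
})

test_that("UPGMA clustering follows average-linkage arithmetic", {
  # two items merge at their distance
  r2 <- matrix(c(1, 0.6, 0.6, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  t2 <- cluster_responses(r2)
  expect_equal(t2$height, 0.4)
  # three items: d(1,2)=0.1, d(1,3)=d(2,3)=0.8
  d3 <- matrix(c(0, 0.1, 0.8, 0.1, 0, 0.8, 0.8, 0.8, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- cluster_responses(1 - d3)
  expect_equal(t3$height, c(0.1, 0.8))
  expect_equal(cophenetic_height(t3, "A", "B"), 0.1)
  expect_equal(cophenetic_height(t3, "A", "C"), 0.8)
  # duplicated item merges at height 0
  r4 <- matrix(1, 2, 2, dimnames = list(c("p", "q"), c("p", "q")))
  expect_equal(cluster_responses(r4)$height, 0)
  expect_error(cluster_responses(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
  # label-order determinism: permuting the input changes nothing
  set.seed(12)
  m <- matrix(rnorm(5 * 10), 5, dimnames = list(letters[1:5], NULL))
  rr <- cor(t(m))
  perm <- c(3, 1, 5, 2, 4)
  t_a <- cluster_responses(rr)
  t_b <- cluster_responses(rr[perm, perm])
  expect_equal(sort(t_a$height), sort(t_b$height))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_equal(cophenetic_height(t_a, letters[i], letters[j]),
                 cophenetic_height(t_b, letters[i], letters[j]))
  }
})

test_that("Newick export parses in a standard tree reader", {
  skip_if_not_installed("ape")
  set.seed(4)
  m <- matrix(rnorm(4 * 12), 4, dimnames = list(c("XXF", "XXM", "XYF", "XYM"),
                                                NULL))
  tr <- cluster_responses(cor(t(m)))
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, path)
  phy <- ape::read.tree(path)
  expect_setequal(phy$tip.label, c("XXF", "XXM", "XYF", "XYM"))
  # ultrametric with root depth = max height / 2
  depths <- ape::node.depth.edgelength(phy)[seq_len(4)]
  expect_equal(unname(depths), rep(max(tr$height) / 2, 4), tolerance = 1e-8)
  expect_s3_class(as_hclust(tr), "hclust")
})

test_that("clinical association encodes variables and stratifies by sex", {
  clin <- data.frame(
    subject_id = sprintf("s%02d", 1:12),
    sex = rep(c("F", "M"), each = 6),
    gestational_age = c(25, 26, 27, 28, 29, 30, 25, 26, 27, 28, 29, 30),
    birth_weight = seq(700, 1800, length.out = 12),
    bpd_status = factor(rep(c("none", "mild", "moderate", "severe"), 3),
                        levels = c("none", "mild", "moderate", "severe"),
                        ordered = TRUE),
    o2_at_28d = rep(c("no", "yes"), 6)
  )
  # scores equal to the encoded variable give r = 1 in every stratum
  enc_bpd <- as.integer(clin$bpd_status) - 1
  sm <- rbind(mirror = enc_bpd)
  colnames(sm) <- clin$subject_id
  out <- clinical_association(sm, clin)
  got <- out[out$variable == "bpd_status", ]
  expect_equal(got$r, rep(1, 3), tolerance = 1e-12)
  expect_setequal(got$stratum, c("all", "F", "M"))
  # a stratum below 3 subjects is reported missing
  small <- clin[c(1:6, 7, 8), ]
  sm2 <- sm[, c(1:6, 7, 8), drop = FALSE]
  out2 <- clinical_association(sm2, small)
  expect_true(all(is.na(out2$r[out2$stratum == "M"])))
  expect_error(clinical_association(sm, clin[1:3, ]), "differ")
})
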