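test_that("size factors follow the median-of-ratios definition", {
  m <- matrix(c(10, 20, 10, 20), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  m2 <- matrix(c(10, 20, 20, 40), 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-6)
  # only gene 2 eligible (gene 1 has a zero)
  m3 <- matrix(c(0, 10, 5, 10), 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_equal(unname(size_factors(m3)), c(1, 1))
  expect_error(size_factors(matrix(0, 2, 2)), "all-zero")
  # fallback: no gene positive everywhere
  m4 <- matrix(c(0, 10, 5, 0), 2,
               dimnames = list(c("g1", "g2"), c("a", "b")))
  expect_warning(s4 <- size_factors(m4), "library-size")
  expect_equal(unname(s4), c(10, 5) / sqrt(50), tolerance = 1e-10)
})

test_that("log normalization keeps zeros at zero and scales by s", {
  m <- matrix(c(0, 15, 2, 30), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  norm <- log_normalize(m, s = c(a = 1, b = 2))
  expect_identical(norm$log2["g1", "a"], 0)
  expect_identical(norm$log2["g1", "b"], 1)     # 2/2 = 1 -> log2(2)
  expect_identical(norm$log2["g2", "a"], 4)     # log2(16)
  expect_error(log_normalize(matrix(-1, 1, 1)), "non-negative")
  expect_error(log_normalize(m, s = c(1, -1)), "positive")
})

test_that("moderated test reproduces the worked single-gene example", {
  m <- matrix(c(1, 2, 3, 3, 4, 5), 1,
              dimnames = list("g1", paste0("s", 1:6)))
  tab <- moderated_two_group_test(m, paste0("s", 1:3), paste0("s", 4:6),
                                  d0 = 4)
  # single gene: s0^2 = s^2 = 1; s2_mod = 1; t = 2/sqrt(2/3)
  expect_equal(tab$log2fc, 2)
  expect_equal(tab$t, 2 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(tab$df, 8)
  expect_equal(tab$p, 0.040, tolerance = 1e-3)
})

test_that("d0 = 0 reduces exactly to the classical pooled t-test", {
  set.seed(11)
  m <- matrix(rnorm(100 * 8), 100,
              dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:8)))
  ga <- paste0("s", 1:4); gb <- paste0("s", 5:8)
  tab <- moderated_two_group_test(m, ga, gb, d0 = 0)
  for (i in seq_len(nrow(m))) {
    tt <- t.test(m[i, gb], m[i, ga], var.equal = TRUE)
    expect_equal(tab$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(tab$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated test guards its preconditions", {
  m <- matrix(rnorm(20), 2, dimnames = list(c("g1", "g2"), paste0("s", 1:10)))
  expect_error(moderated_two_group_test(m, c("s1", "s2"), c("s2", "s3")),
               "overlap")
  expect_error(moderated_two_group_test(m, "s1", c("s2", "s3")), "at least 2")
  expect_error(moderated_two_group_test(m, c("s1", "sX"), c("s2", "s3")),
               "sX")
  flat <- matrix(5, 2, 6, dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  expect_warning(tab <- moderated_two_group_test(flat, paste0("s", 1:3),
                                                 paste0("s", 4:6)),
                 "zero within-group variance")
  expect_equal(tab$t, c(0, 0))
  expect_equal(tab$p, c(1, 1))
})

test_that("empirical variance prior recovers known hyperparameters", {
  set.seed(21)
  d0_true <- 8; s0_true <- 0.25; df <- 4
  s2 <- s0_true * stats::rf(20000, df, d0_true)
  fit <- fit_variance_prior(s2, df)
  expect_equal(fit$d0, d0_true, tolerance = 0.15)
  expect_equal(fit$s0_sq, s0_true, tolerance = 0.05)
  # homogeneous true variances -> (near) complete shrinkage
  s2h <- 0.5 * stats::rchisq(5000, df) / df
  fith <- fit_variance_prior(s2h, df)
  expect_gt(fith$d0, 50)
  expect_equal(fith$s0_sq, 0.5, tolerance = 0.05)
  # log-variance spread below the sampling floor gives d0 = Inf exactly
  fitc <- fit_variance_prior(rep(0.5, 100), df)
  expect_true(is.infinite(fitc$d0))
})

test_that("BH adjustment matches its closed-form examples and p.adjust", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.04)), c(0.01, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(3)
  for (k in 1:5) {
    p <- runif(50)
    expect_equal(bh_adjust(p), p.adjust(p, "BH"), tolerance = 1e-12)
    perm <- sample(50)
    expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]), tolerance = 1e-12)
  }
})

test_that("signature calling applies both thresholds inclusively", {
  tab <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(2, 0.5, -1.0, 1.5),
                    q = c(0.01, 0.01, 0.05, 0.8))
  s <- call_degs(tab, fdr_max = 0.05, lfc_min = 1, name = "toy")
  expect_identical(s$up, "a")
  expect_identical(s$down, "c")   # ties at both thresholds included
  empty <- call_degs(transform(tab, q = 1), name = "none")
  expect_length(c(empty$up, empty$down), 0)
  expect_error(call_degs(tab, fdr_max = 0), "positive")
  # monotonicity: raising lfc_min never enlarges a signature
  set.seed(5)
  big <- data.frame(gene = sprintf("g%02d", 1:60),
                    log2fc = rnorm(60, 0, 2), q = runif(60))
  prev <- Inf
  for (lfc in c(0.5, 1, 1.5, 2)) {
    s <- call_degs(big, lfc_min = lfc)
    n <- length(s$up) + length(s$down)
    expect_lte(n, prev)
    prev <- n
  }
})

test_that("hyperoxia contrasts recover planted treatment effects", {
  fx <- small_study()
  hc <- hyperoxia_contrasts(fx$study, "P5")
  expect_named(hc, c("XXF", "XXM", "XYF", "XYM"))
  core <- names(fx$effects$core_response)
  for (g in names(hc)) {
    s <- hc[[g]]$signature
    expect_gt(mean(core %in% c(s$up, s$down)), 0.6)
    # planted direction is respected for recovered core genes
    up_true <- names(fx$effects$core_response)[fx$effects$core_response > 0]
    expect_length(intersect(s$down, up_true), 0)
  }
  # chromosomal interaction genes: in XY signatures, largely absent from XX
  inter <- names(fx$effects$xx_protective)
  xy_rec <- mean(inter %in% unlist(lapply(hc[c("XYF", "XYM")], function(x)
    signature_genes(x$signature))))
  xx_rec <- mean(inter %in% unlist(lapply(hc[c("XXF", "XXM")], function(x)
    signature_genes(x$signature))))
  expect_gt(xy_rec, 0.5)
  expect_lt(xx_rec, 0.1)
  expect_error(hyperoxia_contrasts(fx$study, "P99"), "design cell")
})

test_that("intergenotype contrasts expose sex-chromosome structure", {
  fx <- small_study()
  ic <- intergenotype_contrasts(fx$study, "RA", "P5")
  expect_length(ic, 6)
  yg <- fx$effects$y_only
  esc <- fx$effects$x_escapees
  for (nm in names(ic)) {
    g2 <- substr(nm, 1, 3)
    g1 <- substr(sub("^[A-Z]+_vs_", "", nm), 1, 3)
    s <- ic[[nm]]$signature
    if (substr(g1, 1, 2) != substr(g2, 1, 2)) {
      # Y genes always separate XX from XY, in the XY-up direction
      y_dir <- if (substr(g2, 1, 2) == "XY") s$up else s$down
      expect_gt(mean(yg %in% y_dir), 0.9)
      # escapees are never called in the wrong (XY-up) direction
      wrong <- if (substr(g2, 1, 2) == "XY") s$up else s$down
      expect_length(intersect(esc, wrong), 0)
    }
  }
  # the +0.585 escapee shift is present in the group means even where the
  # per-gene test lacks power to call it
  des <- fx$study$design
  norm <- log_normalize(fx$study$counts)
  xx <- des$sample_id[des$chromosomal_sex == "XX"]
  xy <- des$sample_id[des$chromosomal_sex == "XY"]
  shift <- rowMeans(norm$log2[esc, xx]) - rowMeans(norm$log2[esc, xy])
  expect_equal(mean(shift), 0.585, tolerance = 0.25)
})

test_that("chromosome tally partitions a signature by direction", {
  ann <- data.frame(gene_id = c("a", "b", "c", "d"),
                    chromosome = c("A", "X", "Y", "A"))
  s <- fcg_signature("t", up = c("a", "b"), down = c("c", "d"))
  tal <- chromosome_tally(s, ann)
  expect_identical(tal["up", "A"], 1L)
  expect_identical(tal["up", "X"], 1L)
  expect_identical(tal["down", "Y"], 1L)
  expect_identical(sum(tal), 4L)
  empty <- chromosome_tally(fcg_signature("e", NULL, NULL), ann)
  expect_identical(sum(empty), 0L)
  bad <- fcg_signature("b", up = "zz", down = NULL)
  expect_error(chromosome_tally(bad, ann), "zz")
})
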