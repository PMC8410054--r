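test_that("ranking is deterministic and rejects bad input", {
  tab <- data.frame(gene = c("b", "a", "c", "d"), t = c(2, 2, -1, 5))
  rk <- rank_from_contrast(tab)
  expect_identical(rk$genes, c("d", "a", "b", "c"))  # tie a/b lexicographic
  expect_true(all(diff(rk$metric) <= 0))
  # permutation of rows changes nothing
  rk2 <- rank_from_contrast(tab[c(3, 1, 4, 2), ])
  expect_identical(rk, rk2)
  # sign flip reverses the order
  rk3 <- rank_from_contrast(transform(tab, t = -t))
  expect_identical(rk3$genes, rev(c("d", "b", "a", "c")))  # ties re-broken
  expect_error(rank_from_contrast(data.frame(gene = c("a", "a"), t = 1:2)),
               "duplicate")
  expect_error(rank_from_contrast(data.frame(gene = "a", t = NaN)), "finite")
})

test_that("enrichment score reproduces the worked examples", {
  rk <- structure(list(genes = c("g1", "g2", "g3", "g4"),
                       metric = c(4, 3, 2, 1)), class = "ranked_list")
  expect_equal(enrichment_score(rk, "g1")$es, 1)
  expect_equal(enrichment_score(rk, "g4")$es, -1)
  expect_error(enrichment_score(rk, character(0)), "subset")
  expect_error(enrichment_score(rk, rk$genes), "subset")
  # p = 0 equals the classical KS statistic
  set.seed(14)
  genes <- sprintf("g%02d", 1:10)
  rk10 <- structure(list(genes = genes, metric = sort(rnorm(10),
                                                      decreasing = TRUE)),
                    class = "ranked_list")
  s <- genes[1:5]
  expect_equal(enrichment_score(rk10, s, weight = 0)$es,
               oracle_es(rk10$genes, rk10$metric, s, p = 0))
})

test_that("vectorized ES equals the loop oracle on random cases", {
  set.seed(41)
  for (k in 1:100) {
    n <- sample(20:60, 1)
    genes <- sprintf("g%03d", seq_len(n))
    metric <- sort(rnorm(n, sd = 2), decreasing = TRUE)
    rk <- structure(list(genes = genes, metric = metric),
                    class = "ranked_list")
    s <- sample(genes, sample.int(n - 1, 1))
    got <- enrichment_score(rk, s)$es
    expect_equal(got, oracle_es(genes, metric, s), tolerance = 1e-12)
    expect_lte(abs(got), 1)
    # hit-position shortcut used in the permutation null agrees too
    pos <- which(genes %in% s)
    expect_equal(fcglung:::es_from_positions(pos, abs(metric[pos]), n), got,
                 tolerance = 1e-12)
    # antisymmetry: negate metrics and reverse the list
    rk_neg <- structure(list(genes = rev(genes), metric = rev(-metric)),
                        class = "ranked_list")
    expect_equal(enrichment_score(rk_neg, s)$es, -got, tolerance = 1e-12)
  }
})

test_that("preranked GSEA is deterministic and obeys its invariants", {
  set.seed(17)
  n <- 300
  tab <- data.frame(gene = sprintf("g%03d", 1:n), t = rnorm(n))
  rk <- rank_from_contrast(tab)
  sets <- lapply(1:8, function(i) sample(tab$gene, 20))
  names(sets) <- sprintf("S%d", 1:8)
  r1 <- gsea_preranked(rk, sets, n_perm = 200, seed = 9)
  r2 <- gsea_preranked(rk, sets, n_perm = 200, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(sign(r1$nes) == sign(r1$es) | r1$es == 0))
  expect_true(all(r1$p >= 1 / 201))
  expect_true(all(r1$q >= 0 & r1$q <= 1))
  # filtering: sets outside the size window are dropped; all dropped errors
  sets$tiny <- sets$S1[1:2]
  r3 <- gsea_preranked(rk, sets, n_perm = 50, seed = 9)
  expect_false("tiny" %in% r3$set)
  expect_error(gsea_preranked(rk, list(a = tab$gene[1:2]), n_perm = 10,
                              seed = 1), "size filter")
})

test_that("a set planted at the top of the ranking is strongly enriched", {
  set.seed(23)
  n <- 500
  tab <- data.frame(gene = sprintf("g%03d", 1:n), t = rnorm(n))
  tab$t[1:25] <- tab$t[1:25] + 4
  rk <- rank_from_contrast(tab)
  sets <- list(planted = tab$gene[1:25])
  for (i in 1:10) sets[[sprintf("rand%d", i)]] <- sample(tab$gene, 25)
  res <- gsea_preranked(rk, sets, n_perm = 500, seed = 3)
  pl <- res[res$set == "planted", ]
  expect_gt(pl$nes, 1.5)
  expect_lt(pl$q, 0.25)
  # leading edge contains only planted genes
  expect_true(all(strsplit(pl$leading_edge, ",")[[1]] %in% tab$gene[1:25]))
})

test_that("NES matrix masks exactly the non-significant entries", {
  r1 <- data.frame(set = c("a", "b", "c"), size = 10, es = c(0.5, -0.4, 0.3),
                   nes = c(2, -1.8, 1.1), p = 0.01, q = c(0.1, 0.24, 0.25),
                   leading_edge = "")
  r2 <- data.frame(set = c("a", "d"), size = 10, es = c(0.2, 0.6),
                   nes = c(0.9, 2.4), p = 0.01, q = c(0.9, 0.01),
                   leading_edge = "")
  m <- nes_matrix(list(x = r1, y = r2), fdr_max = 0.25)
  expect_identical(dim(m), c(2L, 4L))
  expect_equal(m["x", "a"], 2)
  expect_equal(m["x", "b"], -1.8)
  expect_equal(m["x", "c"], 0)       # q = 0.25 is not < 0.25
  expect_equal(m["y", "a"], 0)
  expect_equal(m["y", "d"], 2.4)
  expect_equal(m["x", "d"], 0)       # untested set in response x
  # masking is idempotent: all-nonsignificant gives the zero matrix
  m0 <- nes_matrix(list(x = transform(r1, q = 0.9)), fdr_max = 0.25)
  expect_true(all(m0 == 0))
})

test_that("pathway overlap mirrors the signature convention", {
  expect_equal(pathway_overlap(c("a", "b"), c("a", "b"))$percent, 100)
  expect_equal(pathway_overlap(c("a", "b"), c("c"))$percent, 0)
  ov <- pathway_overlap(sprintf("p%d", 1:10), sprintf("p%d", 6:18))
  expect_identical(ov$n_intersection, 5L)
  expect_identical(ov$n_union, 18L)
  expect_equal(ov$percent, 100 * 5 / 18, tolerance = 1e-10)
})

test_that("the discordance rule matches an exhaustive truth-table oracle", {
  states <- expand.grid(h = 1:4, f1 = 1:4, f2 = 1:4, f3 = 1:4, ym = 1:4)
  # state encoding: 1 sig-up, 2 sig-down, 3 nonsig-up, 4 nonsig-down
  nes_of <- c(2, -2, 0.5, -0.5)
  sig_of <- c(TRUE, TRUE, FALSE, FALSE)
  res_of <- function(code) {
    data.frame(set = "pw", size = 10, es = nes_of[code] / 2,
               nes = nes_of[code], p = 0.01,
               q = ifelse(sig_of[code], 0.01, 0.5), leading_edge = "")
  }
  brute_rule <- function(h, f1, f2, f3, ym) {
    human_ok <- sig_of[h] && nes_of[h] > 0
    fem_ok <- all(sig_of[c(f1, f2, f3)] & nes_of[c(f1, f2, f3)] < 0)
    ym_ok <- (sig_of[ym] && nes_of[ym] > 0) || !sig_of[ym]
    human_ok && fem_ok && ym_ok
  }
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    got <- discordant_pathways(res_of(st$h), res_of(st$f1), res_of(st$f2),
                               res_of(st$f3), res_of(st$ym))
    expect_identical(length(got) == 1L,
                     brute_rule(st$h, st$f1, st$f2, st$f3, st$ym))
  }
})
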