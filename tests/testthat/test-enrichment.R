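# Fisher exact overlap, Bonferroni, point-biserial correlation and term
# enrichment.

test_that("fisher_overlap matches exhaustive same-margin enumeration", {
  # the spec's worked table [[1,9],[11,3]]
  x <- c(rep(TRUE, 10), rep(FALSE, 14))
  y <- c(rep(TRUE, 1), rep(FALSE, 9), rep(TRUE, 11), rep(FALSE, 3))
  ft <- fisher_overlap(x, y)
  expect_equal(ft$table, matrix(c(1L, 11L, 9L, 3L), 2, 2,
                                dimnames = dimnames(ft$table)))
  expect_equal(ft$p_value, enum_fisher_p(1, 9, 11, 3), tolerance = 1e-12)
  # and against the reference implementation
  expect_equal(ft$p_value,
               fisher.test(matrix(c(1, 11, 9, 3), 2))$p.value,
               tolerance = 1e-9)
})

test_that("fisher_overlap equals enumeration on random small tables", {
  withr::local_seed(31)
  for (i in 1:200) {
    n <- sample(2:40, 1)
    x <- runif(n) < runif(1, 0.2, 0.8)
    y <- runif(n) < runif(1, 0.2, 0.8)
    ft <- fisher_overlap(x, y)
    a <- sum(x & y); b <- sum(x & !y); c <- sum(!x & y); d <- sum(!x & !y)
    expect_equal(ft$p_value, enum_fisher_p(a, b, c, d), tolerance = 1e-9)
  }
})

test_that("degenerate margins give p = 1 and a corrected odds ratio", {
  ft <- fisher_overlap(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(ft$p_value, 1)
  # zero cells -> Haldane-Anscombe correction
  expect_equal(ft$odds_ratio, (5.5 * 0.5) / (0.5 * 0.5))
  expect_equal(fisher_overlap(logical(4), c(TRUE, TRUE, FALSE, FALSE))$p_value, 1)
})

test_that("p-values are near-uniform under independence", {
  withr::local_seed(32)
  ps <- replicate(400, {
    x <- runif(60) < 0.4
    y <- runif(60) < 0.3
    fisher_overlap(x, y)$p_value
  })
  # conservative checks appropriate to a discrete exact test
  expect_lte(mean(ps <= 0.05), 0.08)
  expect_gt(mean(ps), 0.35)
})

test_that("bonferroni clips at one and requires a full family size", {
  expect_equal(bonferroni(0.01, 5), 0.05)
  expect_equal(bonferroni(0.5, 10), 1)
  expect_equal(bonferroni(0.3, 1), 0.3)
  expect_equal(bonferroni(c(0.01, 0.2), 4), c(0.04, 0.8))
  expect_error(bonferroni(c(0.1, 0.2), 1), "at least")
})

test_that("point-biserial correlation hits its closed-form endpoints", {
  x <- c(1, 1, 0, 0, 1)
  expect_equal(point_biserial(x, x), 1)
  expect_equal(point_biserial(x, 1 - x), -1)
  expect_true(is.na(point_biserial(rep(1, 5), c(1, 2, 3, 4, 5))))
  withr::local_seed(33)
  r <- point_biserial(runif(10000) < 0.5, rnorm(10000))
  expect_lt(abs(r), 0.05)
})

test_that("term enrichment reproduces the hypergeometric oracle", {
  universe <- paste0("g", 1:20)
  sets <- list(T1 = paste0("g", 1:5), T2 = paste0("g", 16:25),
               TEMPTY = paste0("x", 1:3))
  hits <- paste0("g", c(1:4, 10))
  expect_message(res <- term_enrichment(sets, hits, universe), "TEMPTY")
  expect_equal(nrow(res), 2)
  t1 <- res[res$term_id == "T1", ]
  expect_equal(t1$n_overlap, 4L)
  expect_equal(t1$p_raw, enum_fisher_p(4, 1, 1, 14), tolerance = 1e-9)
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_equal(res$p_adjusted, pmin(1, 2 * res$p_raw))
  # hit set == universe -> degenerate margins, p = 1 everywhere
  all_hits <- term_enrichment(sets["T1"], universe, universe)
  expect_equal(all_hits$p_raw, 1)
})

test_that("feature annotations project through hits onto model positions", {
  hits <- rbind(toy_hit("MMMMIIMMM", protein_id = "P1"),
                toy_hit(strrep("M", 9), protein_id = "P2"))
  feats <- data.frame(protein_id = c("P1", "P1", "P2", "P9"),
                      residue_pos = c(2, 5, 7, 1),
                      feature_name = c("Active site", "Active site",
                                       "Active site", "Active site"))
  ann <- project_features(feats, hits)
  # P1 residue 5 is an insert -> gap rule assigns model 4; P9 unknown
  expect_setequal(ann$model_pos, c(2L, 4L, 7L))
  u <- data.frame(domain_acc = "d1", model_pos = 1:9)
  calls <- data.frame(domain_acc = "d1", model_pos = c(2L, 4L),
                      significant = TRUE)
  fe <- feature_enrichment(calls, ann, u)
  expect_equal(fe$n_overlap, 2L)
  expect_equal(fe$p_raw, enum_fisher_p(2, 0, 1, 6), tolerance = 1e-9)
})
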