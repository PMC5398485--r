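# Pileup of projected variants into per-family position counts.

make_two_gene_family <- function() {
  # two gapless genes over the same 20-position model
  hits <- rbind(toy_hit(strrep("M", 20), protein_id = "P1"),
                toy_hit(strrep("M", 20), protein_id = "P2"))
  reps <- c(g1 = "P1", g2 = "P2")
  list(hits = hits, reps = reps)
}

variant_rows <- function(gene, patient, pos, ct = "TST") {
  n <- length(gene)
  data.frame(gene_id = gene, patient_id = patient,
             cancer_type = rep_len(ct, n), protein_pos = pos,
             ref_aa = rep_len("A", n), alt_aa = rep_len("V", n),
             classification = rep_len("missense", n),
             validation = rep_len("validated", n),
             stringsAsFactors = FALSE)
}

test_that("no variants yield all-zero vectors with n_0 == model_length", {
  fam <- make_two_gene_family()
  pcs <- build_position_counts(variant_rows(character(), character(),
                                            integer()),
                               fam$hits, fam$reps)
  expect_length(pcs, 1)
  pc <- pcs[[1]]
  expect_true(all(pc$counts == 0))
  h <- count_histogram(pc)
  expect_equal(unname(h[["0"]]), pc$model_length)
})

test_that("a hand pileup of five variants lands on the expected positions", {
  fam <- make_two_gene_family()
  v <- variant_rows(gene = c("g1", "g1", "g2", "g2", "g2"),
                    patient = c("PT1", "PT2", "PT1", "PT3", "PT4"),
                    pos = c(5, 5, 5, 9, 13))
  pcs <- build_position_counts(v, fam$hits, fam$reps)
  pc <- pcs[["d1|TST"]]
  # g1 PT1+PT2 at model 5, g2 PT1 at model 5 -> 3; then 9 and 13 once each
  expect_equal(pc$counts[5], 3L)
  expect_equal(pc$counts[9], 1L)
  expect_equal(pc$counts[13], 1L)
  expect_equal(sum(pc$counts), 5L)
  expect_equal(sum(count_histogram(pc)), pc$model_length)
})

test_that("row duplication and permutation leave counts unchanged", {
  fam <- make_two_gene_family()
  v <- variant_rows(gene = c("g1", "g2", "g2"),
                    patient = c("PT1", "PT2", "PT3"),
                    pos = c(3, 7, 7))
  base <- build_position_counts(v, fam$hits, fam$reps)[[1]]$counts
  dup <- build_position_counts(rbind(v, v), fam$hits, fam$reps)[[1]]$counts
  perm <- build_position_counts(v[c(3, 1, 2), ], fam$hits,
                                fam$reps)[[1]]$counts
  expect_identical(dup, base)
  expect_identical(perm, base)
})

test_that("overlapping hits of one family count once, via the best E-value hit", {
  # two hits of the same family on one protein covering residue 5:
  # the better hit starts at residue 3, so residue 5 -> model 3
  hits <- rbind(
    toy_hit(strrep("M", 10), protein_start = 1, evalue = 1e-3),
    toy_hit(strrep("M", 10), protein_start = 3, evalue = 1e-8))
  v <- variant_rows("g1", "PT1", 5)
  pcs <- build_position_counts(v, hits, c(g1 = "P1"))
  pc <- pcs[[1]]
  expect_equal(sum(pc$counts), 1L)
  expect_equal(pc$counts[3], 1L)
})

test_that("hits from different families each receive the event", {
  hits <- rbind(toy_hit(strrep("M", 10), domain_acc = "dA"),
                toy_hit(strrep("M", 10), domain_acc = "dB",
                        protein_start = 2))
  v <- variant_rows("g1", "PT1", 5)
  pcs <- build_position_counts(v, hits, c(g1 = "P1"))
  expect_equal(sum(pcs[["dA|TST"]]$counts), 1L)
  expect_equal(sum(pcs[["dB|TST"]]$counts), 1L)
  expect_equal(pcs[["dA|TST"]]$counts[5], 1L)
  expect_equal(pcs[["dB|TST"]]$counts[4], 1L)
})

test_that("variants without a representative protein are tallied, not counted", {
  fam <- make_two_gene_family()
  v <- variant_rows(c("g1", "gX"), c("PT1", "PT2"), c(4, 4))
  pcs <- build_position_counts(v, fam$hits, fam$reps)
  expect_equal(sum(pcs[[1]]$counts), 1L)
  skip <- attr(pcs, "skip_report")
  expect_equal(unname(skip[["no_representative"]]), 1L)
  expect_equal(unname(skip[["n_projections"]]),
               sum(vapply(pcs, function(p) sum(p$counts), numeric(1))))
})

test_that("pooling merges cancer types under POOLED", {
  fam <- make_two_gene_family()
  v <- rbind(variant_rows("g1", "PT1", 4, ct = "AAA"),
             variant_rows("g2", "PT2", 4, ct = "BBB"))
  pooled <- build_position_counts(v, fam$hits, fam$reps,
                                  group_by_cancer = FALSE)
  expect_named(pooled, "d1|POOLED")
  expect_equal(pooled[[1]]$counts[4], 2L)
  split <- build_position_counts(v, fam$hits, fam$reps)
  expect_setequal(names(split), c("d1|AAA", "d1|BBB"))
})
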