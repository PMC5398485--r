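# Synthetic family and cohort generation: determinism, round-trips, and
# the planted count distributions.

test_that("zero indel rates give gapless alignments of exactly model length", {
  fam <- make_family(family_spec(model_length = 30, n_genes = 3,
                                 ins_rate = 0, del_rate = 0, seed = 2))
  expect_true(all(fam$proteins$length == 30))
  expect_true(all(fam$hits$state_string == strrep("M", 30)))
})

test_that("regeneration from the same spec is byte-identical", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  spec <- family_spec(domain_acc = "ddet", model_length = 50, n_genes = 5,
                      seed = 9)
  f1 <- make_family(spec, dir = d1)
  f2 <- make_family(spec, dir = d2)
  expect_identical(f1$proteins, f2$proteins)
  expect_identical(unname(tools::md5sum(f1$fasta_path)),
                   unname(tools::md5sum(f2$fasta_path)))
  expect_identical(unname(tools::md5sum(f1$dat_path)),
                   unname(tools::md5sum(f2$dat_path)))
  pl <- plant_spec(signal_pos = c(10, 30), seed = 4)
  p1 <- plant_variants(f1, pl, dir = d1)
  p2 <- plant_variants(f2, pl, dir = d2)
  expect_identical(unname(tools::md5sum(p1$maf_path)),
                   unname(tools::md5sum(p2$maf_path)))
})

test_that("written families round-trip through the readers", {
  d <- withr::local_tempdir()
  fam <- make_family(family_spec(domain_acc = "drt", model_length = 40,
                                 n_genes = 6, seed = 3), dir = d)
  hits2 <- read_dat(fam$dat_path)
  expect_equal(hits2$state_string, fam$hits$state_string)
  expect_equal(hits2$protein_start, fam$hits$protein_start)
  prot2 <- read_protein_fasta(fam$fasta_path)
  expect_equal(prot2$sequence, fam$proteins$sequence)
  expect_equal(prot2$gene_id, fam$proteins$gene_id)
  # column structure identical after the round trip
  expect_equal(expand_hits(hits2)$model_pos,
               expand_hits(fam$hits)$model_pos)
})

test_that("a silent null (pi0 = 1) with no signal yields an empty MAF", {
  fam <- make_family(family_spec(model_length = 20, n_genes = 2, seed = 6))
  pv <- plant_variants(fam, plant_spec(pi0 = 1, lambda0 = 0, lambda1 = 1,
                                       seed = 1))
  expect_equal(nrow(pv$maf), 0)
  expect_true(all(pv$truth$planted_count == 0))
})

test_that("planted MAF counts survive the full reader path exactly", {
  d <- withr::local_tempdir()
  mc <- mini_cohort(seed = 8, dir = d)
  v <- read_maf(mc$pv$maf_path)
  reps <- select_representatives(mc$fam$proteins)
  pc <- build_position_counts(v, mc$fam$hits, reps)[[1]]
  expect_identical(pc$counts, mc$pv$truth$planted_count)
})

test_that("null-position counts are distributed as the planted ZIP", {
  fam <- make_family(family_spec(domain_acc = "dchi", model_length = 2000,
                                 n_genes = 3, ins_rate = 0, del_rate = 0,
                                 seed = 12))
  pv <- plant_variants(fam, plant_spec(pi0 = 0.3, lambda0 = 0.4,
                                       lambda1 = 8, n_patients = 60,
                                       seed = 13))
  counts <- pv$truth$planted_count[!pv$truth$is_signal]
  obs <- c(sum(counts == 0), sum(counts == 1), sum(counts == 2),
           sum(counts >= 3))
  p <- c(dzip(0:2, 0.3, 0.4), 1 - sum(dzip(0:2, 0.3, 0.4)))
  gof <- suppressWarnings(chisq.test(obs, p = p))
  expect_gt(gof$p.value, 0.001)
})

test_that("unreachable signal positions are refused by name", {
  fam <- make_family(family_spec(model_length = 12, n_genes = 2,
                                 ins_rate = 0, del_rate = 0, seed = 4))
  # delete model position 2 in every member by hand
  fam$hits$state_string <- sub("^MM", "MD", fam$hits$state_string)
  fam$proteins$sequence <- substr(fam$proteins$sequence, 1, 11)
  fam$proteins$length <- 11L
  expect_error(plant_variants(fam, plant_spec(signal_pos = 2, seed = 1)),
               "deleted in every member gene.*2")
  expect_error(plant_variants(fam, plant_spec(signal_pos = 99, seed = 1)),
               "\\[1, 12\\]")
})
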