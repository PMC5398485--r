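# Shared fixture builders and independent oracles.

## One-row DAT hit table
toy_hit <- function(state_string, protein_start = 1L, model_start = 1L,
                    model_length = NULL, protein_id = "P1",
                    domain_acc = "d1", evalue = 1e-10) {
  nM <- nchar(gsub("[^M]", "", state_string))
  nD <- nchar(gsub("[^D]", "", state_string))
  if (is.null(model_length)) model_length <- model_start - 1L + nM + nD
  data.frame(protein_id = protein_id, domain_acc = domain_acc,
             model_length = model_length, evalue = evalue,
             protein_start = protein_start, model_start = model_start,
             state_string = state_string, stringsAsFactors = FALSE)
}

## Independent projection oracle: explicit character-by-character scan of
## one hit, tracking protein/model cursors and the last match state seen.
brute_project <- function(protein_pos, hit) {
  ch <- strsplit(hit$state_string, "")[[1]]
  p <- hit$protein_start - 1L
  m <- hit$model_start - 1L
  last_match <- NA_integer_
  for (s in ch) {
    if (s == "M") {
      p <- p + 1L; m <- m + 1L; last_match <- m
      if (p == protein_pos) return(list(model_pos = m, via_gap = FALSE))
    } else if (s == "I") {
      p <- p + 1L
      if (p == protein_pos)
        return(if (is.na(last_match)) NULL
               else list(model_pos = last_match, via_gap = TRUE))
    } else if (s == "D") {
      m <- m + 1L
    }
  }
  NULL
}

random_toy_hit <- function(max_len = 30) {
  n <- sample(3:max_len, 1)
  st <- sample(c("M", "I", "D"), n, replace = TRUE,
               prob = c(0.6, 0.2, 0.2))
  if (!any(st == "M")) st[sample(n, 1)] <- "M"
  toy_hit(paste(st, collapse = ""),
          protein_start = sample(1:50, 1),
          model_start = sample(1:10, 1),
          model_length = sum(st != "I") + sample(0:10, 1) + 9L)
}

## Exhaustive same-margin enumeration oracle for the two-sided Fisher
## exact p-value, from first principles (log-factorial table
## probabilities, no dhyper).
enum_fisher_p <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; c1 <- a + c
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  lp <- function(aa) {
    bb <- r1 - aa; cc <- c1 - aa; dd <- n - r1 - c1 + aa
    lfactorial(r1) + lfactorial(n - r1) + lfactorial(c1) +
      lfactorial(n - c1) - lfactorial(n) - lfactorial(aa) -
      lfactorial(bb) - lfactorial(cc) - lfactorial(dd)
  }
  ks <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(ks, lp, numeric(1))
  obs <- lp(a)
  min(1, sum(exp(probs[probs <= obs + 1e-7])))
}

## Write a small MAF file from row vectors
write_mini_maf <- function(path, gene, patient, class, validation, change,
                           cancer = "TST") {
  dt <- data.frame(Hugo_Symbol = gene, Tumor_Sample_Barcode = patient,
                   Cancer_Type = cancer, Variant_Classification = class,
                   Validation_Status = validation, Protein_Change = change,
                   stringsAsFactors = FALSE)
  utils::write.table(dt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

## A small planted two-gene family used by several tests
mini_cohort <- function(seed = 7, L = 60, signal_pos = c(10, 40),
                        lambda1 = 10, dir = NULL) {
  fam <- make_family(family_spec(domain_acc = "dmini", model_length = L,
                                 n_genes = 4, seed = seed), dir = dir)
  pv <- plant_variants(fam, plant_spec(signal_pos = signal_pos,
                                       pi0 = 0.3, lambda0 = 0.4,
                                       lambda1 = lambda1,
                                       n_patients = 80,
                                       cancer_type = "TST",
                                       seed = seed + 1), dir = dir)
  list(fam = fam, pv = pv)
}
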