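# Synthetic cohorts: domain families with seeded insert/delete
# structure, and MAF files whose per-position mutation counts follow a
# known ZIP background with planted elevated-rate hotspot positions.

#' Specification of a synthetic domain family
#'
#' @param domain_acc Model accession label (e.g. `"synd0001"`).
#' @param model_length Number of match states `L` (>= 10).
#' @param n_genes Number of member genes (>= 1); the first gene is always
#'   aligned gaplessly so that every model position is reachable.
#' @param ins_rate Per-position probability of opening an insertion after
#'   a match column.
#' @param del_rate Per-position probability of deleting a match state in
#'   a member protein.
#' @param sub_rate Per-residue probability that a member deviates from
#'   the family consensus residue.
#' @param seed Integer seed; regeneration from an identical spec is
#'   byte-identical.
#' @return An object of class `family_spec`.
#' @export
family_spec <- function(domain_acc = "synd0001", model_length = 200,
                        n_genes = 8, ins_rate = 0.02, del_rate = 0.02,
                        sub_rate = 0.3, seed = 1) {
  stopifnot(model_length >= 10, n_genes >= 1,
            ins_rate >= 0, ins_rate < 1, del_rate >= 0, del_rate < 1,
            sub_rate >= 0, sub_rate <= 1)
  structure(list(domain_acc = domain_acc,
                 model_length = as.integer(model_length),
                 n_genes = as.integer(n_genes), ins_rate = ins_rate,
                 del_rate = del_rate, sub_rate = sub_rate,
                 seed = as.integer(seed)),
            class = "family_spec")
}

#' Generate a synthetic domain family
#'
#' Draws a consensus sequence of `model_length` residues and, per member
#' gene, a protein sequence together with its exact alignment to the
#' model: match states mutate away from the consensus with probability
#' `sub_rate`, are deleted with probability `del_rate` (never in the
#' first gene, which anchors full model coverage), and geometric-length
#' insertions open after a match column with probability `ins_rate`.
#'
#' @param spec A [family_spec()].
#' @param dir Optional directory; when given, writes
#'   `<domain_acc>.fasta` and `<domain_acc>.dat` there.
#' @return List with elements `proteins` (a [read_protein_fasta()]-style
#'   table), `hits` (a validated DAT table) and, when `dir` is given,
#'   `fasta_path` / `dat_path`.
#' @export
make_family <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "family_spec"))
  gen <- function() {
    L <- spec$model_length
    consensus <- sample(.standard_aa, L, replace = TRUE)
    prot <- vector("list", spec$n_genes)
    hits <- vector("list", spec$n_genes)
    for (g in seq_len(spec$n_genes)) {
      anchor <- g == 1L               # gapless member guarantees coverage
      states <- character(0)
      seqres <- character(0)
      for (m in seq_len(L)) {
        if (!anchor && stats::runif(1) < spec$del_rate) {
          states <- c(states, "D")
        } else {
          states <- c(states, "M")
          aa <- if (stats::runif(1) < spec$sub_rate)
            sample(.standard_aa, 1) else consensus[m]
          seqres <- c(seqres, aa)
        }
        if (!anchor && m < L && stats::runif(1) < spec$ins_rate) {
          n_ins <- stats::rgeom(1, 0.5) + 1L
          states <- c(states, rep("I", n_ins))
          seqres <- c(seqres, sample(.standard_aa, n_ins, replace = TRUE))
        }
      }
      if (!any(states == "M"))
        stop("family_spec rates produced an empty alignment for gene ", g,
             call. = FALSE)
      gene <- sprintf("GENE_%s_%02d", spec$domain_acc, g)
      pid <- sprintf("P_%s_%02d", spec$domain_acc, g)
      prot[[g]] <- data.table::data.table(
        protein_id = pid, gene_id = gene, source = "swissprot",
        sequence = paste(seqres, collapse = ""), length = length(seqres))
      hits[[g]] <- data.table::data.table(
        protein_id = pid, domain_acc = spec$domain_acc,
        model_length = L,
        evalue = signif(10^stats::runif(1, -30, -5), 3),
        protein_start = 1L, model_start = 1L,
        state_string = paste(states, collapse = ""))
    }
    list(proteins = data.table::rbindlist(prot),
         hits = validate_hits(data.table::rbindlist(hits)))
  }
  fam <- withr::with_seed(spec$seed, gen())
  fam$spec <- spec
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    fam$fasta_path <- file.path(dir, paste0(spec$domain_acc, ".fasta"))
    fam$dat_path <- file.path(dir, paste0(spec$domain_acc, ".dat"))
    writeLines(paste0(">", fam$proteins$protein_id, "|",
                      fam$proteins$source, "|", fam$proteins$gene_id, "\n",
                      fam$proteins$sequence),
               fam$fasta_path)
    write_dat(fam$hits, fam$dat_path)
  }
  fam
}

#' Specification of planted mutation counts for a family
#'
#' Null model positions draw their mutation count from
#' `ZIP(pi0, lambda0)`; the designated signal positions draw from
#' `Poisson(lambda1)` with `lambda1 > lambda0`.
#'
#' @param signal_pos Integer vector of planted hotspot model positions.
#' @param pi0,lambda0 Null ZIP parameters.
#' @param lambda1 Signal Poisson rate (`> lambda0`).
#' @param n_patients Cohort size; each position's events are spread over
#'   distinct patients, so must be at least the largest per-position
#'   count.
#' @param cancer_type Study label stamped on the synthetic MAF rows.
#' @param seed Integer seed.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(signal_pos = integer(), pi0 = 0.3, lambda0 = 0.4,
                       lambda1 = 8, n_patients = 100,
                       cancer_type = "SYN", seed = 1) {
  stopifnot(pi0 >= 0, pi0 <= 1, lambda0 >= 0, lambda1 > lambda0,
            n_patients >= 1)
  structure(list(signal_pos = as.integer(signal_pos), pi0 = pi0,
                 lambda0 = lambda0, lambda1 = lambda1,
                 n_patients = as.integer(n_patients),
                 cancer_type = as.character(cancer_type),
                 seed = as.integer(seed)),
            class = "plant_spec")
}

#' Plant variants on a synthetic family and emit a MAF
#'
#' Draws a mutation count per model position from the null ZIP (or the
#' signal Poisson at planted positions), assigns each event to a
#' uniformly chosen member gene in which the position is a match state,
#' inverts the alignment map to a protein residue, and writes TCGA-style
#' MAF rows (validated missense, `p.<ref><pos><alt>` protein changes,
#' patient barcodes `SYN-<cancer_type>-<k>`).  Each position's events go
#' to distinct patients so that MAF de-duplication cannot collapse
#' planted events.
#'
#' @param family A [make_family()] result.
#' @param plant A [plant_spec()]; every `signal_pos` must lie in
#'   `[1, model_length]` and be a match state in at least one member
#'   gene.
#' @param dir Optional directory; when given, writes
#'   `<domain_acc>.maf` and `<domain_acc>.truth.tsv` there.
#' @return List with elements `maf` (data.table of MAF rows), `truth`
#'   (`domain_acc`, `model_pos`, `is_signal`, `planted_count`) and, when
#'   `dir` is given, `maf_path` / `truth_path`.
#' @export
plant_variants <- function(family, plant, dir = NULL) {
  stopifnot(inherits(plant, "plant_spec"))
  L <- family$spec$model_length
  acc <- family$spec$domain_acc
  if (length(plant$signal_pos) &&
      (any(plant$signal_pos < 1) || any(plant$signal_pos > L)))
    stop("signal positions must lie in [1, ", L, "]", call. = FALSE)
  map <- expand_hits(family$hits)
  match_map <- map[via_gap == FALSE]
  unreachable <- setdiff(plant$signal_pos, unique(match_map$model_pos))
  if (length(unreachable))
    stop("signal position(s) deleted in every member gene: ",
         paste(unreachable, collapse = ", "), call. = FALSE)
  pid2gene <- stats::setNames(family$proteins$gene_id,
                              family$proteins$protein_id)

  gen <- function() {
    is_signal <- seq_len(L) %in% plant$signal_pos
    counts <- integer(L)
    counts[!is_signal] <- rzip(sum(!is_signal), plant$pi0, plant$lambda0)
    counts[is_signal] <- stats::rpois(sum(is_signal), plant$lambda1)
    if (max(counts) > plant$n_patients)
      stop("n_patients (", plant$n_patients, ") smaller than a planted ",
           "per-position count (", max(counts), ")", call. = FALSE)
    rows <- list()
    for (m in which(counts > 0)) {
      cand <- match_map[model_pos == m]
      pick <- cand[sample.int(nrow(cand), counts[m], replace = TRUE)]
      pick[, patient_id := sprintf("SYN-%s-%03d", plant$cancer_type,
                                   sample.int(plant$n_patients, counts[m]))]
      rows[[length(rows) + 1L]] <- pick
    }
    ev <- data.table::rbindlist(rows)
    maf <- data.table::data.table(
      Hugo_Symbol = character(), Tumor_Sample_Barcode = character(),
      Cancer_Type = character(), Variant_Classification = character(),
      Validation_Status = character(), Protein_Change = character())
    if (nrow(ev)) {
      ev <- family$proteins[, .(protein_id, sequence)][ev, on = "protein_id"]
      ref <- substring(ev$sequence, ev$protein_pos, ev$protein_pos)
      alt <- vapply(ref, function(r) sample(setdiff(.standard_aa, r), 1), "")
      maf <- data.table::data.table(
        Hugo_Symbol = unname(pid2gene[ev$protein_id]),
        Tumor_Sample_Barcode = ev$patient_id,
        Cancer_Type = plant$cancer_type,
        Variant_Classification = "Missense_Mutation",
        Validation_Status = "Valid",
        Protein_Change = paste0("p.", ref, ev$protein_pos, alt))
      data.table::setorder(maf, Hugo_Symbol, Tumor_Sample_Barcode,
                           Protein_Change)
    }
    truth <- data.table::data.table(domain_acc = acc,
                                    model_pos = seq_len(L),
                                    is_signal = is_signal,
                                    planted_count = counts)
    list(maf = maf, truth = truth)
  }
  out <- withr::with_seed(plant$seed, gen())
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    out$maf_path <- file.path(dir, paste0(acc, ".maf"))
    out$truth_path <- file.path(dir, paste0(acc, ".truth.tsv"))
    data.table::fwrite(out$maf, out$maf_path, sep = "\t")
    data.table::fwrite(out$truth, out$truth_path, sep = "\t")
  }
  out
}
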