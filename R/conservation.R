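# Alignment-column conservation: Shannon entropy of amino-acid
# frequencies per model position, and the mean-plus-one-sd conservation
# flag.

.standard_aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Shannon entropy of an alignment column
#'
#' `H = -sum_i p(a_i) ln p(a_i)` over the 20 standard amino acids, with
#' `0 ln 0 = 0`.  Gaps (and non-standard letters such as `X`/`U`) are
#' excluded and the frequencies renormalised over observed residues.
#' High entropy means a variable column; the conservation score used by
#' [flag_conserved()] is `C = -H`.
#'
#' @param column Either a character vector of residues observed in the
#'   column, or a numeric frequency vector (summing to 1).
#' @return Entropy in nats, in `[0, ln 20]`; `NA` for an empty column.
#' @examples
#' column_entropy(rep("A", 10))                 # 0
#' column_entropy(c("A", "V"))                  # ln 2
#' column_entropy(rep(1 / 20, 20))              # ln 20
#' @export
column_entropy <- function(column) {
  if (is.character(column)) {
    column <- toupper(column[column %in% c(.standard_aa, tolower(.standard_aa))])
    if (!length(column)) return(NA_real_)
    p <- as.numeric(table(column)) / length(column)
  } else {
    p <- as.numeric(column)
    if (!length(p) || any(p < 0)) return(NA_real_)
    s <- sum(p)
    if (s <= 0) return(NA_real_)
    if (abs(s - 1) > 1e-6)
      stop("frequency vector must sum to 1", call. = FALSE)
    p <- p / s
  }
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Flag conserved positions within a domain
#'
#' A position is conserved iff its conservation score `C = -H` is at
#' least the domain mean of `C` plus one standard deviation (ties at the
#' threshold are conserved); equivalently `H <= mean(H) - sd(H)`.
#' Positions with undefined entropy (`NA`, e.g. empty columns) are
#' excluded from the mean/sd and never flagged.  When the score is
#' constant across the domain (`sd = 0`) no position is flagged and a
#' warning is raised, since the rule would otherwise vacuously flag every
#' position.
#'
#' @param entropies Numeric vector of per-position entropies (`NA`
#'   allowed).
#' @return Logical vector of conserved flags, same length as the input.
#' @export
flag_conserved <- function(entropies) {
  ok <- !is.na(entropies)
  flags <- rep(FALSE, length(entropies))
  if (sum(ok) < 2) {
    if (length(entropies)) warning("fewer than 2 defined positions; no position flagged",
                                   call. = FALSE)
    return(flags)
  }
  C <- -entropies[ok]
  s <- stats::sd(C)
  if (s == 0) {
    warning("constant conservation score across the domain; no position flagged",
            call. = FALSE)
    return(flags)
  }
  flags[ok] <- C >= mean(C) + s
  flags
}

#' Per-family conservation profiles from alignments
#'
#' Builds, for each domain family, the amino-acid column profiles over
#' the match-state columns of its hits (one residue per aligned protein
#' per match column; insert columns contribute nothing), computes the
#' column entropies and applies the [flag_conserved()] rule per domain.
#'
#' @param proteins Protein table (see [read_protein_fasta()]).
#' @param hits Domain hit table (see [read_dat()]).
#' @param evalue_max Alignment inclusion threshold (default 0.001).
#' @param min_residues Columns with fewer observed residues are excluded
#'   from the mean/sd and never flagged (default 2).
#' @return A `data.table` with columns `domain_acc`, `model_pos`,
#'   `n_residues`, `entropy`, `conserved`.
#' @export
family_conservation <- function(proteins, hits, evalue_max = 0.001,
                                min_residues = 2) {
  p <- data.table::as.data.table(proteins)
  h <- data.table::as.data.table(hits)
  if (!"hit_id" %in% names(h)) h <- validate_hits(h)
  h <- h[evalue <= evalue_max]
  map <- expand_hits(h)
  map <- map[via_gap == FALSE]              # match columns only
  map <- map[p[, .(protein_id, sequence)], on = "protein_id", nomatch = NULL]
  map[, aa := substring(sequence, protein_pos, protein_pos)]
  map[, sequence := NULL]

  out <- list()
  for (acc in unique(h$domain_acc)) {
    L <- h[domain_acc == acc]$model_length[1]
    sub <- map[domain_acc == acc & aa %chin% .standard_aa]
    prof <- data.table::data.table(domain_acc = acc, model_pos = seq_len(L))
    byp <- sub[, .(n_residues = .N, entropy = column_entropy(aa)),
               by = model_pos]
    prof <- byp[prof, on = "model_pos"]
    prof[is.na(n_residues), n_residues := 0L]
    prof[n_residues < min_residues, entropy := NA_real_]
    prof[, conserved := suppressWarnings(flag_conserved(entropy))]
    prof[, domain_acc := acc]
    data.table::setcolorder(prof, c("domain_acc", "model_pos",
                                    "n_residues", "entropy", "conserved"))
    out[[acc]] <- prof
  }
  data.table::rbindlist(out)
}
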