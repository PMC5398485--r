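# Pileup of projected variants into per-(domain family, cancer type)
# position count vectors.

#' Aggregate variants onto domain-model position counts
#'
#' Projects every retained variant onto the domain families whose hits
#' cover it and accumulates, per `(domain_acc, cancer_type)` (or per
#' `domain_acc` alone when pooling), a count vector over the model
#' positions `1..model_length`.  Each variant event contributes once to
#' every *family* covering it; when several hits of the *same* family
#' overlap the residue (tandem repeats), the event is assigned to the
#' single hit with the smallest E-value, tie-broken by leftmost envelope
#' start, so it is never double-counted within one family.
#'
#' @param variants Variant table as returned by [read_maf()] (already
#'   filtered and de-duplicated).
#' @param hits Domain hit table (see [read_dat()]).
#' @param representatives Named character vector mapping `gene_id` to its
#'   representative `protein_id` (see [select_representatives()]).
#' @param group_by_cancer If `TRUE` (default), one count vector per
#'   `(domain_acc, cancer_type)`; if `FALSE`, cancer types are pooled
#'   under the label `"POOLED"`.
#' @param evalue_max Alignment inclusion threshold; hits with larger
#'   E-values are ignored (default 0.001).
#' @return A list of `position_counts` objects (elements `domain_acc`,
#'   `cancer_type`, `model_length`, `counts`, `n_events`), named
#'   `"<domain_acc>|<cancer_type>"`, with a `skip_report` attribute
#'   tallying variants without a representative protein, not covered by
#'   any hit, or dropped at an insert preceding the first match column.
#' @export
build_position_counts <- function(variants, hits, representatives,
                                  group_by_cancer = TRUE,
                                  evalue_max = 0.001) {
  v <- data.table::as.data.table(variants)
  h <- data.table::as.data.table(hits)
  if (!"hit_id" %in% names(h)) h <- validate_hits(h)
  skip <- c(n_variants = nrow(v), no_representative = 0L,
            not_covered = 0L, insert_before_first_match = 0L,
            n_projections = 0L)

  if (nrow(v)) {
    v <- unique(v, by = c("gene_id", "patient_id", "protein_pos", "alt_aa"))
    skip[["n_variants"]] <- nrow(v)
    v[, protein_id := representatives[gene_id]]
    skip[["no_representative"]] <- sum(is.na(v$protein_id))
    v <- v[!is.na(protein_id)]
    if (!group_by_cancer) v[, cancer_type := "POOLED"]
    v[, variant_id := seq_len(.N)]
  }

  h <- h[evalue <= evalue_max]
  groups <- unique(h[, .(domain_acc, model_length)])
  if (anyDuplicated(groups$domain_acc))
    stop("inconsistent model_length within a domain accession",
         call. = FALSE)

  proj <- NULL
  if (nrow(v) && nrow(h)) {
    map <- expand_hits(h)
    cand <- map[v[, .(variant_id, protein_id, protein_pos, cancer_type)],
                on = c("protein_id", "protein_pos"), nomatch = NULL,
                allow.cartesian = TRUE]
    covered <- unique(cand$variant_id)
    skip[["not_covered"]] <- nrow(v) - length(covered)
    if (nrow(cand)) {
      # within one family, keep the best hit covering the residue
      data.table::setorder(cand, variant_id, domain_acc, evalue,
                           protein_start, hit_id)
      cand <- cand[, .SD[1], by = .(variant_id, domain_acc)]
      skip[["insert_before_first_match"]] <- sum(is.na(cand$model_pos))
      proj <- cand[!is.na(model_pos)]
      proj <- v[, .(variant_id, gene_id, patient_id)][proj, on = "variant_id"]
      skip[["n_projections"]] <- nrow(proj)
    }
  } else if (nrow(v)) {
    skip[["not_covered"]] <- nrow(v)
  }

  cts <- if (group_by_cancer && nrow(v)) sort(unique(v$cancer_type))
    else "POOLED"

  out <- list()
  for (g in seq_len(nrow(groups))) {
    for (ct in cts) {
      L <- groups$model_length[g]
      counts <- integer(L)
      if (!is.null(proj)) {
        sub <- proj[domain_acc == groups$domain_acc[g] & cancer_type == ct]
        if (nrow(sub)) {
          tb <- table(factor(sub$model_pos, levels = seq_len(L)))
          counts <- as.integer(tb)
        }
      }
      pc <- structure(list(domain_acc = groups$domain_acc[g],
                           cancer_type = ct, model_length = L,
                           counts = counts, n_events = sum(counts)),
                      class = "position_counts")
      out[[paste(groups$domain_acc[g], ct, sep = "|")]] <- pc
    }
  }
  attr(out, "skip_report") <- skip
  if (!is.null(proj))
    attr(out, "projections") <-
      proj[, .(domain_acc, cancer_type, model_pos, gene_id, patient_id,
               protein_id, protein_pos, via_gap)]
  out
}

#' Histogram of per-position counts
#'
#' Returns `n_j`, the number of model positions carrying exactly `j`
#' somatic variants, for `j = 0..j_max`.  `sum(n_j)` always equals the
#' model length.
#'
#' @param x A `position_counts` object or an integer count vector.
#' @return Named integer vector (`names = j`).
#' @export
count_histogram <- function(x) {
  if (inherits(x, "position_counts")) x <- x$counts
  tab <- tabulate(as.integer(x) + 1L)
  stats::setNames(as.integer(tab), seq_along(tab) - 1L)
}

#' @export
print.position_counts <- function(x, ...) {
  cat(sprintf("position_counts: %s / %s, L = %d, %d events, max count %d\n",
              x$domain_acc, x$cancer_type, x$model_length, x$n_events,
              if (x$model_length) max(x$counts) else 0L))
  invisible(x)
}
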