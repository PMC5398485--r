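# Hotspot calling from fitted count mixtures and Table-1-style roll-ups.

#' Call oncodomain hotspots for one domain family
#'
#' A model position is a hotspot iff it carries at least one variant and
#' the local fdr of its count is below the cutoff; zero-count positions
#' are never significant.  Because the local fdr is monotonised over the
#' count, calls are nested: if count `t` is called, so is every count
#' `t' >= t`.
#'
#' @param counts A `position_counts` object (see
#'   [build_position_counts()]).
#' @param fit The matching [fit_null_mixture()] result (may be `NULL`,
#'   e.g. a skipped small family, in which case no positions are called).
#' @param cutoff Primary local-fdr significance cutoff (default 0.05).
#' @param cutoffs Additional cutoffs to report as `significant_at_*`
#'   columns (default `c(0.05, 0.01)`).
#' @return A `data.table` with one row per mutated position
#'   (`count >= 1`): `domain_acc`, `cancer_type`, `model_pos`, `count`,
#'   `fdr_local`, `fdr_tail`, `significant`, plus one logical
#'   `significant_at_<cutoff>` column per requested cutoff.
#' @export
call_hotspots <- function(counts, fit, cutoff = 0.05,
                          cutoffs = c(0.05, 0.01)) {
  stopifnot(inherits(counts, "position_counts"))
  pos <- which(counts$counts >= 1L)
  out <- data.table::data.table(
    domain_acc = character(), cancer_type = character(),
    model_pos = integer(), count = integer(), fdr_local = numeric(),
    fdr_tail = numeric(), significant = logical())
  for (cut in cutoffs)
    out[, paste0("significant_at_", cut) := logical()]
  if (!length(pos) || is.null(fit)) return(out[])
  cnt <- counts$counts[pos]
  fl <- local_fdr(cnt, fit)
  ft <- tail_fdr(cnt, fit)
  out <- data.table::data.table(
    domain_acc = counts$domain_acc, cancer_type = counts$cancer_type,
    model_pos = pos, count = cnt, fdr_local = fl, fdr_tail = ft,
    significant = fl < cutoff)
  for (cut in cutoffs)
    out[, paste0("significant_at_", cut) := fl < cut]
  data.table::setorder(out, model_pos)
  out[]
}

#' Summarise hotspot calls per cancer type
#'
#' Table-1-style roll-up: per cancer type, the number of oncodomains
#' (domain families with at least one significant position) and hotspot
#' positions at each cutoff, optionally alongside cohort sizes.
#'
#' @param calls A hotspot call table ([call_hotspots()] rows bound over
#'   all families/cancer types).
#' @param variants Optional variant table; adds `n_patients` and
#'   `n_variants` columns per cancer type.
#' @param cutoffs Local-fdr cutoffs to tabulate (default
#'   `c(0.05, 0.01)`; these must have matching `significant_at_*`
#'   columns in `calls`).
#' @return A `data.table` with one row per cancer type and columns
#'   `n_oncodomains_at_<cutoff>` / `n_hotspots_at_<cutoff>`.
#' @export
summarize_hotspots <- function(calls, variants = NULL,
                               cutoffs = c(0.05, 0.01)) {
  calls <- data.table::as.data.table(calls)
  cts <- sort(unique(c(calls$cancer_type,
                       if (!is.null(variants)) variants$cancer_type)))
  out <- data.table::data.table(cancer_type = cts)
  if (!is.null(variants)) {
    v <- data.table::as.data.table(variants)
    cohort <- v[, .(n_patients = data.table::uniqueN(patient_id),
                    n_variants = .N), by = cancer_type]
    out <- cohort[out, on = "cancer_type"]
    out[is.na(n_patients), `:=`(n_patients = 0L, n_variants = 0L)]
  }
  for (cut in cutoffs) {
    col <- paste0("significant_at_", cut)
    if (!col %in% names(calls))
      stop("calls table lacks column ", col, call. = FALSE)
    agg <- calls[calls[[col]] == TRUE,
                 .(nd = data.table::uniqueN(domain_acc), nh = .N),
                 by = cancer_type]
    out[, paste0("n_oncodomains_at_", cut) :=
          ifelse(is.na(match(cancer_type, agg$cancer_type)), 0L,
                 agg$nd[match(cancer_type, agg$cancer_type)])]
    out[, paste0("n_hotspots_at_", cut) :=
          ifelse(is.na(match(cancer_type, agg$cancer_type)), 0L,
                 agg$nh[match(cancer_type, agg$cancer_type)])]
  }
  data.table::setorder(out, cancer_type)
  out[]
}

#' Fit diagnostics table for a set of fitted families
#'
#' @param fits Named list of [fit_null_mixture()] results (possibly
#'   containing `NULL` entries for skipped families), named
#'   `"<domain_acc>|<cancer_type>"`.
#' @return A `data.table` with one row per family: mixture parameters,
#'   log-likelihood and convergence flags.
#' @export
fit_diagnostics <- function(fits) {
  rows <- lapply(names(fits), function(key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    f <- fits[[key]]
    if (is.null(f))
      return(data.table::data.table(
        domain_acc = parts[1], cancer_type = parts[2], skipped = TRUE,
        pi0 = NA_real_, lambda0 = NA_real_, lambda1 = NA_real_,
        p0 = NA_real_, loglik = NA_real_, converged = NA,
        degenerate = NA))
    data.table::data.table(
      domain_acc = parts[1], cancer_type = parts[2], skipped = FALSE,
      pi0 = f$pi0, lambda0 = f$lambda0, lambda1 = f$lambda1, p0 = f$p0,
      loglik = f$loglik, converged = f$converged,
      degenerate = f$degenerate)
  })
  data.table::rbindlist(rows)
}

#' Uniform random background placement of variants
#'
#' Diagnostic null: places `n_variants` events uniformly at random over
#' `model_length` positions (multinomial), mirroring the use of a
#' randomly distributed background of the same size as the observed
#' non-synonymous variants.
#'
#' @param n_variants Number of events to place.
#' @param model_length Number of model positions.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return Integer count vector of length `model_length` summing to
#'   `n_variants`.
#' @export
simulate_random_background <- function(n_variants, model_length,
                                       seed = NULL) {
  stopifnot(n_variants >= 0, model_length >= 1)
  draw <- function() {
    if (n_variants == 0) return(integer(model_length))
    as.integer(stats::rmultinom(1, n_variants,
                                rep(1 / model_length, model_length))[, 1])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
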