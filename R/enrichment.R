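# Overlap and enrichment statistics: two-sided Fisher exact test via the
# hypergeometric distribution, Bonferroni adjustment, point-biserial
# correlation, and term enrichment over gene or domain sets.

#' Two-sided Fisher exact overlap test
#'
#' Builds the 2x2 contingency table of two equal-length binary vectors
#' over the same position universe (e.g. hotspot yes/no vs annotated
#' yes/no) and computes the two-sided exact p-value as the sum of
#' hypergeometric probabilities, over all tables with the observed
#' margins, that do not exceed the probability of the observed table.
#' The odds ratio is the sample cross-product ratio, with the
#' Haldane-Anscombe 0.5 correction applied when any cell is zero
#' (reported, not used in the test).  A table with a zero margin has
#' `p = 1` by convention.
#'
#' @param x,y Logical (or 0/1) vectors of equal length.
#' @return An object of class `overlap_test`: list with elements `table`
#'   (2x2 integer matrix, rows = `x`, cols = `y`), `odds_ratio` and
#'   `p_value`.
#' @export
fisher_overlap <- function(x, y) {
  x <- as.logical(x); y <- as.logical(y)
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA in input vectors", call. = FALSE)
  a <- sum(x & y); b <- sum(x & !y); c <- sum(!x & y); d <- sum(!x & !y)
  tab <- matrix(c(a, c, b, d), 2, 2,
                dimnames = list(x = c("yes", "no"), y = c("yes", "no")))
  or <- if (min(a, b, c, d) == 0)
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)) else (a * d) / (b * c)
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0) {
    p <- 1
  } else {
    kk <- max(0, k - n):min(k, m)         # all tables with these margins
    pr <- stats::dhyper(kk, m, n, k)
    p <- min(1, sum(pr[pr <= stats::dhyper(a, m, n, k) * (1 + 1e-7)]))
  }
  structure(list(table = tab, odds_ratio = or, p_value = p),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat("Fisher exact overlap test\n")
  print(x$table)
  cat(sprintf("odds ratio = %.4g, two-sided p = %.4g\n",
              x$odds_ratio, x$p_value))
  invisible(x)
}

#' Bonferroni adjustment with explicit family size
#'
#' `min(1, m * p)` per test, where `m` is the number of tests in the
#' family (which must be at least the number of p-values supplied).
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size; defaults to `length(p)`.
#' @return Adjusted p-values, clipped at 1.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (m < length(p))
    stop("`m` must be at least the number of tests", call. = FALSE)
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  pmin(1, m * p)
}

#' Point-biserial (Pearson) correlation
#'
#' Pearson product-moment correlation between a binary indicator and a
#' real or binary vector (e.g. hotspot membership vs conservation).
#'
#' @param x Binary vector.
#' @param y Real or binary vector of the same length.
#' @return Correlation in `[-1, 1]`, or `NA` when either vector is
#'   constant.
#' @export
point_biserial <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Term enrichment of a hit set over a universe
#'
#' One Fisher exact 2x2 per term (membership in the hit set crossed with
#' membership in the term), Bonferroni-adjusted over the number of terms
#' tested.  Terms with no member in the universe are skipped (and
#' reported via a message).
#'
#' @param member_sets Named list mapping term id to a character vector of
#'   member identifiers (genes or domain accessions).
#' @param hit_set Character vector of hit identifiers; must be a subset
#'   of `universe`.
#' @param universe Character vector of all identifiers under test.
#' @return A `data.table` with one row per tested term: `term_id`,
#'   `n_term`, `n_hits`, `n_overlap`, `odds_ratio`, `p_raw`,
#'   `p_adjusted`, sorted by adjusted then raw p-value.
#' @export
term_enrichment <- function(member_sets, hit_set, universe) {
  universe <- unique(as.character(universe))
  hit_set <- unique(as.character(hit_set))
  if (!all(hit_set %in% universe))
    stop("`hit_set` must be a subset of `universe`", call. = FALSE)
  in_hit <- universe %in% hit_set
  rows <- list()
  skipped <- character()
  for (term in names(member_sets)) {
    members <- intersect(member_sets[[term]], universe)
    if (!length(members)) { skipped <- c(skipped, term); next }
    in_term <- universe %in% members
    ft <- fisher_overlap(in_hit, in_term)
    rows[[term]] <- data.table::data.table(
      term_id = term, n_term = length(members), n_hits = length(hit_set),
      n_overlap = sum(in_hit & in_term), odds_ratio = ft$odds_ratio,
      p_raw = ft$p_value)
  }
  if (length(skipped))
    message("skipped term(s) with empty universe intersection: ",
            paste(skipped, collapse = ", "))
  out <- data.table::rbindlist(rows)
  if (nrow(out)) {
    out[, p_adjusted := bonferroni(p_raw, m = nrow(out))]
    data.table::setorder(out, p_adjusted, p_raw, term_id)
  } else {
    out <- data.table::data.table(
      term_id = character(), n_term = integer(), n_hits = integer(),
      n_overlap = integer(), odds_ratio = numeric(), p_raw = numeric(),
      p_adjusted = numeric())
  }
  out[]
}

#' Project per-residue feature annotations onto model positions
#'
#' Maps protein-residue feature annotations (UniProt-feature-style TSV:
#' `protein_id`, `residue_pos`, `feature_name`) through the same domain
#' hit machinery as variants.  A model position is annotated with a
#' feature iff any member protein has that feature at a residue aligning
#' there.
#'
#' @param features Data frame with columns `protein_id`, `residue_pos`
#'   (1-based), `feature_name`.
#' @param hits Domain hit table (see [read_dat()]).
#' @param evalue_max Alignment inclusion threshold (default 0.001).
#' @return A `data.table` of unique (`domain_acc`, `model_pos`,
#'   `feature_name`) annotations.
#' @export
project_features <- function(features, hits, evalue_max = 0.001) {
  f <- data.table::as.data.table(features)
  stopifnot(all(c("protein_id", "residue_pos", "feature_name") %in% names(f)))
  h <- data.table::as.data.table(hits)
  if (!"hit_id" %in% names(h)) h <- validate_hits(h)
  map <- expand_hits(h[evalue <= evalue_max])
  hit <- map[f[, .(protein_id, protein_pos = as.integer(residue_pos),
                   feature_name)],
             on = c("protein_id", "protein_pos"), nomatch = NULL,
             allow.cartesian = TRUE]
  unique(hit[!is.na(model_pos),
             .(domain_acc, model_pos, feature_name)])
}

#' Feature enrichment of hotspot positions
#'
#' Pools all analysed (`domain_acc`, `model_pos`) positions into one
#' universe and tests, per feature, whether hotspot positions overlap
#' annotated positions more than expected (Fisher exact, Bonferroni over
#' features) — a Table-2-style ranking of features by adjusted p-value.
#'
#' @param calls Hotspot call table (see [call_hotspots()]); rows with
#'   `significant == TRUE` define hotspot positions.
#' @param annotations Projected feature table (see [project_features()]).
#' @param universe A `data.table` of all analysed (`domain_acc`,
#'   `model_pos`) pairs, e.g. every position of every analysed family.
#' @return A `data.table` with one row per feature: counts, odds ratio,
#'   raw and Bonferroni-adjusted p-values, sorted by adjusted p.
#' @export
feature_enrichment <- function(calls, annotations, universe) {
  u <- unique(data.table::as.data.table(universe)[, .(domain_acc, model_pos)])
  calls <- data.table::as.data.table(calls)
  hs <- unique(calls[significant == TRUE, .(domain_acc, model_pos)])
  ann <- data.table::as.data.table(annotations)
  key <- function(d) paste(d$domain_acc, d$model_pos, sep = "@")
  uk <- key(u)
  in_hot <- uk %in% key(hs)
  feats <- sort(unique(ann$feature_name))
  rows <- lapply(feats, function(fn) {
    in_ann <- uk %in% key(ann[feature_name == fn])
    ft <- fisher_overlap(in_hot, in_ann)
    data.table::data.table(feature_name = fn,
                           n_annotated = sum(in_ann),
                           n_hotspot = sum(in_hot),
                           n_overlap = sum(in_hot & in_ann),
                           odds_ratio = ft$odds_ratio, p_raw = ft$p_value)
  })
  out <- data.table::rbindlist(rows)
  if (nrow(out)) {
    out[, p_adjusted := bonferroni(p_raw, m = nrow(out))]
    data.table::setorder(out, p_adjusted, p_raw, feature_name)
  }
  out[]
}
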