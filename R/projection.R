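# Projection of protein-level variant positions onto 1-based domain
# model coordinates.

#' Project a protein position onto domain-model coordinates
#'
#' Maps 1-based protein residue positions through one domain hit onto the
#' hit's 1-based model match states.  A residue aligned to a match column
#' returns that model position (`via_gap = FALSE`); a residue in an
#' insert column is assigned to the last match position before the gap
#' (`via_gap = TRUE`); a residue outside the hit's span, or in an insert
#' that precedes the hit's first match column, has no projection
#' (`model_pos = NA`).
#'
#' @param protein_pos Vector of 1-based protein residue positions.
#' @param hit One hit: a single-row data frame (or list) in DAT layout
#'   (see [read_dat()]).
#' @param evalue_max Hits with E-value above this threshold are rejected
#'   with an error (default 0.001, the alignment inclusion threshold).
#' @return A `data.table` with columns `protein_pos`, `model_pos`
#'   (integer, `NA` when no projection exists) and `via_gap` (logical).
#' @export
project_variant <- function(protein_pos, hit, evalue_max = 0.001) {
  hit <- data.table::as.data.table(as.list(hit))
  if (nrow(hit) != 1) stop("`hit` must be a single hit", call. = FALSE)
  if (hit$evalue > evalue_max)
    stop(sprintf("hit E-value %g exceeds threshold %g", hit$evalue,
                 evalue_max), call. = FALSE)
  if (any(protein_pos < 1) || any(protein_pos != floor(protein_pos)))
    stop("`protein_pos` must contain positive integers", call. = FALSE)
  map <- expand_hits(validate_hits(hit))
  idx <- match(as.integer(protein_pos), map$protein_pos)
  mp <- map$model_pos[idx]
  data.table::data.table(
    protein_pos = as.integer(protein_pos),
    model_pos = mp,
    via_gap = ifelse(is.na(mp), NA, map$via_gap[idx]))
}
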