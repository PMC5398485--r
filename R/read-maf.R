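# MAF (Mutation Annotation Format) reading in the TCGA tab-separated
# dialect: column aliasing, HGVS-p parsing, validation/class filters,
# duplicate-event collapsing, and a skip report.

## default alias table; names resolved case-insensitively
.maf_aliases <- list(
  gene_id        = c("Hugo_Symbol", "Gene_Symbol", "gene", "gene_id"),
  patient_id     = c("Tumor_Sample_Barcode", "patient_barcode", "patient",
                     "patient_id", "sample_barcode"),
  classification = c("Variant_Classification", "classification"),
  validation     = c("Validation_Status", "validation_status", "validation"),
  protein_change = c("Protein_Change", "HGVSp_Short", "HGVSp",
                     "amino_acid_change", "aa_change", "AAChange"),
  protein_pos    = c("Protein_Position", "protein_position", "protein_pos",
                     "aa_position"),
  cancer_type    = c("Cancer_Type", "cancer_type", "tumor_type", "study")
)

.resolve_column <- function(header, aliases) {
  hit <- match(tolower(aliases), tolower(header))
  hit <- hit[!is.na(hit)]
  if (length(hit)) header[hit[1]] else NA_character_
}

## three-letter -> one-letter amino-acid code (plus Ter/stop)
.aa3to1 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
             Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
             Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
             Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V",
             Ter = "*", Sec = "U", Xaa = "X")

#' Parse short-form HGVS protein changes
#'
#' Extracts the reference amino acid, 1-based protein position and
#' alternate amino acid from strings such as `"p.V600E"`, `"V600E"` or
#' the three-letter form `"p.Val600Glu"`.  Unparseable strings yield `NA`
#' rows (and are counted in the [read_maf()] skip report).
#'
#' @param x Character vector of protein-change strings.
#' @return A `data.table` with columns `ref_aa`, `protein_pos`, `alt_aa`.
#' @export
parse_protein_change <- function(x) {
  x <- sub("^p\\.", "", trimws(as.character(x)))
  m1 <- regmatches(x, regexec("^([A-Z*])([0-9]+)([A-Z*])$", x))
  m3 <- regmatches(x, regexec("^([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$", x))
  ref <- alt <- rep(NA_character_, length(x))
  pos <- rep(NA_integer_, length(x))
  for (i in seq_along(x)) {
    if (length(m1[[i]]) == 4) {
      ref[i] <- m1[[i]][2]; pos[i] <- as.integer(m1[[i]][3]); alt[i] <- m1[[i]][4]
    } else if (length(m3[[i]]) == 4) {
      r <- .aa3to1[m3[[i]][2]]; a <- .aa3to1[m3[[i]][4]]
      if (!is.na(r) && !is.na(a)) {
        ref[i] <- unname(r); pos[i] <- as.integer(m3[[i]][3]); alt[i] <- unname(a)
      }
    }
  }
  data.table::data.table(ref_aa = ref, protein_pos = pos, alt_aa = alt)
}

.normalize_class <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("other", length(x))
  out[x %in% c("missense_mutation", "missense")] <- "missense"
  out[x %in% c("nonsense_mutation", "nonsense", "stop_gained")] <- "nonsense"
  out[x %in% c("silent", "synonymous", "synonymous_variant")] <- "silent"
  out
}

.normalize_validation <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unvalidated", length(x))
  out[x %in% c("valid", "validated", "verified")] <- "validated"
  out[x %in% c("unknown", "", "na", "none") | is.na(x)] <- "unknown"
  out
}

#' Read a TCGA-dialect MAF file of somatic variants
#'
#' Reads a tab-separated MAF, resolving column names case-insensitively
#' against an alias table (`Hugo_Symbol`, `Tumor_Sample_Barcode`,
#' `Variant_Classification`, `Validation_Status`, `Protein_Change` /
#' `HGVSp_Short`, ...), parses protein positions from an explicit position
#' column or from short-form HGVS-p protein changes, applies the
#' validation and variant-class filters, and collapses duplicate events
#' (identical gene, patient, protein position and alternate residue) to a
#' single record.  Gzipped files are read transparently.
#'
#' @param path Path to the MAF file (optionally gzipped).
#' @param require_validated If `TRUE` (default), keep only variants whose
#'   validation status is `validated`.
#' @param classes Character vector of variant classes to retain, from
#'   `{"missense", "nonsense", "silent", "other"}`.  Default: missense
#'   only (silent variants are never informative for protein-position
#'   hotspots and are excluded from null estimation by design).
#' @param cancer_type Study code attached to every record (e.g. `"SKCM"`);
#'   if `NULL`, taken from a `Cancer_Type` column when present, else
#'   `"NA"`.
#' @return A `data.table` with columns `gene_id`, `patient_id`,
#'   `cancer_type`, `protein_pos`, `ref_aa`, `alt_aa`, `classification`,
#'   `validation`, carrying a `skip_report` attribute (named integer
#'   vector: rows read and rows dropped per filter).  An empty result is a
#'   warning, not an error.
#' @export
read_maf <- function(path, require_validated = TRUE, classes = "missense",
                     cancer_type = NULL) {
  stopifnot(length(path) == 1)
  bad <- setdiff(classes, c("missense", "nonsense", "silent", "other"))
  if (length(bad))
    stop("unknown variant class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  magic <- readBin(path, "raw", 2)
  dt <- if (length(magic) == 2 && identical(magic, as.raw(c(0x1f, 0x8b)))) {
    con <- gzfile(path, "rt")
    on.exit(close(con), add = TRUE)
    data.table::fread(text = readLines(con), sep = "\t", header = TRUE,
                      colClasses = "character", showProgress = FALSE)
  } else {
    data.table::fread(path, sep = "\t", header = TRUE,
                      colClasses = "character", showProgress = FALSE)
  }
  header <- names(dt)
  cols <- vapply(.maf_aliases, .resolve_column, character(1), header = header)
  mandatory <- c("gene_id", "patient_id", "classification", "validation")
  for (m in mandatory)
    if (is.na(cols[[m]]))
      stop(sprintf("MAF %s lacks a '%s' column (known aliases: %s)",
                   path, m, paste(.maf_aliases[[m]], collapse = ", ")),
           call. = FALSE)
  if (is.na(cols[["protein_change"]]) && is.na(cols[["protein_pos"]]))
    stop(sprintf(paste0("MAF %s lacks both a 'protein_change' and a ",
                        "'protein_pos' column (known aliases: %s / %s)"),
                 path, paste(.maf_aliases$protein_change, collapse = ", "),
                 paste(.maf_aliases$protein_pos, collapse = ", ")),
         call. = FALSE)

  n_read <- nrow(dt)
  skip <- c(rows_read = n_read, dropped_validation = 0L, dropped_class = 0L,
            dropped_no_position = 0L, duplicates_collapsed = 0L)
  empty <- data.table::data.table(
    gene_id = character(), patient_id = character(),
    cancer_type = character(), protein_pos = integer(),
    ref_aa = character(), alt_aa = character(),
    classification = character(), validation = character())
  if (n_read == 0) {
    warning("MAF ", path, " contains no data rows", call. = FALSE)
    data.table::setattr(empty, "skip_report", skip)
    return(empty)
  }

  out <- data.table::data.table(
    gene_id = dt[[cols[["gene_id"]]]],
    patient_id = dt[[cols[["patient_id"]]]],
    classification = .normalize_class(dt[[cols[["classification"]]]]),
    validation = .normalize_validation(dt[[cols[["validation"]]]]))
  out$cancer_type <- if (!is.null(cancer_type)) as.character(cancer_type)
    else if (!is.na(cols[["cancer_type"]])) dt[[cols[["cancer_type"]]]]
    else NA_character_

  if (!is.na(cols[["protein_change"]])) {
    pc <- parse_protein_change(dt[[cols[["protein_change"]]]])
    out$protein_pos <- pc$protein_pos
    out$ref_aa <- pc$ref_aa
    out$alt_aa <- pc$alt_aa
  } else {
    out$protein_pos <- suppressWarnings(as.integer(dt[[cols[["protein_pos"]]]]))
    out$ref_aa <- NA_character_
    out$alt_aa <- NA_character_
  }
  out[is.na(protein_pos) | protein_pos < 1, protein_pos := NA_integer_]

  keep_v <- if (require_validated) out$validation == "validated" else
    rep(TRUE, nrow(out))
  skip[["dropped_validation"]] <- sum(!keep_v)
  out <- out[keep_v]
  keep_c <- out$classification %in% classes
  skip[["dropped_class"]] <- sum(!keep_c)
  out <- out[keep_c]
  keep_p <- !is.na(out$protein_pos)
  skip[["dropped_no_position"]] <- sum(!keep_p)
  out <- out[keep_p]

  n_before <- nrow(out)
  out <- unique(out, by = c("gene_id", "patient_id", "protein_pos", "alt_aa"))
  skip[["duplicates_collapsed"]] <- n_before - nrow(out)

  data.table::setcolorder(out, names(empty))
  if (nrow(out) == 0)
    warning("MAF ", path, " is empty after filtering", call. = FALSE)
  data.table::setattr(out, "skip_report", skip)
  out[]
}
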