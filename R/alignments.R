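# Protein <-> domain-model alignments.  The canonical input is the
# Domain Alignment Table (DAT): one TSV row per domain hit with a
# state_string over {M, I, D} read left to right — M consumes one protein
# residue and one model match state, I consumes one protein residue
# (insert), D consumes one model position (deletion).  Stockholm
# alignments are converted to DAT via the profile-HMM case convention.

.dat_columns <- c("protein_id", "domain_acc", "model_length", "evalue",
                  "protein_start", "model_start", "state_string")

#' Read a Domain Alignment Table (DAT)
#'
#' @param path Path to a TSV with columns `protein_id`, `domain_acc`,
#'   `model_length`, `evalue`, `protein_start`, `model_start`,
#'   `state_string` (gzip transparently supported).
#' @return A `data.table` of domain hits with an added integer `hit_id`
#'   key, validated (states in `{M,I,D}`, at least one match state, model
#'   span within `[1, model_length]`, non-negative E-values).
#' @export
read_dat <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          showProgress = FALSE)
  miss <- setdiff(.dat_columns, names(dt))
  if (length(miss))
    stop("DAT ", path, " lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  dt <- dt[, .dat_columns, with = FALSE]
  validate_hits(dt)
}

#' @rdname read_dat
#' @param hits A hit table in DAT column layout.
#' @export
validate_hits <- function(hits) {
  dt <- data.table::as.data.table(hits)
  dt[, `:=`(model_length = as.integer(model_length),
            protein_start = as.integer(protein_start),
            model_start = as.integer(model_start),
            evalue = as.numeric(evalue))]
  if (nrow(dt)) {
    if (any(grepl("[^MID]", dt$state_string)))
      stop("state_string characters must be M, I or D", call. = FALSE)
    nM <- nchar(gsub("[^M]", "", dt$state_string))
    nD <- nchar(gsub("[^D]", "", dt$state_string))
    if (any(nM == 0))
      stop("every hit needs at least one match (M) state", call. = FALSE)
    if (any(dt$model_start < 1) ||
        any(dt$model_start - 1L + nM + nD > dt$model_length))
      stop("model span exceeds [1, model_length]", call. = FALSE)
    if (any(dt$protein_start < 1))
      stop("protein_start must be >= 1", call. = FALSE)
    if (any(!is.finite(dt$evalue)) || any(dt$evalue < 0))
      stop("E-values must be non-negative", call. = FALSE)
  }
  dt[, hit_id := seq_len(.N)]
  dt[]
}

#' Write a Domain Alignment Table
#'
#' @param hits Hit table (DAT columns; extra columns dropped).
#' @param path Output path.
#' @export
write_dat <- function(hits, path) {
  dt <- data.table::as.data.table(hits)[, .dat_columns, with = FALSE]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' Expand hits to a per-residue coordinate map
#'
#' Walks each hit's state string and returns one row per protein residue
#' the hit consumes, with the model match state it aligns to.  Residues
#' in insert columns carry the model position of the nearest preceding
#' match column (`via_gap = TRUE`), or `NA` when the insert precedes the
#' first match state of the hit.
#'
#' @param hits Validated hit table (see [read_dat()]).
#' @return A `data.table` with columns `hit_id`, `protein_id`,
#'   `domain_acc`, `model_length`, `evalue`, `protein_start`,
#'   `protein_pos`, `model_pos`, `via_gap`.
#' @export
expand_hits <- function(hits) {
  dt <- data.table::as.data.table(hits)
  if (!"hit_id" %in% names(dt)) dt <- validate_hits(dt)
  maps <- lapply(seq_len(nrow(dt)), function(i) {
    ch <- strsplit(dt$state_string[i], "", fixed = TRUE)[[1]]
    isM <- ch == "M"; isI <- ch == "I"
    res <- isM | isI                       # consumes a protein residue
    ppos <- dt$protein_start[i] - 1L + cumsum(res)
    midx <- dt$model_start[i] - 1L + cumsum(!isI)  # M or D consume model
    lastM <- cummax(ifelse(isM, midx, 0L)) # most recent match state so far
    mp <- ifelse(isM, midx, ifelse(lastM > 0L, lastM, NA_integer_))
    data.table::data.table(hit_id = dt$hit_id[i],
                           protein_pos = as.integer(ppos[res]),
                           model_pos = as.integer(mp[res]),
                           via_gap = isI[res])
  })
  map <- data.table::rbindlist(maps)
  meta <- dt[, .(hit_id, protein_id, domain_acc, model_length, evalue,
                 protein_start)]
  out <- meta[map, on = "hit_id"]
  data.table::setcolorder(out, c("hit_id", "protein_id", "domain_acc",
                                 "model_length", "evalue", "protein_start",
                                 "protein_pos", "model_pos", "via_gap"))
  out[]
}

#' Convert a Stockholm alignment to a Domain Alignment Table
#'
#' Reads a Stockholm-format alignment (e.g. `hmmalign` output) and
#' derives each sequence's match/insert/delete structure from the
#' profile-HMM case convention: uppercase letters are match-state
#' residues, `-` is a deletion at a match state, lowercase letters are
#' insert-state residues, and `.` pads insert columns.  Sequence names in
#' `id/start-end` form set the protein start coordinate; otherwise the
#' aligned region is assumed to start at residue 1.
#'
#' Stockholm files carry no E-values, so hits are assigned `evalue`
#' (default 0, i.e. always below threshold); filter upstream if needed.
#'
#' @param path Path to a Stockholm file.
#' @param domain_acc Domain accession for the resulting hits; defaults to
#'   the `#=GF AC` (or `#=GF ID`) record, else the file basename.
#' @param evalue E-value assigned to every hit.
#' @return A validated hit `data.table` in DAT layout.
#' @export
stockholm_to_dat <- function(path, domain_acc = NULL, evalue = 0) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^# STOCKHOLM", lines[1]))
    stop(path, " is not a Stockholm file", call. = FALSE)
  acc <- sub("^#=GF AC\\s+", "", grep("^#=GF AC\\s", lines, value = TRUE))
  id <- sub("^#=GF ID\\s+", "", grep("^#=GF ID\\s", lines, value = TRUE))
  if (is.null(domain_acc))
    domain_acc <- if (length(acc)) acc[1] else if (length(id)) id[1] else
      tools::file_path_sans_ext(basename(path))
  seq_lines <- lines[!grepl("^#", lines) & !grepl("^//", lines) &
                       nzchar(trimws(lines))]
  if (!length(seq_lines)) stop("no sequences in ", path, call. = FALSE)
  parts <- regmatches(seq_lines, regexec("^(\\S+)\\s+(\\S+)$", seq_lines))
  if (any(lengths(parts) != 3))
    stop("malformed Stockholm sequence line in ", path, call. = FALSE)
  nm <- vapply(parts, `[`, "", 2)
  aln <- vapply(parts, `[`, "", 3)
  aln <- vapply(split(aln, factor(nm, levels = unique(nm))),
                paste0, "", collapse = "")   # join interleaved blocks
  nm <- names(aln)

  rows <- lapply(seq_along(aln), function(i) {
    ch <- strsplit(aln[[i]], "", fixed = TRUE)[[1]]
    st <- character(length(ch))
    st[grepl("[A-Z]", ch)] <- "M"
    st[ch %in% c("-", "_")] <- "D"
    st[grepl("[a-z]", ch)] <- "I"
    st <- st[nzchar(st)]                  # '.' and '~' pad columns
    span <- regmatches(nm[i], regexec("^(.*)/([0-9]+)-([0-9]+)$", nm[i]))[[1]]
    pid <- if (length(span)) span[2] else nm[i]
    pstart <- if (length(span)) as.integer(span[3]) else 1L
    data.table::data.table(protein_id = pid, domain_acc = domain_acc,
                           model_length = sum(st != "I"),
                           evalue = evalue, protein_start = pstart,
                           model_start = 1L,
                           state_string = paste(st, collapse = ""))
  })
  dt <- data.table::rbindlist(rows)
  if (length(unique(dt$model_length)) > 1)
    stop("inconsistent match-column count across sequences in ", path,
         call. = FALSE)
  validate_hits(dt)
}
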