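# End-to-end orchestration: configuration, the full
# read -> project -> fit -> call -> report pipeline, and the cohort
# subsampling ("bootstrap") experiment.

#' Assemble or load a run configuration
#'
#' A run configuration names the inputs and the analysis parameters.
#' Required fields: `maf` (one or more MAF paths; names, when present,
#' set the cancer-type label per file), `fasta` (protein FASTA),
#' `alignments` (DAT or Stockholm paths) and `out_dir`.  Optional:
#' `features` (per-residue feature TSV), `terms` (term TSV with columns
#' `term_id`, `term_name`, `member_id`), `term_level` (`"gene"` or
#' `"domain"`), `evalue_max` (0.001), `cutoffs` (`c(0.05, 0.01)`),
#' `classes` (`"missense"`), `require_validated` (`TRUE`),
#' `min_positions` (10), `pooled` (`FALSE`) and `seed` (1).
#'
#' @param config A named list, or the path to a YAML file holding one.
#' @return A validated configuration list of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  defaults <- list(evalue_max = 0.001, cutoffs = c(0.05, 0.01),
                   classes = "missense", require_validated = TRUE,
                   min_positions = 10, pooled = FALSE, seed = 1,
                   features = NULL, terms = NULL, term_level = "gene")
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  for (nm in c("maf", "fasta", "alignments", "out_dir"))
    if (is.null(config[[nm]]))
      stop("run configuration lacks required field '", nm, "'",
           call. = FALSE)
  config$cutoffs <- as.numeric(unlist(config$cutoffs))
  if (any(config$cutoffs <= 0 | config$cutoffs >= 1))
    stop("fdr cutoffs must lie in (0, 1)", call. = FALSE)
  if (!config$term_level %in% c("gene", "domain"))
    stop("term_level must be 'gene' or 'domain'", call. = FALSE)
  config$seed <- as.integer(config$seed)
  structure(config, class = "run_config")
}

.config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(deparse(config[sort(names(config))]), collapse = ""), tmp)
  unname(tools::md5sum(tmp))
}

.report_header <- function(config) {
  sprintf("# oncodomains %s seed=%d config=%s",
          as.character(utils::packageVersion("oncodomains")),
          config$seed, .config_hash(unclass(config)))
}

.write_report_tsv <- function(dt, path, header) {
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE,
                     col.names = TRUE)
  invisible(path)
}

.read_alignments <- function(paths, stage = "alignments") {
  hits <- lapply(paths, function(p) {
    first <- tryCatch(readLines(p, n = 1), error = function(e)
      stop(sprintf("[%s] cannot read %s: %s", stage, p, conditionMessage(e)),
           call. = FALSE))
    if (length(first) && grepl("^# STOCKHOLM", first))
      stockholm_to_dat(p) else read_dat(p)
  })
  validate_hits(data.table::rbindlist(
    lapply(hits, function(h) h[, .dat_columns, with = FALSE])))
}

#' Run the oncodomain hotspot pipeline end to end
#'
#' Reads variants, proteins and alignments, selects one representative
#' protein per gene, projects variants onto domain-model positions, fits
#' the ZIP-null mixture per (domain family, cancer type), calls hotspot
#' positions by local fdr, scores per-family conservation, and (when
#' annotation inputs are configured) performs feature and term
#' enrichment.  All result tables are written to `out_dir` as TSV files
#' with one `#`-prefixed header line carrying the package version, seed
#' and configuration hash, together with a machine-readable
#' `run_report.yaml`.  Outputs are deterministic given the configuration.
#'
#' @param config A [run_config()] (or anything it accepts).
#' @return Invisibly, a list with the in-memory results: `variants`,
#'   `representatives`, `hits`, `counts`, `fits`, `calls`, `summary`,
#'   `diagnostics`, `conservation`, `feature_enrichment`,
#'   `term_enrichment`, `report`.
#' @export
run_pipeline <- function(config) {
  config <- run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- .report_header(config)
  withr::local_seed(config$seed)

  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }

  proteins <- stage("fasta", read_protein_fasta(config$fasta))
  representatives <- select_representatives(proteins)
  hits <- .read_alignments(config$alignments)

  maf_paths <- config$maf
  ct_labels <- names(maf_paths)
  maf_list <- lapply(seq_along(maf_paths), function(i) {
    ct <- if (!is.null(ct_labels) && nzchar(ct_labels[i])) ct_labels[i]
      else NULL
    stage(paste0("maf:", maf_paths[i]),
          read_maf(maf_paths[i], require_validated = config$require_validated,
                   classes = config$classes, cancer_type = ct))
  })
  skip_maf <- Reduce(`+`, lapply(maf_list, attr, "skip_report"))
  variants <- data.table::rbindlist(maf_list, fill = TRUE)

  counts <- build_position_counts(variants, hits, representatives,
                                  group_by_cancer = !isTRUE(config$pooled),
                                  evalue_max = config$evalue_max)
  fits <- lapply(counts, function(pc) {
    if (pc$model_length < config$min_positions || all(pc$counts == 0))
      return(NULL)
    fit_null_mixture(pc$counts, min_positions = config$min_positions)
  })
  primary <- max(config$cutoffs)
  calls <- data.table::rbindlist(lapply(names(counts), function(key) {
    call_hotspots(counts[[key]], fits[[key]], cutoff = primary,
                  cutoffs = config$cutoffs)
  }))
  summary <- summarize_hotspots(calls, variants, cutoffs = config$cutoffs)
  diagnostics <- fit_diagnostics(fits)
  conservation <- family_conservation(proteins, hits,
                                      evalue_max = config$evalue_max)

  feat_enr <- term_enr <- NULL
  universe <- data.table::rbindlist(lapply(counts, function(pc)
    data.table::data.table(domain_acc = pc$domain_acc,
                           model_pos = seq_len(pc$model_length))))
  universe <- unique(universe)
  if (!is.null(config$features)) {
    features <- stage("features",
                      data.table::fread(config$features, sep = "\t"))
    ann <- project_features(features, hits, evalue_max = config$evalue_max)
    feat_enr <- feature_enrichment(calls, ann, universe)
  }
  if (!is.null(config$terms)) {
    terms <- stage("terms", data.table::fread(config$terms, sep = "\t"))
    member_sets <- split(as.character(terms$member_id), terms$term_id)
    proj <- attr(counts, "projections")
    if (config$term_level == "gene") {
      hot <- unique(calls[significant == TRUE,
                          .(domain_acc, cancer_type, model_pos)])
      hit_genes <- if (!is.null(proj) && nrow(hot))
        unique(proj[hot, on = c("domain_acc", "cancer_type", "model_pos"),
                    nomatch = NULL]$gene_id) else character()
      uni <- if (!is.null(proj)) unique(proj$gene_id) else character()
      term_enr <- term_enrichment(member_sets, hit_genes, uni)
    } else {
      onco <- unique(calls[significant == TRUE]$domain_acc)
      term_enr <- term_enrichment(member_sets, onco,
                                  unique(universe$domain_acc))
    }
  }

  report <- list(
    seed = config$seed,
    n_maf_files = length(maf_paths),
    variant_filter = as.list(skip_maf),
    projection = as.list(attr(counts, "skip_report")),
    families_total = length(counts),
    families_fitted = sum(!vapply(fits, is.null, logical(1))),
    families_skipped = sum(vapply(fits, is.null, logical(1))),
    n_hotspot_calls = as.list(stats::setNames(
      lapply(config$cutoffs, function(cut)
        sum(calls[[paste0("significant_at_", cut)]])),
      paste0("at_", config$cutoffs))))

  .write_report_tsv(calls, file.path(config$out_dir, "hotspots.tsv"), hdr)
  .write_report_tsv(summary, file.path(config$out_dir, "summary.tsv"), hdr)
  .write_report_tsv(diagnostics,
                    file.path(config$out_dir, "fit_diagnostics.tsv"), hdr)
  .write_report_tsv(conservation,
                    file.path(config$out_dir, "conservation.tsv"), hdr)
  if (!is.null(feat_enr))
    .write_report_tsv(feat_enr,
                      file.path(config$out_dir, "feature_enrichment.tsv"),
                      hdr)
  if (!is.null(term_enr))
    .write_report_tsv(term_enr,
                      file.path(config$out_dir, "term_enrichment.tsv"), hdr)
  yaml::write_yaml(report, file.path(config$out_dir, "run_report.yaml"))

  invisible(list(variants = variants, representatives = representatives,
                 hits = hits, counts = counts, fits = fits, calls = calls,
                 summary = summary, diagnostics = diagnostics,
                 conservation = conservation,
                 feature_enrichment = feat_enr,
                 term_enrichment = term_enr, report = report))
}

#' Cohort subsampling ("bootstrap") experiment
#'
#' Repeatedly subsamples, *without replacement*, a fraction of the
#' cohort — whole patients (with all their variants) or individual
#' variant events — then recounts, refits and recalls hotspots, tracking
#' how many oncodomains and hotspot positions survive at the primary
#' cutoff.  Subsampling without replacement mirrors the "use only 75% /
#' 50% of the available data" design; a classical with-replacement
#' bootstrap cannot take a strict subset of patients.
#'
#' @param variants Variant table (see [read_maf()]).
#' @param hits Domain hit table.
#' @param representatives Gene-to-protein mapping.
#' @param fractions Subsampling fractions in `(0, 1]`.
#' @param unit `"patients"` or `"variants"`.
#' @param reps Replicates per fraction (default 100).
#' @param cutoff Local-fdr cutoff for calling (default 0.05).
#' @param evalue_max,min_positions As in [run_pipeline()].
#' @param group_by_cancer Passed to [build_position_counts()].
#' @param seed Integer seed for the whole experiment.
#' @return A `data.table` with one row per (fraction, replicate):
#'   `fraction`, `unit`, `replicate`, `n_units`, `n_oncodomains`,
#'   `n_hotspots`.  Replicates whose subsample contains zero units are
#'   skipped and recorded in the `skipped` attribute.
#' @export
bootstrap_cohort <- function(variants, hits, representatives,
                             fractions = c(0.5, 0.75), unit = "patients",
                             reps = 100, cutoff = 0.05,
                             evalue_max = 0.001, min_positions = 10,
                             group_by_cancer = TRUE, seed = 1) {
  unit <- match.arg(unit, c("patients", "variants"))
  if (any(fractions <= 0 | fractions > 1))
    stop("fractions must lie in (0, 1]", call. = FALSE)
  v <- data.table::as.data.table(variants)
  h <- data.table::as.data.table(hits)
  if (!"hit_id" %in% names(h)) h <- validate_hits(h)

  run_once <- function(sub) {
    counts <- build_position_counts(sub, h, representatives,
                                    group_by_cancer = group_by_cancer,
                                    evalue_max = evalue_max)
    calls <- data.table::rbindlist(lapply(counts, function(pc) {
      if (pc$model_length < min_positions || all(pc$counts == 0))
        return(NULL)
      fit <- fit_null_mixture(pc$counts, min_positions = min_positions)
      call_hotspots(pc, fit, cutoff = cutoff, cutoffs = cutoff)
    }))
    if (!nrow(calls)) return(c(0L, 0L))
    sig <- calls[significant == TRUE]
    c(data.table::uniqueN(sig$domain_acc), nrow(sig))
  }

  rows <- list()
  skipped <- list()
  withr::with_seed(seed, {
    for (f in fractions) {
      for (r in seq_len(reps)) {
        if (unit == "patients") {
          pats <- unique(v$patient_id)
          n_units <- floor(f * length(pats))
          if (n_units == 0) {
            skipped[[length(skipped) + 1L]] <- list(fraction = f,
                                                    replicate = r)
            next
          }
          keep <- sample(pats, n_units)
          sub <- v[patient_id %in% keep]
        } else {
          n_units <- floor(f * nrow(v))
          if (n_units == 0) {
            skipped[[length(skipped) + 1L]] <- list(fraction = f,
                                                    replicate = r)
            next
          }
          sub <- v[sample.int(nrow(v), n_units)]
        }
        res <- run_once(sub)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          fraction = f, unit = unit, replicate = r, n_units = n_units,
          n_oncodomains = res[1], n_hotspots = res[2])
      }
    }
  })
  out <- data.table::rbindlist(rows)
  attr(out, "skipped") <- skipped
  out[]
}
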