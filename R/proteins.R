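# Protein FASTA input and the one-representative-per-gene rule.

#' Parse `protein_id|source|gene_id` FASTA headers
#'
#' Default header parser for protein FASTA input: each header carries the
#' protein accession, the source database (`swissprot` or `refseq`) and
#' the gene identifier, pipe-separated.  Supply your own function of the
#' header string to [read_protein_fasta()] for other conventions (e.g.
#' native RefSeq / Swiss-Prot deflines).
#'
#' @param header Character vector of FASTA header lines (without `>`).
#' @return A `data.frame` with columns `protein_id`, `source`, `gene_id`.
#' @export
parse_fasta_header <- function(header) {
  parts <- data.table::tstrsplit(header, "|", fixed = TRUE)
  if (length(parts) < 3)
    stop("FASTA header not in 'protein_id|source|gene_id' form: ",
         header[1], call. = FALSE)
  src <- tolower(trimws(parts[[2]]))
  if (any(!src %in% c("swissprot", "refseq")))
    stop("FASTA header source must be 'swissprot' or 'refseq'",
         call. = FALSE)
  data.frame(protein_id = trimws(parts[[1]]), source = src,
             gene_id = trimws(parts[[3]]))
}

#' Read protein sequences with gene and source metadata
#'
#' Reads an amino-acid FASTA via [Biostrings::readAAStringSet()] and
#' extracts per-protein metadata from the headers.
#'
#' @param path Path to a FASTA file.
#' @param header_parser Function mapping header strings to a data frame
#'   with columns `protein_id`, `source`, `gene_id`;
#'   defaults to [parse_fasta_header()].
#' @return A `data.table` with columns `protein_id`, `gene_id`, `source`,
#'   `sequence`, `length`.
#' @export
read_protein_fasta <- function(path, header_parser = parse_fasta_header) {
  seqs <- Biostrings::readAAStringSet(path)
  meta <- header_parser(names(seqs))
  dt <- data.table::as.data.table(meta)
  dt[, `:=`(sequence = as.character(seqs), length = Biostrings::width(seqs))]
  dt[]
}

#' Choose one representative protein per gene
#'
#' Redundant protein entries exist across source databases and isoforms;
#' for each gene the representative is the longest Swiss-Prot protein, or
#' the longest RefSeq protein if the gene has no Swiss-Prot entry.
#' Swiss-Prot always beats RefSeq regardless of length; within a source
#' the longest wins (ties broken by accession for determinism).
#'
#' @param proteins A data frame as returned by [read_protein_fasta()]
#'   (columns `protein_id`, `gene_id`, `source`, `length`).
#' @return Named character vector mapping `gene_id` to the representative
#'   `protein_id`.
#' @export
select_representatives <- function(proteins) {
  dt <- data.table::as.data.table(proteins)
  if (nrow(dt) == 0) return(stats::setNames(character(), character()))
  stopifnot(all(c("protein_id", "gene_id", "source", "length") %in% names(dt)))
  dt <- dt[order(gene_id, factor(source, levels = c("swissprot", "refseq")),
                 -length, protein_id)]
  rep <- dt[, .SD[1], by = gene_id]
  stats::setNames(rep$protein_id, rep$gene_id)
}
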