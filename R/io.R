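# Plain-text interchange: AIRR-style rearrangement TSVs, participant and
# response tables, and FASTA for germline templates and reads.

#' Read / write AIRR-style rearrangement tables
#'
#' The rearrangement TSV uses the columns `sequence_id`, `participant_id`,
#' `umi`, `v_call`, `v_mismatches`, `cdr3_aa`, `primer_set`.
#'
#' @param path File path.
#' @return `read_airr_tsv()` returns a tibble.
#' @export
read_airr_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    v_mismatches = readr::col_integer(),
                    .default = readr::col_character()
                  ))
}

#' @param records Rearrangement tibble (see [simulate_repertoire()]).
#' @rdname read_airr_tsv
#' @export
write_airr_tsv <- function(records, path) {
  readr::write_tsv(tibble::as_tibble(records), path)
  invisible(path)
}

#' Read / write participant and response tables
#'
#' Participants: `participant_id`, `dose_group`, `allele_1`, `allele_2`,
#' `n02`, `n04`. Responses: `participant_id`, `dose_group`, `compartment`,
#' `week`, `n02`, `n04`, `high_dose`, `V`, `N`.
#'
#' @param x Tibble to write.
#' @param path File path.
#' @export
write_trial_tsv <- function(x, path) {
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}

#' @rdname write_trial_tsv
#' @export
read_participants_tsv <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  out$dose_group <- factor(out$dose_group,
                           levels = c("low", "high", "placebo"))
  out
}

#' @rdname write_trial_tsv
#' @export
read_responses_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write named sequences as FASTA
#'
#' @param sequences Named character vector (names become FASTA headers), or
#'   a tibble with `sequence_id` and `sequence` columns.
#' @param path Output path.
#' @export
write_fasta <- function(sequences, path) {
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$sequence, sequences$sequence_id)
  }
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  } else {
    writeLines(paste0(">", names(sequences), "\n", unname(sequences)), path)
  }
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    s <- Biostrings::readDNAStringSet(path)
    return(setNames(as.character(s), names(s)))
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) paste(x, collapse = ""), character(1))
  setNames(unname(seqs), sub("^>", "", lines[hdr]))
}
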