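# FASTA and tabular I/O. FASTA handling is delegated to Biostrings; record
# ids are preserved verbatim and output is wrapped at 60 columns.

#' Read DNA records from a FASTA file
#' @param path Path to a FASTA file.
#' @return Named character vector of upper-case DNA sequences; names are the
#'   record ids, preserved verbatim.
#' @export
read_fasta_dna <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  out <- toupper(as.character(set))
  names(out) <- names(set)
  out
}

#' Read amino-acid records from a FASTA file
#' @param path Path to a FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta_aa <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  out <- toupper(as.character(set))
  names(out) <- names(set)
  out
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector (DNA or amino acid).
#' @param path Output path.
#' @param type `"dna"` or `"aa"`.
#' @export
write_fasta <- function(sequences, path, type = c("dna", "aa")) {
  type <- match.arg(type)
  stopifnot(is.character(sequences), !is.null(names(sequences)))
  set <- if (type == "dna") {
    Biostrings::DNAStringSet(sequences)
  } else {
    Biostrings::AAStringSet(sequences)
  }
  Biostrings::writeXStringSet(set, filepath = path, width = 60L)
  invisible(path)
}

#' Read a tabular file of amino-acid windows
#'
#' Expects a TSV with header and columns `id`, `window`, `start_site`
#' (additional columns are carried through).
#'
#' @param path Path to the TSV.
#' @return A data.frame.
#' @export
read_window_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE)
  need <- c("id", "window", "start_site")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("window TSV lacks columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("empty window TSV: ", path)
  df$start_site <- as.integer(df$start_site)
  df
}

#' Read tip states from a two-column TSV
#'
#' @param path TSV with header columns `tip` and `state`.
#' @return Named character vector of states, names are tip labels.
#' @export
read_states_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("tip", "state") %in% names(df))) {
    stop("states TSV must have columns 'tip' and 'state'")
  }
  stats::setNames(as.character(df$state), df$tip)
}
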