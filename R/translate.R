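# DNA handling and translation for short SWS1 opsin fragments.
# All sequences are plain upper-case character strings over the IUPAC DNA
# alphabet; translation uses the standard genetic code.

.pkg_cache <- new.env(parent = emptyenv())

.dna_alphabet <- function() names(Biostrings::IUPAC_CODE_MAP)

.iupac_complement <- c(
  A = "T", C = "G", G = "C", T = "A",
  M = "K", R = "Y", W = "W", S = "S", Y = "R", K = "M",
  V = "B", H = "D", D = "H", B = "V", N = "N"
)

#' Normalize and validate a DNA sequence
#'
#' Upper-cases the input and checks every character against the IUPAC DNA
#' alphabet (the four bases plus ambiguity codes).
#'
#' @param sequence Character scalar, the DNA sequence.
#' @return The normalized (upper-case) sequence.
#' @export
normalize_dna <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  s <- toupper(sequence)
  if (nchar(s) == 0L) stop("DNA sequence is empty")
  bad <- setdiff(unique(strsplit(s, "")[[1]]), .dna_alphabet())
  if (length(bad) > 0L) {
    stop("invalid DNA characters: ", paste(bad, collapse = ", "))
  }
  s
}

#' Reverse complement of a DNA sequence
#'
#' IUPAC ambiguity codes are complemented to their ambiguous counterparts.
#'
#' @param sequence Character scalar DNA sequence.
#' @return Character scalar, the reverse complement.
#' @export
reverse_complement <- function(sequence) {
  s <- normalize_dna(sequence)
  chars <- rev(strsplit(s, "")[[1]])
  paste(.iupac_complement[chars], collapse = "")
}

# Residue for one codon; ambiguity codes are expanded and the codon
# translates to a residue only if all disambiguations agree, otherwise "X".
# Stop codons give "*". Memoised: the 15^3 possible codons are few.
.translate_codon <- function(codon) {
  if (is.null(.pkg_cache$codon_memo)) {
    .pkg_cache$codon_memo <- new.env(parent = emptyenv())
  }
  memo <- .pkg_cache$codon_memo
  hit <- memo[[codon]]
  if (!is.null(hit)) return(hit)
  gc_tab <- Biostrings::GENETIC_CODE
  map <- Biostrings::IUPAC_CODE_MAP
  bases <- strsplit(codon, "")[[1]]
  expansions <- expand.grid(
    strsplit(map[[bases[1]]], "")[[1]],
    strsplit(map[[bases[2]]], "")[[1]],
    strsplit(map[[bases[3]]], "")[[1]],
    stringsAsFactors = FALSE
  )
  aas <- unique(gc_tab[paste0(expansions[[1]], expansions[[2]], expansions[[3]])])
  res <- if (length(aas) == 1L) aas else "X"
  memo[[codon]] <- res
  res
}

#' Translate a DNA fragment
#'
#' Translates in the given reading frame with the standard genetic code.
#' Codons containing IUPAC ambiguity codes translate to their residue when
#' all disambiguations agree, and to `X` otherwise; stop codons render `*`.
#' Trailing bases that do not fill a codon are dropped.
#'
#' @param sequence Character scalar DNA sequence (IUPAC codes allowed).
#' @param frame Integer 0, 1 or 2: offset of the first codon.
#' @param reverse If `TRUE`, translate the reverse complement.
#' @return Character scalar amino-acid sequence (one-letter codes, `X` for
#'   undetermined, `*` for stop).
#' @examples
#' translate_dna("TTC")           # "F"
#' translate_dna("AGC")           # "S"
#' translate_dna("TCN")           # "S": all disambiguations agree
#' translate_dna("ATN")           # "X": ATA (I) and ATG (M) disagree
#' @export
translate_dna <- function(sequence, frame = 0L, reverse = FALSE) {
  s <- normalize_dna(sequence)
  stopifnot(frame %in% 0:2)
  if (isTRUE(reverse)) s <- reverse_complement(s)
  s <- substr(s, frame + 1L, nchar(s))
  n_codons <- nchar(s) %/% 3L
  if (n_codons < 1L) {
    stop("fragment shorter than one codon after frame offset: nothing to translate")
  }
  starts <- 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- substring(s, starts, starts + 2L)
  paste(vapply(codons, .translate_codon, character(1)), collapse = "")
}

#' Codons of a reading frame
#'
#' Splits an oriented in-frame sequence into its codons.
#'
#' @param sequence DNA sequence.
#' @param frame Frame offset (0, 1, 2).
#' @param reverse Use the reverse complement first.
#' @return Character vector of 3-base codons.
#' @export
frame_codons <- function(sequence, frame = 0L, reverse = FALSE) {
  s <- normalize_dna(sequence)
  if (isTRUE(reverse)) s <- reverse_complement(s)
  s <- substr(s, frame + 1L, nchar(s))
  n_codons <- nchar(s) %/% 3L
  if (n_codons < 1L) return(character(0))
  starts <- 3L * (seq_len(n_codons) - 1L) + 1L
  substring(s, starts, starts + 2L)
}
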