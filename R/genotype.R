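# Tuning-site genotypes: residues (and optionally codons) at sites 86, 90
# and 93, the unit of spectral classification.

.tuning_sites <- c(86L, 90L, 93L)

#' Extract the tuning-site genotype from a window
#'
#' Reads the residues at bovine rhodopsin sites 86, 90 and 93. When the
#' window came from DNA, per-site codons can be attached; each codon must
#' translate to its residue.
#'
#' @param window An [aa_window()] covering sites 86, 90 and 93.
#' @param codons Optional: either a character vector of in-frame codons for
#'   the whole window (as returned by [select_frame()]) or a named vector
#'   with elements `"86"`, `"90"`, `"93"`.
#' @return A `tuning_genotype` object with fields `res86`, `res90`, `res93`
#'   and (possibly `NA`) `codon86`, `codon90`, `codon93`.
#' @examples
#' extract_genotype(aa_window("FIFCVFCVFMV", 84))  # ostrich-type: F, C, M
#' @export
extract_genotype <- function(window, codons = NULL) {
  stopifnot(inherits(window, "aa_window"))
  sites <- window_sites(window)
  missing_sites <- setdiff(.tuning_sites, sites)
  if (length(missing_sites) > 0L) {
    stop("window does not cover tuning site(s): ",
         paste(missing_sites, collapse = ", "))
  }
  res <- vapply(.tuning_sites, function(s) residue_at(window, s), character(1))
  cod <- rep(NA_character_, 3L)
  if (!is.null(codons)) {
    if (!is.null(names(codons))) {
      cod <- unname(codons[as.character(.tuning_sites)])
    } else {
      # positional codons for the whole window
      if (length(codons) != nchar(window$residues)) {
        stop("positional codons must match the window length")
      }
      cod <- codons[.tuning_sites - window$start_site + 1L]
    }
    for (i in seq_along(.tuning_sites)) {
      if (is.na(cod[i])) next
      tr <- .translate_codon(normalize_dna(cod[i]))
      if (tr != res[i]) {
        stop(sprintf("codon %s at site %d translates to %s, not %s",
                     cod[i], .tuning_sites[i], tr, res[i]))
      }
    }
  }
  structure(
    list(res86 = res[1], res90 = res[2], res93 = res[3],
         codon86 = cod[1], codon90 = cod[2], codon93 = cod[3]),
    class = "tuning_genotype"
  )
}

#' Construct a tuning-site genotype directly
#' @param res86,res90,res93 One-letter residues (or `X`).
#' @param codon86,codon90,codon93 Optional codons; each must translate to
#'   its residue.
#' @return A `tuning_genotype`.
#' @export
tuning_genotype <- function(res86, res90, res93,
                            codon86 = NA, codon90 = NA, codon93 = NA) {
  res <- toupper(c(res86, res90, res93))
  stopifnot(all(res %in% .aa_alphabet()))
  cod <- as.character(c(codon86, codon90, codon93))
  for (i in 1:3) {
    if (!is.na(cod[i])) {
      cod[i] <- normalize_dna(cod[i])
      tr <- .translate_codon(cod[i])
      if (tr != res[i]) {
        stop(sprintf("codon %s translates to %s, not %s", cod[i], tr, res[i]))
      }
    }
  }
  structure(
    list(res86 = res[1], res90 = res[2], res93 = res[3],
         codon86 = cod[1], codon90 = cod[2], codon93 = cod[3]),
    class = "tuning_genotype"
  )
}

#' @export
print.tuning_genotype <- function(x, ...) {
  cods <- c(x$codon86, x$codon90, x$codon93)
  cods <- ifelse(is.na(cods), "", paste0(" (", cods, ")"))
  cat(sprintf("<tuning_genotype> 86:%s%s 90:%s%s 93:%s%s\n",
              x$res86, cods[1], x$res90, cods[2], x$res93, cods[3]))
  invisible(x)
}

#' Substitution notation
#'
#' Standard notation: original residue, site number, replacement residue,
#' e.g. `S90C`.
#'
#' @param site Site number.
#' @param aa_from,aa_to Differing residues.
#' @return Character scalar label.
#' @examples
#' substitution_label(90, "S", "C")  # "S90C"
#' @export
substitution_label <- function(site, aa_from, aa_to) {
  aa_from <- toupper(aa_from); aa_to <- toupper(aa_to)
  stopifnot(aa_from %in% .aa_alphabet(), aa_to %in% .aa_alphabet())
  if (aa_from == aa_to) stop("no substitution: residues are identical")
  sprintf("%s%d%s", aa_from, as.integer(site), aa_to)
}
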