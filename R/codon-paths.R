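# Minimal-nucleotide-substitution analysis between codons and amino acids.
# Distances are unweighted base differences; the single-step neighborhood
# of a codon and all orderings of a minimal substitution path are exposed
# so the residues visited by multi-step paths can be inspected.

.check_codon <- function(x, arg = "codon") {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  if (nchar(x) != 3L || !all(strsplit(x, "")[[1]] %in% c("A", "C", "G", "T"))) {
    stop(arg, " must be 3 unambiguous bases (A/C/G/T): got '", x, "'")
  }
  x
}

.stop_codons <- c("TAA", "TAG", "TGA")

#' Number of differing positions between two codons
#'
#' @param a,b Codons (3 unambiguous bases).
#' @return Integer in 0..3.
#' @examples
#' codon_distance("AGC", "TGC")  # 1
#' codon_distance("TCC", "ATG")  # 3
#' @export
codon_distance <- function(a, b) {
  a <- .check_codon(a, "a"); b <- .check_codon(b, "b")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Codons encoding a residue
#' @param aa One-letter residue (or `*` for stop).
#' @return Character vector of codons, alphabetical.
#' @export
codons_for <- function(aa) {
  aa <- toupper(aa)
  gc_tab <- Biostrings::GENETIC_CODE
  out <- sort(names(gc_tab)[gc_tab == aa])
  if (length(out) == 0L) stop("no codons encode '", aa, "'")
  out
}

#' Minimum nucleotide substitutions between two amino acids
#'
#' The minimum codon distance over all codon pairs encoding the two
#' residues; with `codon_from` fixed, the minimum over target codons only.
#'
#' @param aa_from,aa_to Residues from the 20-letter alphabet.
#' @param codon_from Optional source codon, fixed.
#' @return Integer in 0..3.
#' @examples
#' min_aa_substitutions("S", "C")                    # 1
#' min_aa_substitutions("S", "F", codon_from = "TCC") # 1 (TCC -> TTC)
#' @export
min_aa_substitutions <- function(aa_from, aa_to, codon_from = NULL) {
  std <- setdiff(.aa_alphabet(), c("X", "*"))
  aa_from <- toupper(aa_from); aa_to <- toupper(aa_to)
  if (!(aa_from %in% std) || !(aa_to %in% std)) {
    stop("residues must be from the 20-letter alphabet (stop rejected)")
  }
  from_codons <- if (is.null(codon_from)) codons_for(aa_from) else {
    cf <- .check_codon(codon_from, "codon_from")
    if (.translate_codon(cf) != aa_from) {
      stop("codon_from ", cf, " does not encode ", aa_from)
    }
    cf
  }
  to_codons <- codons_for(aa_to)
  min(vapply(from_codons, function(a) {
    min(vapply(to_codons, function(b) codon_distance(a, b), integer(1)))
  }, integer(1)))
}

#' All minimal substitution paths between two codons
#'
#' Enumerates every ordering of the differing positions as a path of
#' single-base steps, reporting the codon and translated residue after
#' each step. With `forbid_stops = TRUE`, paths passing through a stop
#' codon (TAA/TAG/TGA) are excluded. Paths are returned in deterministic
#' order (lexicographic by the sequence of step positions).
#'
#' @param a,b Source and target codons.
#' @param forbid_stops Exclude paths through stop codons (default off).
#' @return List of paths; each path is a data.frame with columns `step`,
#'   `site` (codon position 1-3), `from_base`, `to_base`, `codon`,
#'   `residue`. For identical codons a single empty path is returned.
#' @examples
#' length(enumerate_minimal_paths("AGC", "TGC"))  # 1
#' length(enumerate_minimal_paths("TCC", "ATG"))  # 6
#' @export
enumerate_minimal_paths <- function(a, b, forbid_stops = FALSE) {
  a <- .check_codon(a, "a"); b <- .check_codon(b, "b")
  ab <- strsplit(a, "")[[1]]; bb <- strsplit(b, "")[[1]]
  diff_pos <- which(ab != bb)
  if (length(diff_pos) == 0L) {
    empty <- data.frame(step = integer(0), site = integer(0),
                        from_base = character(0), to_base = character(0),
                        codon = character(0), residue = character(0),
                        stringsAsFactors = FALSE)
    return(list(empty))
  }
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  orders <- perms(diff_pos)
  # lexicographic by step-position sequence
  key <- vapply(orders, paste, character(1), collapse = ",")
  orders <- orders[order(key)]
  paths <- list()
  for (ord in orders) {
    cur <- ab
    steps <- vector("list", length(ord))
    ok <- TRUE
    for (k in seq_along(ord)) {
      p <- ord[k]
      from_base <- cur[p]
      cur[p] <- bb[p]
      codon <- paste(cur, collapse = "")
      if (forbid_stops && k < length(ord) && codon %in% .stop_codons) {
        ok <- FALSE
        break
      }
      steps[[k]] <- data.frame(
        step = k, site = p, from_base = from_base, to_base = bb[p],
        codon = codon, residue = Biostrings::GENETIC_CODE[[codon]],
        stringsAsFactors = FALSE
      )
    }
    if (ok) paths[[length(paths) + 1L]] <- do.call(rbind, steps)
  }
  paths
}

#' Single-base neighbors of a codon
#'
#' The 9 codons at Hamming distance 1, with their translations and a stop
#' flag.
#'
#' @param a A codon.
#' @return Data.frame with columns `codon`, `residue`, `is_stop`; 9 rows.
#' @export
single_step_neighbors <- function(a) {
  a <- .check_codon(a, "a")
  ab <- strsplit(a, "")[[1]]
  rows <- list()
  for (p in 1:3) {
    for (base in setdiff(c("A", "C", "G", "T"), ab[p])) {
      nb <- ab; nb[p] <- base
      codon <- paste(nb, collapse = "")
      rows[[length(rows) + 1L]] <- data.frame(
        codon = codon, residue = Biostrings::GENETIC_CODE[[codon]],
        is_stop = codon %in% .stop_codons, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
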