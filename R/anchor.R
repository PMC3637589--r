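# Reading-frame selection by ungapped anchoring to a reference window.
# The amplicon is a short exonic fragment with no indels, so anchoring is a
# sliding ungapped comparison of each of the six frame/strand translations
# against a reference amino-acid window with known site numbering.

#' Reference anchor for the SWS1 tuning-site region
#'
#' A reference amino-acid window with known bovine rhodopsin numbering used
#' to orient and number short fragments. The default is the modal residue
#' per site over the neognath rows of the packaged survey dataset, covering
#' sites 84-94 (`FISCIFSVFTV`).
#'
#' @param reference_window Amino-acid sequence of the anchor.
#' @param site_of_first_residue Bovine rhodopsin site of its first residue.
#' @return A `reference_anchor` object.
#' @export
reference_anchor <- function(reference_window = "FISCIFSVFTV",
                             site_of_first_residue = 84L) {
  w <- aa_window(reference_window, site_of_first_residue)
  sites <- window_sites(w)
  if (!all(84:94 %in% sites)) {
    stop("anchor must cover sites 84-94 at minimum")
  }
  structure(list(window = w), class = "reference_anchor")
}

#' @export
print.reference_anchor <- function(x, ...) {
  cat("<reference_anchor>\n")
  print(x$window)
  invisible(x)
}

#' Default anchor window
#'
#' Modal residue per site across the neognath rows of the packaged survey
#' dataset, sites 84-94.
#' @return A `reference_anchor`.
#' @export
default_anchor <- function() reference_anchor()

# Best ungapped placement of the anchor inside one translation.
# Returns identity (matched sites), the translation position aligned to the
# anchor start, and whether a stop codon falls inside the overlap.
.best_anchor_placement <- function(translation, anchor_res) {
  tr <- strsplit(translation, "")[[1]]
  an <- strsplit(anchor_res, "")[[1]]
  nt <- length(tr); na <- length(an)
  best <- list(identity = -1L, pos = NA_integer_, stop_inside = FALSE)
  # offset: translation index of anchor position 1 (may be outside [1, nt])
  for (pos in (1L - na + 1L):nt) {
    idx_a <- seq_len(na)
    idx_t <- pos + idx_a - 1L
    keep <- idx_t >= 1L & idx_t <= nt
    if (!any(keep)) next
    ta <- tr[idx_t[keep]]
    aa <- an[idx_a[keep]]
    ident <- sum(ta == aa & ta != "X")
    stop_inside <- any(ta == "*")
    if (ident > best$identity) {
      best <- list(identity = ident, pos = pos, stop_inside = stop_inside)
    }
  }
  best
}

#' Select reading frame and strand by anchoring
#'
#' Translates the fragment in all six frame/strand combinations and picks
#' the one whose translation has the highest ungapped identity to the
#' anchor. A stop codon inside the anchored region invalidates a candidate
#' regardless of its identity.
#'
#' @param sequence DNA fragment (IUPAC codes allowed).
#' @param anchor A [reference_anchor()].
#' @param min_identity Minimum number of anchor sites that must match
#'   (default 5 of the 11 anchor sites).
#' @return A list with elements `frame` (0-2), `reverse` (logical),
#'   `window` (an [aa_window()] for the full translation, with absolute
#'   site numbering), `identity`, and `codons` (the in-frame codons of the
#'   oriented sequence, aligned to the window).
#' @examples
#' dna <- "TTCATCTCCTGTATCTTCAGCGTCTTCACCGTC"  # encodes FISCIFSVFTV
#' sf <- select_frame(dna)
#' sf$frame; sf$window
#' @export
select_frame <- function(sequence, anchor = default_anchor(), min_identity = 5L) {
  s <- normalize_dna(sequence)
  anchor_res <- anchor$window$residues
  anchor_start <- anchor$window$start_site
  candidates <- list()
  for (reverse in c(FALSE, TRUE)) {
    for (frame in 0:2) {
      tr <- tryCatch(translate_dna(s, frame, reverse), error = function(e) NULL)
      if (is.null(tr)) next
      placement <- .best_anchor_placement(tr, anchor_res)
      if (placement$stop_inside) next
      if (placement$identity < min_identity) next
      candidates[[length(candidates) + 1L]] <- list(
        frame = frame, reverse = reverse, translation = tr,
        identity = placement$identity, pos = placement$pos
      )
    }
  }
  if (length(candidates) == 0L) {
    stop("no-anchor: no frame/strand reaches identity ", min_identity,
         " to the anchor without an internal stop codon")
  }
  idents <- vapply(candidates, `[[`, integer(1), "identity")
  best <- which(idents == max(idents))
  if (length(best) > 1L) {
    desc <- vapply(candidates[best], function(cc) {
      sprintf("frame=%d %s (identity %d)", cc$frame,
              if (cc$reverse) "reverse" else "forward", cc$identity)
    }, character(1))
    stop("ambiguous anchoring, candidates tie: ", paste(desc, collapse = "; "))
  }
  hit <- candidates[[best]]
  # translation position `pos` carries anchor site `anchor_start`
  start_site <- anchor_start - (hit$pos - 1L)
  window <- aa_window(hit$translation, start_site)
  list(
    frame = hit$frame,
    reverse = hit$reverse,
    window = window,
    identity = hit$identity,
    codons = frame_codons(s, hit$frame, hit$reverse)
  )
}
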