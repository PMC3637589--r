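# Amino-acid windows addressed in bovine rhodopsin site numbering.
# A window stores absolute site numbers, never fragment-relative offsets,
# so the spectral tuning sites 86, 90 and 93 can be read directly.

.aa_alphabet <- function() c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "*")

#' Construct an amino-acid window
#'
#' @param residues Character scalar of one-letter amino-acid codes (`X`
#'   allowed for unknown residues).
#' @param start_site Bovine rhodopsin site number of the first residue
#'   (1-based; the packaged survey windows start at site 84).
#' @return An `aa_window` object.
#' @examples
#' w <- aa_window("FISCIFSVFTV", 84)
#' residue_at(w, 90)
#' @export
aa_window <- function(residues, start_site) {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  if (nchar(residues) == 0L) stop("empty residue string")
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), .aa_alphabet())
  if (length(bad) > 0L) stop("invalid residue codes: ", paste(bad, collapse = ", "))
  start_site <- as.integer(start_site)
  if (is.na(start_site) || start_site < 1L) stop("start_site must be a positive integer")
  structure(
    list(residues = residues, start_site = start_site),
    class = "aa_window"
  )
}

#' @export
print.aa_window <- function(x, ...) {
  cat(sprintf(
    "<aa_window> sites %d-%d: %s\n",
    x$start_site, x$start_site + nchar(x$residues) - 1L, x$residues
  ))
  invisible(x)
}

#' Sites covered by a window
#' @param window An `aa_window`.
#' @return Integer vector of bovine rhodopsin site numbers.
#' @export
window_sites <- function(window) {
  stopifnot(inherits(window, "aa_window"))
  window$start_site + seq_len(nchar(window$residues)) - 1L
}

#' Residue at an absolute site
#' @param window An `aa_window`.
#' @param site Bovine rhodopsin site number.
#' @return One-letter residue code.
#' @export
residue_at <- function(window, site) {
  stopifnot(inherits(window, "aa_window"))
  pos <- site - window$start_site + 1L
  if (pos < 1L || pos > nchar(window$residues)) {
    stop(sprintf("window [%d-%d] does not cover site %d",
                 window$start_site, window$start_site + nchar(window$residues) - 1L, site))
  }
  substr(window$residues, pos, pos)
}

#' Hamming distance between two aligned windows
#'
#' Counts positions with differing residues. Both windows must cover the
#' same sites (equal length and `start_site`). Positions where either
#' residue is `X` are, under the default policy, excluded from the
#' comparison; the number of compared and excluded positions is attached
#' as attributes.
#'
#' @param a,b `aa_window` objects on the same sites.
#' @param x_policy `"exclude"` (default) drops positions with an `X` in
#'   either window; `"mismatch"` counts `X` against any residue as a
#'   difference.
#' @return Integer distance, with attributes `compared` and `excluded`.
#' @examples
#' w1 <- aa_window("FISCILSVFVV", 84)  # rock ptarmigan survey window
#' w2 <- aa_window("FIACIFSVFTV", 84)  # spotted sandpiper survey window
#' window_hamming(w1, w2)              # 3
#' @export
window_hamming <- function(a, b, x_policy = c("exclude", "mismatch")) {
  x_policy <- match.arg(x_policy)
  stopifnot(inherits(a, "aa_window"), inherits(b, "aa_window"))
  if (nchar(a$residues) != nchar(b$residues) || a$start_site != b$start_site) {
    stop("alignment mismatch: windows must have equal length and start_site")
  }
  ra <- strsplit(a$residues, "")[[1]]
  rb <- strsplit(b$residues, "")[[1]]
  has_x <- ra == "X" | rb == "X"
  if (x_policy == "exclude") {
    cmp <- !has_x
    d <- sum(ra[cmp] != rb[cmp])
    excluded <- sum(has_x)
  } else {
    d <- sum(ra != rb | has_x)
    # X vs X counts as a mismatch too under this policy
    cmp <- rep(TRUE, length(ra))
    excluded <- 0L
  }
  structure(as.integer(d), compared = sum(cmp), excluded = as.integer(excluded))
}
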