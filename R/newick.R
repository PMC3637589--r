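# Newick parsing and writing (ape-backed) plus an annotated writer that
# tags branches carrying reconstructed events with bracket comments.

#' Parse a Newick tree
#'
#' Accepts a Newick string or a file path. Bracket comments (`[...]`) are
#' stripped before parsing, so annotated output from
#' [write_annotated_newick()] round-trips.
#'
#' @param x Newick string (must end in `;`) or path to a file.
#' @return A rooted `phylo` object.
#' @export
parse_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  text <- if (file.exists(x) && !grepl(";", x, fixed = TRUE)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else x
  text <- gsub("\\[[^]]*\\]", "", text)
  if (!grepl(";", text, fixed = TRUE)) {
    stop("not a Newick description (no ';' found): ", substr(x, 1, 40))
  }
  # basic structural check with a useful position on failure
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) stop("unbalanced parentheses at character ", i)
  }
  if (depth != 0L) stop("unbalanced parentheses: ", depth, " '(' unclosed")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) stop("Newick parse error: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse error: no tree read")
  .check_phylo(tree)
}

#' Write a tree as Newick
#' @param tree A `phylo` object.
#' @param path Optional output path; when `NULL` the string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  .check_phylo(tree)
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Write a Newick tree annotated with reconstructed events
#'
#' Branches carrying events of the representative MPR are tagged with a
#' bracket comment after the child element, e.g. `Larus[&shift=S90C]`.
#' The output is accepted by [parse_newick()] (comments are stripped).
#'
#' @param recon A [reconstruct_shifts()] result.
#' @param path Optional output path.
#' @return The annotated Newick string, invisibly when written.
#' @export
write_annotated_newick <- function(recon, path = NULL) {
  stopifnot(inherits(recon, "shift_recon"))
  tree <- recon$tree
  ev <- recon$representative_events
  tag <- stats::setNames(ev$label, ev$child)
  n <- length(tree$tip.label)
  children_of <- split(tree$edge[, 2L], tree$edge[, 1L])
  build <- function(id) {
    name <- .node_name(tree, id)
    base <- if (id <= n) {
      name
    } else {
      kids <- children_of[[as.character(id)]]
      inner <- paste(vapply(kids, build, character(1)), collapse = ",")
      lbl <- if (!is.null(tree$node.label)) {
        l <- tree$node.label[id - n]
        if (is.na(l)) "" else l
      } else ""
      paste0("(", inner, ")", lbl)
    }
    if (name %in% names(tag)) {
      base <- paste0(base, "[&shift=", tag[[name]], "]")
    }
    base
  }
  s <- paste0(build(n + 1L), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}
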