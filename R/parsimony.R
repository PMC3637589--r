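# Parsimony reconstruction of tuning-site characters and UVS/VS phenotype
# on a rooted tree.
#
# The engine is the unit-cost dynamic programme over unordered states
# (Sankoff recursion with a 0/1 cost matrix), which coincides with Fitch
# parsimony on binary trees and generalizes it exactly to multifurcating
# trees. On top of the minimum change count it computes, exactly:
#   * the set of root states attainable in at least one most-parsimonious
#     reconstruction (MPR),
#   * per-node MPR state sets,
#   * the minimum and maximum number of events of each labelled type over
#     ALL MPRs (per-type DP, cross-validated against exhaustive MPR
#     enumeration on small trees),
#   * one representative MPR with branch-localized events.

.INF <- 1e9

.check_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "))
  }
  tree
}

# Drop tips without states (warning); error when fewer than 2 remain.
.prune_to_states <- function(tree, states) {
  .check_phylo(tree)
  states <- states[!is.na(states)]
  mapped <- intersect(tree$tip.label, names(states))
  if (length(mapped) == 0L) stop("no tip has a state: nothing to reconstruct")
  dropped <- setdiff(tree$tip.label, mapped)
  if (length(dropped) > 0L) {
    warning("dropping ", length(dropped), " tip(s) without states: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
    tree <- ape::keep.tip(tree, mapped)
  }
  if (length(tree$tip.label) < 2L) stop("need at least 2 mapped tips")
  list(tree = tree, states = states[tree$tip.label], dropped = dropped)
}

.node_name <- function(tree, id) {
  n <- length(tree$tip.label)
  if (id <= n) return(tree$tip.label[id])
  if (!is.null(tree$node.label)) {
    lbl <- tree$node.label[id - n]
    if (!is.na(lbl) && nzchar(lbl)) return(lbl)
  }
  paste0("node", id)
}

# Downpass cost matrix: cost[v, s] = min changes in the subtree of v given
# state s at v. Postorder over the edge matrix handles polytomies natively.
.sankoff_down <- function(tree, states, alphabet) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  k <- length(alphabet)
  cost <- matrix(0, n + m, k, dimnames = list(NULL, alphabet))
  for (i in seq_len(n)) {
    cost[i, ] <- ifelse(alphabet == states[[tree$tip.label[i]]], 0, .INF)
  }
  eo <- stats::reorder(tree, "postorder")$edge
  for (r in seq_len(nrow(eo))) {
    ch <- eo[r, 2L]
    cost[eo[r, 1L], ] <- cost[eo[r, 1L], ] +
      pmin(cost[ch, ], min(cost[ch, ]) + 1)
  }
  cost
}

# MPR-feasible state sets per node (logical matrix), given the downpass
# cost matrix. A state is feasible at a node when some MPR assigns it.
.mpr_feasible <- function(tree, cost) {
  n <- length(tree$tip.label)
  root <- n + 1L
  k <- ncol(cost)
  feasible <- matrix(FALSE, nrow(cost), k, dimnames = dimnames(cost))
  feasible[root, ] <- cost[root, ] == min(cost[root, ])
  eo <- stats::reorder(tree, "postorder")$edge
  for (r in rev(seq_len(nrow(eo)))) {       # preorder
    par <- eo[r, 1L]; ch <- eo[r, 2L]
    chmin <- min(cost[ch, ])
    for (s in which(feasible[par, ])) {
      best <- min(cost[ch, s], chmin + 1)
      feasible[ch, ] <- feasible[ch, ] |
        (cost[ch, ] + as.numeric(seq_len(k) != s)) == best
    }
  }
  feasible
}

#' Generalized Fitch parsimony count
#'
#' Exact minimum number of unordered state changes for one character on a
#' rooted, possibly multifurcating tree, with per-node state sets. Tips
#' with missing states are dropped with a warning.
#'
#' @param tree Rooted `phylo` tree.
#' @param states Named character vector: tip label -> state.
#' @return List with `min_changes`, `root_state_set` (states attainable at
#'   the root in at least one MPR), `mpr_sets` (list, per node, of MPR
#'   state sets), `alphabet`, `tree` (possibly pruned), `states` and
#'   `dropped_tips`.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' fitch_count(tr, c(A = "UVS", B = "UVS", C = "VS", D = "VS"))$min_changes
#' @export
fitch_count <- function(tree, states) {
  pr <- .prune_to_states(tree, states)
  tree <- pr$tree; states <- pr$states
  alphabet <- sort(unique(unname(states)))
  cost <- .sankoff_down(tree, states, alphabet)
  root <- length(tree$tip.label) + 1L
  feas <- .mpr_feasible(tree, cost)
  mpr_sets <- lapply(seq_len(nrow(feas)), function(i) alphabet[feas[i, ]])
  names(mpr_sets) <- vapply(seq_len(nrow(feas)), function(i) .node_name(tree, i),
                            character(1))
  list(
    min_changes = as.integer(min(cost[root, ])),
    root_state_set = alphabet[cost[root, ] == min(cost[root, ])],
    mpr_sets = mpr_sets,
    alphabet = alphabet,
    tree = tree,
    states = states,
    dropped_tips = pr$dropped
  )
}

#' Root states attainable across all MPRs
#' @inheritParams fitch_count
#' @return Character vector of states.
#' @export
root_state_set <- function(tree, states) {
  fitch_count(tree, states)$root_state_set
}

#' Exhaustive-minimum oracle for small trees
#'
#' Minimum change count by enumerating every assignment of states to
#' internal nodes. Independent of the dynamic programme; intended as a
#' test oracle. Refuses trees with more than `max_internal` internal
#' nodes.
#'
#' @inheritParams fitch_count
#' @param max_internal Size cap (default 12).
#' @return Integer minimum number of changes.
#' @export
brute_force_min_changes <- function(tree, states, max_internal = 12L) {
  pr <- .prune_to_states(tree, states)
  tree <- pr$tree; states <- pr$states
  n <- length(tree$tip.label)
  m <- tree$Nnode
  if (m > max_internal) stop("too many internal nodes (", m, ") for brute force")
  alphabet <- sort(unique(unname(states)))
  k <- length(alphabet)
  edge <- tree$edge
  tip_state <- match(states[tree$tip.label], alphabet)
  combo <- rep(1L, m)
  best <- Inf
  repeat {
    assign_all <- c(tip_state, combo)
    changes <- sum(assign_all[edge[, 1L]] != assign_all[edge[, 2L]])
    if (changes < best) best <- changes
    # next combination in base-k counting
    i <- 1L
    while (i <= m) {
      combo[i] <- combo[i] + 1L
      if (combo[i] <= k) break
      combo[i] <- 1L
      i <- i + 1L
    }
    if (i > m) break
  }
  as.integer(best)
}

#' Enumerate all most-parsimonious reconstructions
#'
#' Every assignment of internal-node states achieving the minimum change
#' count. The candidate space is the product of per-node MPR state sets;
#' enumeration refuses when that product exceeds `limit`.
#'
#' @inheritParams fitch_count
#' @param limit Maximum number of candidate assignments (default 50000).
#' @return List with `assignments` (matrix, one row per MPR, columns =
#'   internal node ids) and `min_changes`.
#' @export
enumerate_mprs <- function(tree, states, limit = 50000L) {
  fc <- fitch_count(tree, states)
  tree <- fc$tree; states <- fc$states
  n <- length(tree$tip.label)
  m <- tree$Nnode
  sets <- fc$mpr_sets[(n + 1L):(n + m)]
  sizes <- lengths(sets)
  if (prod(sizes) > limit) {
    stop("MPR candidate space too large to enumerate: ", prod(sizes))
  }
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  edge <- tree$edge
  tip_state <- unname(states[tree$tip.label])
  keep <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    assign_all <- c(tip_state, as.character(unlist(grid[i, ], use.names = FALSE)))
    keep[i] <- sum(assign_all[edge[, 1L]] != assign_all[edge[, 2L]]) ==
      fc$min_changes
  }
  out <- as.matrix(grid[keep, , drop = FALSE])
  colnames(out) <- names(sets)
  rownames(out) <- NULL
  list(assignments = out, min_changes = fc$min_changes)
}

# ---- event labelers ---------------------------------------------------

#' Event labeler for residue characters
#'
#' Produces substitution notation such as `S90C` for changes of a
#' residue-valued character at a given site.
#' @param site Site number used in the labels.
#' @return Function `(from, to) -> label`.
#' @export
labeler_substitutions <- function(site) {
  force(site)
  function(from, to) substitution_label(site, from, to)
}

#' Event labeler for the UVS/VS route coding
#'
#' For characters over `{VS, UVS_C90, UVS_F86}` (or binary `{VS, UVS}`):
#' transitions into a UVS state are labelled with the causal substitution
#' (`S90C` for the C90 route, `S86F` for the F86 route, `UV-gain` for the
#' binary coding) and transitions back are `C90S` / `F86S` / `UV-loss`.
#' @return Function `(from, to) -> label`.
#' @export
labeler_uv_route <- function() {
  function(from, to) {
    key <- paste(from, to, sep = "->")
    switch(key,
           "VS->UVS_C90" = "S90C", "UVS_C90->VS" = "C90S",
           "VS->UVS_F86" = "S86F", "UVS_F86->VS" = "F86S",
           "VS->UVS" = "UV-gain", "UVS->VS" = "UV-loss",
           "other")
  }
}

.direction_of_label <- function(label) {
  if (label %in% c("S90C", "S86F", "UV-gain")) "UV-gain"
  else if (label %in% c("C90S", "F86S", "UV-loss")) "UV-loss"
  else "other"
}

# ---- event counting over all MPRs -------------------------------------

# Per-label DP: for each node v and state s, the min/max count of events
# with a given label among subtree assignments that are optimal given
# state s at v. Children contribute independently; an MPR is exactly a
# choice, for each child, of a state minimizing cost + edge mismatch.
.event_ranges_dp <- function(tree, cost, labeler, alphabet) {
  n <- length(tree$tip.label)
  root <- n + 1L
  k <- length(alphabet)
  nn <- nrow(cost)
  label_mat <- matrix(NA_character_, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) label_mat[i, j] <- labeler(alphabet[i], alphabet[j])
  }
  labels <- sort(unique(stats::na.omit(as.vector(label_mat))))
  nl <- length(labels)
  emin <- array(0, dim = c(nn, k, nl))
  emax <- array(0, dim = c(nn, k, nl))
  eo <- stats::reorder(tree, "postorder")$edge
  for (r in seq_len(nrow(eo))) {
    par <- eo[r, 1L]; ch <- eo[r, 2L]
    chmin <- min(cost[ch, ])
    for (s in seq_len(k)) {
      if (cost[par, s] >= .INF) next
      best <- min(cost[ch, s], chmin + 1)
      opt_t <- which((cost[ch, ] + as.numeric(seq_len(k) != s)) == best)
      for (l in seq_len(nl)) {
        inc <- vapply(opt_t, function(t) {
          ev <- if (t != s && identical(label_mat[s, t], labels[l])) 1 else 0
          c(ev + emin[ch, t, l], ev + emax[ch, t, l])
        }, numeric(2))
        emin[par, s, l] <- emin[par, s, l] + min(inc[1, ])
        emax[par, s, l] <- emax[par, s, l] + max(inc[2, ])
      }
    }
  }
  opt_root <- which(cost[root, ] == min(cost[root, ]))
  data.frame(
    label = labels,
    min = vapply(seq_len(nl), function(l) min(emin[root, opt_root, l]), numeric(1)),
    max = vapply(seq_len(nl), function(l) max(emax[root, opt_root, l]), numeric(1)),
    stringsAsFactors = FALSE
  )
}

# Representative MPR by deterministic backtracking: root takes the
# alphabetically first optimal state; each child keeps its parent's state
# when optimal, otherwise the alphabetically first optimal state.
.representative_mpr <- function(tree, cost, alphabet) {
  n <- length(tree$tip.label)
  root <- n + 1L
  k <- length(alphabet)
  assign_state <- integer(nrow(cost))
  assign_state[root] <- which(cost[root, ] == min(cost[root, ]))[1L]
  eo <- stats::reorder(tree, "postorder")$edge
  for (r in rev(seq_len(nrow(eo)))) {
    par <- eo[r, 1L]; ch <- eo[r, 2L]
    s <- assign_state[par]
    best <- min(cost[ch, s], min(cost[ch, ]) + 1)
    opt_t <- which((cost[ch, ] + as.numeric(seq_len(k) != s)) == best)
    assign_state[ch] <- if (s %in% opt_t) s else opt_t[1L]
  }
  alphabet[assign_state]
}

.events_of_assignment <- function(tree, node_states, labeler) {
  edge <- tree$edge
  rows <- list()
  for (r in seq_len(nrow(edge))) {
    par <- edge[r, 1L]; ch <- edge[r, 2L]
    if (node_states[par] != node_states[ch]) {
      lbl <- labeler(node_states[par], node_states[ch])
      rows[[length(rows) + 1L]] <- data.frame(
        parent = .node_name(tree, par), child = .node_name(tree, ch),
        from = node_states[par], to = node_states[ch],
        label = lbl, direction = .direction_of_label(lbl),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(parent = character(0), child = character(0),
                      from = character(0), to = character(0),
                      label = character(0), direction = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Reconstruct state shifts on a tree
#'
#' Fits a parsimony reconstruction of one character and summarizes it:
#' minimum change count, root state set, exact `[min, max]` count of each
#' labelled event type over all MPRs, and one representative MPR with its
#' branch-localized events.
#'
#' @param tree Rooted `phylo` tree (polytomies allowed).
#' @param states Named character vector of tip states; tips without states
#'   are dropped with a warning.
#' @param labeler Function `(from, to) -> label` naming event types;
#'   default labels every ordered pair `"from->to"`. See
#'   [labeler_uv_route()] and [labeler_substitutions()].
#' @param character_name Optional name carried in the summary.
#' @param method `"dp"` (default; per-type dynamic programme, exact) or
#'   `"enumerate"` (exhaustive MPR enumeration; refuses large trees). The
#'   two agree; enumeration exists as the cross-validation path.
#' @param enumerate_limit Candidate-space cap for `method = "enumerate"`.
#' @return A `shift_recon` object.
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' st <- c(A = "UVS", B = "UVS", C = "VS", D = "VS")
#' reconstruct_shifts(tr, st)
#' @export
reconstruct_shifts <- function(tree, states, labeler = NULL,
                               character_name = "character",
                               method = c("dp", "enumerate"),
                               enumerate_limit = 50000L) {
  method <- match.arg(method)
  if (is.null(labeler)) labeler <- function(from, to) paste0(from, "->", to)
  fc <- fitch_count(tree, states)
  tree <- fc$tree; states <- fc$states
  alphabet <- fc$alphabet
  cost <- .sankoff_down(tree, states, alphabet)
  if (method == "dp") {
    ranges <- .event_ranges_dp(tree, cost, labeler, alphabet)
  } else {
    en <- enumerate_mprs(tree, states, limit = enumerate_limit)
    tip_state <- unname(states[tree$tip.label])
    # same label universe as the DP: all labels the labeler can produce
    labels <- character(0)
    for (a in alphabet) for (b in alphabet) {
      if (a != b) labels <- c(labels, labeler(a, b))
    }
    labels <- sort(unique(labels))
    counts <- vapply(seq_len(nrow(en$assignments)), function(i) {
      node_states <- c(tip_state, en$assignments[i, ])
      ev <- .events_of_assignment(tree, node_states, labeler)
      cnt <- table(factor(ev$label, levels = labels))
      as.numeric(cnt)
    }, numeric(length(labels)))
    counts <- matrix(counts, nrow = length(labels))
    ranges <- data.frame(label = labels,
                         min = apply(counts, 1, min),
                         max = apply(counts, 1, max),
                         stringsAsFactors = FALSE)
  }
  rep_states <- .representative_mpr(tree, cost, alphabet)
  rep_events <- .events_of_assignment(tree, rep_states, labeler)
  structure(
    list(character_name = character_name,
         min_changes = fc$min_changes,
         root_state_set = fc$root_state_set,
         event_range = ranges,
         representative_events = rep_events,
         n_tips = length(tree$tip.label),
         dropped_tips = fc$dropped_tips,
         alphabet = alphabet,
         method = method,
         tree = tree,
         states = states),
    class = "shift_recon"
  )
}

#' @export
print.shift_recon <- function(x, ...) {
  cat(sprintf("Parsimony reconstruction of '%s' (%d tips, %d states)\n",
              x$character_name, x$n_tips, length(x$alphabet)))
  cat(sprintf("  minimum changes: %d\n", x$min_changes))
  cat(sprintf("  root state set: {%s}\n", paste(x$root_state_set, collapse = ", ")))
  if (nrow(x$event_range) > 0L) {
    cat("  event ranges over all MPRs:\n")
    for (i in seq_len(nrow(x$event_range))) {
      rng <- if (x$event_range$min[i] == x$event_range$max[i]) {
        sprintf("%d", as.integer(x$event_range$min[i]))
      } else {
        sprintf("%d-%d", as.integer(x$event_range$min[i]),
                as.integer(x$event_range$max[i]))
      }
      cat(sprintf("    %-8s %s\n", x$event_range$label[i], rng))
    }
  }
  invisible(x)
}

#' @export
summary.shift_recon <- function(object, ...) {
  gains <- object$event_range$label[vapply(object$event_range$label,
                                           .direction_of_label,
                                           character(1)) == "UV-gain"]
  losses <- object$event_range$label[vapply(object$event_range$label,
                                            .direction_of_label,
                                            character(1)) == "UV-loss"]
  rng_sum <- function(lbls, fun) {
    if (length(lbls) == 0L) return(NA_real_)
    sel <- object$event_range$label %in% lbls
    sum(object$event_range[[fun]][sel])
  }
  out <- list(
    character_name = object$character_name,
    min_changes = object$min_changes,
    root_state_set = object$root_state_set,
    event_range = object$event_range,
    uv_gain_naive_range = c(rng_sum(gains, "min"), rng_sum(gains, "max")),
    uv_loss_naive_range = c(rng_sum(losses, "min"), rng_sum(losses, "max")),
    representative_events = object$representative_events
  )
  class(out) <- "summary.shift_recon"
  out
}

#' @export
print.summary.shift_recon <- function(x, ...) {
  cat(sprintf("Reconstruction summary: '%s'\n", x$character_name))
  cat(sprintf("  minimum changes: %d\n", x$min_changes))
  cat(sprintf("  root state set: {%s}\n", paste(x$root_state_set, collapse = ", ")))
  print(x$event_range, row.names = FALSE)
  cat("Representative MPR events:\n")
  print(x$representative_events, row.names = FALSE)
  invisible(x)
}

#' Aggregate event ranges by direction
#'
#' Exact `[min, max]` over all MPRs of the total number of UV-gain and
#' UV-loss events (recomputed by a direction-level DP, not by summing
#' per-label ranges, so the bounds are jointly attainable).
#'
#' @param tree,states,labeler As in [reconstruct_shifts()].
#' @return Data.frame with rows `UV-gain` and `UV-loss`.
#' @export
direction_ranges <- function(tree, states, labeler = labeler_uv_route()) {
  dir_labeler <- function(from, to) .direction_of_label(labeler(from, to))
  reconstruct_shifts(tree, states, labeler = dir_labeler,
                     character_name = "direction")$event_range
}
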