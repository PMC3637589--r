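# Seeded simulator: evolves the tuning-site codon region down a tree with
# planted codon substitutions on chosen branches, wraps the coding region
# in random flanks and optional per-base noise, and reports the per-tip
# truth. Used to validate the whole pipeline (translate -> anchor ->
# classify -> reconstruct) without external data.

# default residues of the simulated coding region, sites 81-94; the
# tuning sites 86/90/93 are overridden by the root genotype
.sim_region_residues <- function() {
  stats::setNames(strsplit("TLYFISCIFSVFTV", "")[[1]], 81:94)
}

.pick_codon <- function(aa) codons_for(aa)[1L]

#' Specify a tuning-site simulation
#'
#' @param tree Rooted `phylo` tree with unique tip labels.
#' @param root_codons Codons at sites 86/90/93 at the root (named or
#'   positional, translated to the root genotype). Default `TCC`/`AGC`/
#'   `ACC`: the S86+S90 violet-type ancestral neognath genotype with the
#'   modal threonine at 93.
#' @param events Data.frame of planted substitutions with columns `child`
#'   (tip or internal node label identifying the branch above it), `site`
#'   (86, 90 or 93), `from_codon`, `to_codon`.
#' @param flank5,flank3 Lengths of random flanking sequence (bases).
#' @param noise Per-base substitution probability in [0, 1].
#' @param ambiguity Per-base probability of masking to `N`.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A `sim_spec` object.
#' @export
simulation_spec <- function(tree,
                            root_codons = c(`86` = "TCC", `90` = "AGC",
                                            `93` = "ACC"),
                            events = NULL,
                            flank5 = 30L, flank3 = 30L,
                            noise = 0, ambiguity = 0, seed = 1L) {
  .check_phylo(tree)
  root_codons <- vapply(unname(root_codons), .check_codon, character(1))
  stopifnot(length(root_codons) == 3L)
  if (is.null(events)) {
    events <- data.frame(child = character(0), site = integer(0),
                         from_codon = character(0), to_codon = character(0),
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("child", "site", "from_codon", "to_codon") %in% names(events)))
  if (nrow(events) > 0L) {
    known <- c(tree$tip.label,
               if (!is.null(tree$node.label)) tree$node.label)
    bad <- setdiff(events$child, known)
    if (length(bad) > 0L) {
      stop("planted events reference unknown branches (child labels): ",
           paste(bad, collapse = ", "))
    }
    stopifnot(all(events$site %in% c(86L, 90L, 93L)))
  }
  stopifnot(noise >= 0, noise <= 1, ambiguity >= 0, ambiguity <= 1,
            flank5 >= 0, flank3 >= 0)
  structure(
    list(tree = tree, root_codons = root_codons, events = events,
         flank5 = as.integer(flank5), flank3 = as.integer(flank3),
         noise = noise, ambiguity = ambiguity, seed = as.integer(seed)),
    class = "sim_spec"
  )
}

# node id for a tip or internal label
.node_id_by_label <- function(tree, label) {
  n <- length(tree$tip.label)
  i <- match(label, tree$tip.label)
  if (!is.na(i)) return(i)
  if (!is.null(tree$node.label)) {
    j <- match(label, tree$node.label)
    if (!is.na(j)) return(n + j)
  }
  stop("no node labelled '", label, "'")
}

#' Run a tuning-site simulation
#'
#' Propagates the site 81-94 codon region from the root down the tree,
#' applying planted codon substitutions on their branches; each tip is
#' then wrapped in seeded random flanks and (optionally) per-base noise
#' and `N`-masking. An event whose `from_codon` does not match the codon
#' inherited at its branch is a planting error.
#'
#' @param spec A [simulation_spec()].
#' @return List with `fragments` (named character vector of tip DNA
#'   sequences), `truth` (data.frame: tip, residues and codons at
#'   86/90/93, genotype and phenotype class) and `spec`.
#' @export
simulate_fragments <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  tree <- spec$tree
  n <- length(tree$tip.label)
  region <- .sim_region_residues()
  codons <- vapply(region, .pick_codon, character(1))
  codons[c("86", "90", "93")] <- spec$root_codons

  # codon state per node, filled root-down
  node_codons <- vector("list", n + tree$Nnode)
  root <- n + 1L
  node_codons[[root]] <- codons
  eo <- stats::reorder(tree, "postorder")$edge
  ev_child_id <- if (nrow(spec$events) > 0L) {
    vapply(spec$events$child, function(l) .node_id_by_label(tree, l), integer(1))
  } else integer(0)
  for (r in rev(seq_len(nrow(eo)))) {          # preorder
    par <- eo[r, 1L]; ch <- eo[r, 2L]
    cur <- node_codons[[par]]
    hits <- which(ev_child_id == ch)
    for (h in hits) {
      site <- as.character(spec$events$site[h])
      from <- .check_codon(spec$events$from_codon[h])
      to <- .check_codon(spec$events$to_codon[h])
      if (!identical(cur[[site]], from)) {
        stop(sprintf(
          "planting error on branch above '%s': inherited codon at site %s is %s, event expects %s",
          spec$events$child[h], site, cur[[site]], from))
      }
      cur[[site]] <- to
    }
    node_codons[[ch]] <- cur
  }

  rand_bases <- function(k) {
    if (k == 0L) return("")
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = "")
  }
  apply_noise <- function(s) {
    if (spec$noise == 0 && spec$ambiguity == 0) return(s)
    chars <- strsplit(s, "")[[1]]
    if (spec$noise > 0) {
      flip <- stats::runif(length(chars)) < spec$noise
      if (any(flip)) {
        chars[flip] <- vapply(chars[flip], function(b) {
          sample(setdiff(c("A", "C", "G", "T"), b), 1L)
        }, character(1))
      }
    }
    if (spec$ambiguity > 0) {
      mask <- stats::runif(length(chars)) < spec$ambiguity
      chars[mask] <- "N"
    }
    paste(chars, collapse = "")
  }

  fragments <- character(n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    cod <- node_codons[[i]]
    coding <- paste(cod, collapse = "")
    fragments[i] <- apply_noise(paste0(rand_bases(spec$flank5), coding,
                                       rand_bases(spec$flank3)))
    res <- vapply(cod[c("86", "90", "93")], .translate_codon, character(1))
    g <- tuning_genotype(res[1], res[2], res[3],
                         cod[["86"]], cod[["90"]], cod[["93"]])
    call <- classify_genotype(g)
    truth[[i]] <- data.frame(
      tip = tree$tip.label[i],
      res86 = res[1], res90 = res[2], res93 = res[3],
      codon86 = cod[["86"]], codon90 = cod[["90"]], codon93 = cod[["93"]],
      genotype_class = call$genotype_class,
      phenotype_class = call$phenotype_class,
      stringsAsFactors = FALSE
    )
  }
  names(fragments) <- tree$tip.label
  list(fragments = fragments, truth = do.call(rbind, truth), spec = spec)
}

#' Sample branches for well-separated planted events
#'
#' Chooses `k` branches of a binary tree such that the planted events are
#' recoverable by parsimony by construction: descendant tip sets are
#' pairwise disjoint, no two chosen branches are children of the same
#' node (so no union of planted clades collapses into a single clade),
#' and the implied derived/ancestral tip coloring requires exactly `k`
#' changes (placements that a reconstruction could explain more cheaply,
#' e.g. by flipping the root side, are rejected and resampled).
#'
#' @param tree Rooted binary `phylo` tree.
#' @param k Number of branches.
#' @param site,from_codon,to_codon The substitution planted on each branch
#'   (default the C90 gain `AGC -> TGC` at site 90).
#' @return Events data.frame for [simulation_spec()].
#' @export
plant_random_events <- function(tree, k, site = 90L,
                                from_codon = "AGC", to_codon = "TGC") {
  .check_phylo(tree)
  n <- length(tree$tip.label)
  edge <- tree$edge
  desc_tips <- function(node) {
    if (node <= n) return(node)
    unlist(lapply(edge[edge[, 1L] == node, 2L], desc_tips))
  }
  tipsets <- lapply(edge[, 2L], desc_tips)
  chosen <- integer(0)
  for (try in seq_len(200L)) {            # greedy with random restarts
    ord <- sample(seq_len(nrow(edge)))
    chosen <- integer(0)
    for (e in ord) {
      ok <- TRUE
      for (c2 in chosen) {
        if (length(intersect(tipsets[[e]], tipsets[[c2]])) > 0L ||
            edge[e, 1L] == edge[c2, 1L]) {
          ok <- FALSE
          break
        }
      }
      if (ok) chosen <- c(chosen, e)
      if (length(chosen) == k) break
    }
    if (length(chosen) == k) {
      # the events are "well separated" only if the implied tip coloring
      # cannot be explained by fewer than k changes (e.g. flipping the
      # root side when the unaffected tips happen to form one clade)
      derived <- unique(unlist(tipsets[chosen]))
      st <- stats::setNames(ifelse(seq_len(n) %in% derived, "derived",
                                   "ancestral"), tree$tip.label)
      if (fitch_count(tree, st)$min_changes == k) break
      chosen <- integer(0)
    }
  }
  if (length(chosen) < k) stop("could not place ", k, " separated events")
  # identify each branch by its child label; unlabelled internal children
  # get labels assigned here
  child <- edge[chosen, 2L]
  if (is.null(tree$node.label)) {
    tree$node.label <- rep("", tree$Nnode)
  }
  labs <- character(length(child))
  for (i in seq_along(child)) {
    if (child[i] <= n) {
      labs[i] <- tree$tip.label[child[i]]
    } else {
      if (!nzchar(tree$node.label[child[i] - n])) {
        tree$node.label[child[i] - n] <- paste0("node", child[i])
      }
      labs[i] <- tree$node.label[child[i] - n]
    }
  }
  list(
    tree = tree,
    events = data.frame(child = labs, site = site, from_codon = from_codon,
                        to_codon = to_codon, stringsAsFactors = FALSE)
  )
}
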