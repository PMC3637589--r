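# Shared test helpers: small generators and independent oracles.

# random rooted binary tree with reproducible topology
random_tree <- function(n, seed) {
  set.seed(seed)
  ape::rtree(n, rooted = TRUE, br = NULL)
}

# encode an amino-acid string as DNA, choosing synonymous codons at random
encode_aa <- function(aa, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(vapply(strsplit(aa, "")[[1]], function(a) {
    cods <- codons_for(a)
    cods[sample.int(length(cods), 1L)]
  }, character(1)), collapse = "")
}

# independent oracle: all shortest paths between codons by breadth-first
# search over the 64-codon graph (edges = single-base changes), optionally
# excluding stop codons as intermediates. Returns the number of shortest
# paths and the shortest distance.
bfs_codon_paths <- function(a, b, forbid_stops = FALSE) {
  bases <- c("A", "C", "G", "T")
  all_codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  stops <- c("TAA", "TAG", "TGA")
  neighbors <- function(x) {
    xb <- strsplit(x, "")[[1]]
    out <- character(0)
    for (p in 1:3) for (bb in setdiff(bases, xb[p])) {
      y <- xb; y[p] <- bb
      out <- c(out, paste(y, collapse = ""))
    }
    out
  }
  if (a == b) return(list(distance = 0L, n_paths = 1L))
  dist <- stats::setNames(rep(Inf, length(all_codons)), all_codons)
  npaths <- stats::setNames(rep(0, length(all_codons)), all_codons)
  dist[a] <- 0; npaths[a] <- 1
  queue <- a
  while (length(queue) > 0L) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (nb in neighbors(cur)) {
      if (forbid_stops && nb %in% stops && nb != b) next
      if (is.infinite(dist[nb])) {
        dist[nb] <- dist[cur] + 1
        npaths[nb] <- npaths[cur]
        queue <- c(queue, nb)
      } else if (dist[nb] == dist[cur] + 1) {
        npaths[nb] <- npaths[nb] + npaths[cur]
      }
    }
  }
  list(distance = as.integer(dist[b]), n_paths = as.integer(npaths[b]))
}

# all rooted binary tree shapes on n labelled tips (as newick strings);
# enough for the exhaustive parsimony cross-checks
all_rooted_topologies <- function(tips) {
  if (length(tips) == 1L) return(tips)
  out <- character(0)
  n <- length(tips)
  # split tips into left/right non-empty subsets (unordered)
  for (mask in 1:(2^n - 2)) {
    left <- tips[bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0]
    if (!(tips[1L] %in% left)) next   # avoid mirror duplicates
    right <- setdiff(tips, left)
    for (l in all_rooted_topologies(left)) {
      for (r in all_rooted_topologies(right)) {
        out <- c(out, paste0("(", l, ",", r, ")"))
      }
    }
  }
  out
}
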