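# Independent brute-force oracles, deliberately implemented differently
# from the package internals (plain recursion over the raw edge matrix,
# explicit tip-to-root paths), plus small fixture builders.

# Sister-clade change sum by naive top-down recursion: every node value is
# recomputed from scratch, no postorder bookkeeping shared with the
# implementation under test.
oracle_changes <- function(tree, states) {
  nt <- ape::Ntip(tree)
  node_value <- function(v) {
    if (v <= nt) return(as.numeric(states[[tree$tip.label[v]]]))
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    mean(vapply(kids, node_value, numeric(1)))
  }
  internal <- (nt + 1):(nt + tree$Nnode)
  sum(vapply(internal, function(v) {
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    vals <- vapply(kids, node_value, numeric(1))
    abs(vals[1] - vals[2])
  }, numeric(1)))
}

# Patristic distances via explicitly enumerated root paths:
# d(i, j) = depth(i) + depth(j) - 2 * depth(mrca(i, j)).
oracle_patristic <- function(tree) {
  nt <- ape::Ntip(tree)
  nn <- nt + tree$Nnode
  parent <- integer(nn)
  elen <- numeric(nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  root_path <- function(v) {            # v, parent(v), ..., root
    path <- v
    while (parent[v] != 0) {
      v <- parent[v]
      path <- c(path, v)
    }
    path
  }
  d <- matrix(0, nt, nt, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(nt), root_path)
  depths <- vapply(seq_len(nt), function(i) sum(elen[paths[[i]]]), numeric(1))
  node_depth <- function(v) sum(elen[root_path(v)])
  for (i in seq_len(nt)) {
    for (j in seq_len(nt)) {
      if (i == j) next
      mrca <- intersect(paths[[i]], paths[[j]])[1]
      d[i, j] <- depths[i] + depths[j] - 2 * node_depth(mrca)
    }
  }
  d
}

# Hamming mismatch count by explicit elementwise loop.
oracle_mismatch <- function(x, y) {
  sum(vapply(seq_along(x), function(i) as.numeric(x[i] != y[i]), numeric(1)))
}

random_states <- function(tree, k) {
  n <- ape::Ntip(tree)
  s <- numeric(n)
  s[sample.int(n, k)] <- 1
  names(s) <- tree$tip.label
  s
}

# Random symmetric zero-diagonal labelled matrix.
random_distance_matrix <- function(n, labels = paste0("t", seq_len(n))) {
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[upper.tri(m)] <- stats::runif(n * (n - 1) / 2)
  m + t(m)
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}
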