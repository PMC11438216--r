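# Independent brute-force oracles for the graph views: walks are enumerated
# by filtering *all* node tuples against the adjacency matrix (no shared code
# with the package's recursive enumeration), and the view vectors are rebuilt
# from first principles on top of that enumeration.

oracle_adjacency <- function(g) {
  A <- matrix(0L, g$n_atoms, g$n_atoms)
  lab <- matrix(NA_character_, g$n_atoms, g$n_atoms)
  if (nrow(g$bonds)) {
    for (r in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[r]; j <- g$bonds$j[r]
      A[i, j] <- A[j, i] <- 1L
      lab[i, j] <- lab[j, i] <- g$bonds$label[r]
    }
  }
  list(A = A, lab = lab)
}

# All directed walks with 1..k edges as a list of node-index vectors.
oracle_walks <- function(g, k) {
  adj <- oracle_adjacency(g)
  n <- g$n_atoms
  walks <- list()
  for (len in seq_len(k)) {
    tuples <- as.matrix(expand.grid(rep(list(seq_len(n)), len + 1L)))
    ok <- rep(TRUE, nrow(tuples))
    for (s in seq_len(len)) {
      ok <- ok & adj$A[cbind(tuples[, s], tuples[, s + 1L])] == 1L
    }
    keep <- tuples[ok, , drop = FALSE]
    walks <- c(walks, lapply(seq_len(nrow(keep)), function(r) unname(keep[r, ])))
  }
  walks
}

oracle_hash <- function(codes, base, len) {
  h <- 0
  for (cde in codes) h <- (h * base + cde) %% len
  h
}

oracle_graph_views <- function(g, cfg) {
  adj <- oracle_adjacency(g)
  walks <- oracle_walks(g, cfg$k)
  codes <- c(single = 1, double = 2, triple = 3, aromatic = 4)

  v1 <- numeric(cfg$L1)
  for (z in g$atoms) v1[z + 1] <- v1[z + 1] + 1

  v2 <- numeric(cfg$L2)
  v4 <- numeric(cfg$L4)
  for (w in walks) {
    bond_seq <- codes[adj$lab[cbind(w[-length(w)], w[-1])]]
    v2[oracle_hash(bond_seq, 5, cfg$L2) + 1] <-
      v2[oracle_hash(bond_seq, 5, cfg$L2) + 1] + 1
    atom_seq <- g$atoms[w]
    v4[oracle_hash(atom_seq, 128, cfg$L4) + 1] <-
      v4[oracle_hash(atom_seq, 128, cfg$L4) + 1] + 1
  }

  # all-pairs shortest paths by Floyd-Warshall
  v3 <- numeric(cfg$L3)
  n <- g$n_atoms
  if (n >= 2) {
    dist <- matrix(Inf, n, n)
    diag(dist) <- 0
    dist[adj$A == 1L] <- 1
    for (m in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
      if (dist[i, m] + dist[m, j] < dist[i, j]) dist[i, j] <- dist[i, m] + dist[m, j]
    }
    for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
      d <- dist[i, j]
      if (is.finite(d)) {
        pos <- min(d, cfg$L3 - 1)
        v3[pos + 1] <- v3[pos + 1] + 1
      }
    }
  }
  list(v1 = v1, v2 = v2, v3 = v3, v4 = v4)
}
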