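# Drug view 2: deterministic multi-view embedding of the heavy-atom
# molecular graph.  Four sub-views -- atom-label counts, hashed bond-label
# walk counts, a shortest-path-length histogram, and hashed atom-label walk
# counts -- are concatenated and tanh-normalized over the drug set.

BOND_LABEL_CODES <- c(single = 1L, double = 2L, triple = 3L, aromatic = 4L)

#' Graph-view configuration
#'
#' Vector lengths of the four graph sub-views and the walk-length cap.
#' Positions within each sub-view are 0-based in the descriptions below
#' (an atom with atomic number `z` lands at R index `z + 1`).
#'
#' @param L1 Atom-label count vector length (default 128; must exceed every
#'   atomic number present).
#' @param L2 Bond-label walk vector length (default 256).
#' @param L3 Shortest-path-length histogram length (default 32).
#' @param L4 Atom-label walk vector length (default 512).
#' @param k Maximum walk length in edges (default 3).
#' @return A list of class `graph_view_config`.
#' @export
graph_view_config <- function(L1 = 128L, L2 = 256L, L3 = 32L, L4 = 512L, k = 3L) {
  stopifnot(L1 >= 1, L2 >= 1, L3 >= 1, L4 >= 1, k >= 1)
  structure(list(L1 = as.integer(L1), L2 = as.integer(L2), L3 = as.integer(L3),
                 L4 = as.integer(L4), k = as.integer(k)),
            class = "graph_view_config")
}

#' Convert a SMILES string to a molecular graph
#'
#' Heavy atoms only (hydrogens implicit); atom labels are atomic numbers and
#' bond labels one of single/double/triple/aromatic, as perceived by the
#' chemistry engine.
#'
#' @param smiles A single SMILES string.
#' @return An object of class `molecular_graph`: list with `n_atoms`,
#'   `atoms` (integer atomic numbers) and `bonds` (data.frame `i`, `j`,
#'   `label`; undirected, 1-based, no duplicates).
#' @export
smiles_to_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  res <- chem_batch("graphs", smiles)[[1L]]
  if (!isTRUE(res$ok)) stop("unparseable SMILES ", sQuote(smiles), ": ", res$error)
  graph_from_bridge(res)
}

graph_from_bridge <- function(res) {
  atoms <- vapply(res$atoms, as.integer, integer(1))
  nb <- length(res$bonds)
  bonds <- data.frame(
    i = vapply(res$bonds, function(b) as.integer(b[[1L]]), integer(1)),
    j = vapply(res$bonds, function(b) as.integer(b[[2L]]), integer(1)),
    label = vapply(res$bonds, function(b) as.character(b[[3L]]), character(1)),
    stringsAsFactors = FALSE
  )
  if (nb == 0L) bonds <- data.frame(i = integer(0), j = integer(0),
                                    label = character(0), stringsAsFactors = FALSE)
  structure(list(n_atoms = length(atoms), atoms = atoms, bonds = bonds),
            class = "molecular_graph")
}

# Adjacency list; each entry holds neighbor index and bond-label code.
graph_adjacency <- function(g) {
  adj <- rep(list(list(nb = integer(0), code = integer(0))), g$n_atoms)
  if (nrow(g$bonds)) {
    codes <- BOND_LABEL_CODES[g$bonds$label]
    if (anyNA(codes)) stop("unknown bond label in graph")
    for (r in seq_len(nrow(g$bonds))) {
      i <- g$bonds$i[r]; j <- g$bonds$j[r]; cde <- codes[[r]]
      adj[[i]]$nb <- c(adj[[i]]$nb, j); adj[[i]]$code <- c(adj[[i]]$code, cde)
      adj[[j]]$nb <- c(adj[[j]]$nb, i); adj[[j]]$code <- c(adj[[j]]$code, cde)
    }
  }
  adj
}

#' Enumerate directed walks of a molecular graph
#'
#' All directed walks of 1 to `k` edges; node revisits are permitted, so a
#' single bond already yields back-and-forth walks at lengths 2 and 3.
#'
#' @param g A `molecular_graph`.
#' @param k Maximum number of edges per walk.
#' @return A list of integer node sequences (length `l + 1` for an `l`-edge
#'   walk); each distinct ordered node sequence appears exactly once.
#' @export
enumerate_walks <- function(g, k) {
  stopifnot(inherits(g, "molecular_graph"), k >= 1)
  adj <- graph_adjacency(g)
  walks <- list()
  grow <- function(seq_nodes, depth) {
    last <- seq_nodes[length(seq_nodes)]
    for (nb in adj[[last]]$nb) {
      w <- c(seq_nodes, nb)
      walks[[length(walks) + 1L]] <<- w
      if (depth < k) grow(w, depth + 1L)
    }
  }
  for (v in seq_len(g$n_atoms)) grow(v, 1L)
  walks
}

# Polynomial rolling hash of an integer code sequence: h <- (h*base + code)
# mod len; fixed base, unsalted, so results are bit-stable across platforms.
poly_hash <- function(codes, base, len) {
  h <- 0
  for (cde in codes) h <- (h * base + cde) %% len
  h  # 0-based position
}

#' Graph sub-view 1: atom-label counts
#'
#' Zero vector of length `L1`; 0-based position `z` is incremented once per
#' atom with atomic number `z`.
#'
#' @param g A `molecular_graph`.
#' @param cfg A [graph_view_config()].
#' @return Numeric vector of length `cfg$L1`; entries sum to the atom count.
#' @export
view_node_labels <- function(g, cfg = graph_view_config()) {
  stopifnot(inherits(g, "molecular_graph"))
  if (any(g$atoms >= cfg$L1)) {
    stop("atomic number ", max(g$atoms), " >= L1 (", cfg$L1,
         "); increase L1 in graph_view_config()")
  }
  v <- numeric(cfg$L1)
  for (z in g$atoms) v[z + 1L] <- v[z + 1L] + 1
  v
}

#' Graph sub-view 2: hashed bond-label walk counts
#'
#' For every directed walk of up to `cfg$k` edges, the sequence of bond-label
#' codes (single=1, double=2, triple=3, aromatic=4) is hashed with a
#' polynomial rolling hash (base 5) into a vector of length `L2`.
#'
#' @inheritParams view_node_labels
#' @return Numeric vector of length `cfg$L2`; entries sum to the number of
#'   walks.
#' @export
view_edge_label_walks <- function(g, cfg = graph_view_config()) {
  v <- numeric(cfg$L2)
  adj <- graph_adjacency(g)
  grow <- function(last, codes, depth) {
    nbs <- adj[[last]]$nb; cds <- adj[[last]]$code
    for (t in seq_along(nbs)) {
      cs <- c(codes, cds[t])
      p <- poly_hash(cs, 5, cfg$L2)
      v[p + 1L] <<- v[p + 1L] + 1
      if (depth < cfg$k) grow(nbs[t], cs, depth + 1L)
    }
  }
  for (s in seq_len(g$n_atoms)) grow(s, integer(0), 1L)
  v
}

#' Graph sub-view 3: shortest-path-length histogram
#'
#' Unweighted all-pairs shortest path lengths over unordered atom pairs
#' (i < j); 0-based position `l` counts pairs at distance `l` for
#' `l < L3 - 1`, the last position accumulates all larger distances, and
#' disconnected pairs are ignored.
#'
#' @inheritParams view_node_labels
#' @return Numeric vector of length `cfg$L3`.
#' @export
view_shortest_path_hist <- function(g, cfg = graph_view_config()) {
  v <- numeric(cfg$L3)
  n <- g$n_atoms
  if (n < 2L) return(v)
  adj <- graph_adjacency(g)
  for (s in seq_len(n - 1L)) {
    dist <- rep(NA_integer_, n); dist[s] <- 0L
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) for (w in adj[[u]]$nb) {
        if (is.na(dist[w])) { dist[w] <- dist[u] + 1L; nxt <- c(nxt, w) }
      }
      frontier <- nxt
    }
    for (t in seq.int(s + 1L, n)) {
      d <- dist[t]
      if (!is.na(d) && d >= 1L) {
        pos <- min(d, cfg$L3 - 1L)
        v[pos + 1L] <- v[pos + 1L] + 1
      }
    }
  }
  v
}

#' Graph sub-view 4: hashed atom-label walk counts
#'
#' For every directed walk of up to `cfg$k` edges, the sequence of atomic
#' numbers along the walk (`l + 1` labels for an `l`-edge walk) is hashed
#' with a polynomial rolling hash (base 128) into a vector of length `L4`.
#' Sequences are direction-sensitive: C->O and O->C count separately.
#'
#' @inheritParams view_node_labels
#' @return Numeric vector of length `cfg$L4`; entries sum to the number of
#'   walks (same total as [view_edge_label_walks()]).
#' @export
view_node_label_walks <- function(g, cfg = graph_view_config()) {
  v <- numeric(cfg$L4)
  adj <- graph_adjacency(g)
  labs <- g$atoms
  grow <- function(last, codes, depth) {
    for (nb in adj[[last]]$nb) {
      cs <- c(codes, labs[nb])
      p <- poly_hash(cs, 128, cfg$L4)
      v[p + 1L] <<- v[p + 1L] + 1
      if (depth < cfg$k) grow(nb, cs, depth + 1L)
    }
  }
  for (s in seq_len(g$n_atoms)) grow(s, labs[s], 1L)
  v
}

graph_feature_vector <- function(g, cfg) {
  c(view_node_labels(g, cfg), view_edge_label_walks(g, cfg),
    view_shortest_path_hist(g, cfg), view_node_label_walks(g, cfg))
}

#' Compute the graph drug view
#'
#' Concatenates the four graph sub-views per drug (length
#' `L1 + L2 + L3 + L4`) and tanh-normalizes the resulting matrix column-wise
#' over the drug set.  The pre-normalization matrix is kept in the `raw`
#' field for fold-local refitting of the normalization.
#'
#' @param drugs List of drug records (see [drug_record()]).
#' @param cfg A [graph_view_config()].
#' @param c Tanh-norm scale constant.
#' @return A `drug_view_matrix` (see [drug_view_matrix()]) with view name
#'   `"graph"`.
#' @export
compute_graph_view <- function(drugs, cfg = graph_view_config(), c = 0.01) {
  ids <- drug_ids(drugs)
  parsed <- chem_batch("graphs", drug_smiles(drugs))
  chem_stop_on_failure(parsed, drug_smiles(drugs), ids)
  rows <- lapply(parsed, function(r) graph_feature_vector(graph_from_bridge(r), cfg))
  raw <- do.call(rbind, rows)
  rownames(raw) <- ids
  colnames(raw) <- c(sprintf("nl%03d", seq_len(cfg$L1) - 1L),
                     sprintf("ew%03d", seq_len(cfg$L2) - 1L),
                     sprintf("sp%03d", seq_len(cfg$L3) - 1L),
                     sprintf("nw%03d", seq_len(cfg$L4) - 1L))
  params <- tanh_norm_fit(raw, c = c)
  drug_view_matrix("graph", ids, tanh_norm_apply(params, raw),
                   raw = raw, norm = params)
}
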