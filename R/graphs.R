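## Decomposable-graph machinery for the residual-correlation model.
## Graphs live on the q outcomes (q is small), represented as symmetric 0/1
## adjacency matrices with zero diagonal. Decomposability (= chordality) is
## what makes the hyper-inverse Wishart factorize over a perfect sequence of
## cliques, so every proposal is screened with a maximum cardinality search.

## Maximum cardinality search: visit order plus the standard chordality test
## (the earlier neighbors of each vertex must form a clique anchored at the
## most recently visited one).
.mcs <- function(adj) {
  q <- nrow(adj)
  wt <- rep(0L, q); ord <- integer(q); numbered <- rep(FALSE, q)
  for (i in seq_len(q)) {
    cand <- which(!numbered)
    v <- cand[which.max(wt[cand])]
    ord[i] <- v; numbered[v] <- TRUE
    nb <- which(adj[v, ] == 1 & !numbered)
    wt[nb] <- wt[nb] + 1L
  }
  pos <- integer(q); pos[ord] <- seq_len(q)
  chordal <- TRUE
  if (q >= 3) {
    for (i in 2:q) {
      v <- ord[i]
      earlier <- ord[seq_len(i - 1)]
      S <- earlier[adj[v, earlier] == 1]
      if (length(S) > 1) {
        m <- S[which.max(pos[S])]
        rest <- S[S != m]
        if (any(adj[m, rest] == 0)) { chordal <- FALSE; break }
      }
    }
  }
  list(order = ord, pos = pos, chordal = chordal)
}

## Memoized per-adjacency analysis: chordality plus (when chordal) the
## perfect clique sequence. The sampler revisits the same few graphs
## thousands of times, so this dominates its cost if recomputed.
.graph_cache <- new.env(parent = emptyenv())

.graph_info <- function(adj) {
  key <- paste0(nrow(adj), ":", paste(adj[upper.tri(adj)], collapse = ""))
  hit <- .graph_cache[[key]]
  if (!is.null(hit)) return(hit)
  m <- .mcs(adj)
  info <- if (m$chordal)
    list(chordal = TRUE, dec = .clique_decomposition_raw(adj, m))
  else list(chordal = FALSE, dec = NULL)
  if (length(ls(.graph_cache)) > 4096) rm(list = ls(.graph_cache), envir = .graph_cache)
  assign(key, info, envir = .graph_cache)
  info
}

#' Test whether an undirected graph is decomposable
#'
#' @param adj symmetric 0/1 adjacency matrix (zero diagonal).
#' @return `TRUE` if the graph is chordal (equivalently, decomposable).
#' @keywords internal
is_decomposable <- function(adj) .graph_info(adj)$chordal

## Maximal cliques by exhaustive subset screening; the model targets a
## handful of outcomes, so 2^q enumeration is cheap and foolproof.
.max_cliques <- function(adj) {
  q <- nrow(adj)
  if (q > 16) stop("clique enumeration supports at most 16 outcomes")
  subsets <- lapply(seq_len(2^q - 1), function(m) which(bitwAnd(m, 2^(seq_len(q) - 1)) > 0))
  complete <- vapply(subsets, function(s) {
    if (length(s) == 1) return(TRUE)
    all(adj[s, s][upper.tri(diag(length(s)))] == 1)
  }, logical(1))
  comp <- subsets[complete]
  maximal <- vapply(comp, function(s) {
    out <- setdiff(seq_len(q), s)
    !any(vapply(out, function(v) all(adj[v, s] == 1), logical(1)))
  }, logical(1))
  comp[maximal]
}

## Perfect clique sequence with running-intersection separators: order the
## maximal cliques by the MCS rank of their latest vertex; separator j is
## the intersection of clique j with the union of the earlier cliques.
clique_decomposition <- function(adj) {
  info <- .graph_info(adj)
  if (!info$chordal) stop("graph is not decomposable")
  info$dec
}

.clique_decomposition_raw <- function(adj, m) {
  cl <- .max_cliques(adj)
  rank <- vapply(cl, function(s) max(m$pos[s]), numeric(1))
  cl <- cl[order(rank)]
  seps <- vector("list", length(cl))
  if (length(cl) > 1) {
    covered <- cl[[1]]
    for (j in 2:length(cl)) {
      seps[[j]] <- intersect(cl[[j]], covered)
      covered <- union(covered, cl[[j]])
    }
  }
  list(cliques = cl, separators = seps[-1])
}

## All edge toggles that keep the graph decomposable (used by tests and by
## the sampler's proposal screening).
.edge_pairs <- function(q) {
  if (q < 2) return(matrix(numeric(0), ncol = 2))
  which(upper.tri(diag(q)), arr.ind = TRUE)
}
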