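# Shared fixtures and independent oracles used across the test files.
# Oracles are deliberately written as naive brute-force code, separate from
# the package's implementation paths.

# --- tiny handcrafted patient -------------------------------------------

make_tiny_patient <- function(n_var = 5, with_normal = TRUE) {
  samples <- data.frame(
    sample_id = c("Pri1", "Lyn1", "Met1"),
    site = c("primary", "regional_lymph_node", "distant_metastasis"),
    region = 1L, timing = "pre_treatment", purity = 0.8,
    stringsAsFactors = FALSE)
  variants <- data.frame(
    chrom = "chr1", pos = 100L * seq_len(n_var), ref = "A", alt = "T",
    stringsAsFactors = FALSE)
  if (with_normal) { variants$normal_alt <- 0L; variants$normal_depth <- 100L }
  alt <- matrix(20L, n_var, 3)
  depth <- matrix(100L, n_var, 3)
  patient_dataset("P1", samples, variants, alt, depth)
}

# --- Fisher exact test by hypergeometric enumeration --------------------

fisher_p_oracle <- function(a, b, c, d) {
  # two-sided: sum of P(tables) <= P(observed), margins fixed
  m <- a + b; n2 <- c + d; k <- a + c
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# --- epsilon-connectivity clustering (DBSCAN oracle at minPts = 1) ------

eps_connectivity_oracle <- function(X, eps) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  adj <- D <= eps
  labels <- integer(n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i]) next
    cl <- cl + 1L
    frontier <- i
    while (length(frontier)) {
      labels[frontier] <- cl
      frontier <- which(colSums(adj[frontier, , drop = FALSE]) > 0 & labels == 0L)
    }
  }
  labels
}

same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, `==`) == outer(b, b, `==`))
}

# --- rooted-tree enumeration via Pruefer sequences ----------------------

# All rooted trees over m non-root nodes plus a fixed root, returned as
# parent vectors (0 = root). Decodes Pruefer sequences over m + 1 labels
# (label m + 1 is the root).
prufer_trees_oracle <- function(m) {
  n <- m + 1L
  if (m == 1L) return(list(0L))
  seqs <- do.call(expand.grid, rep(list(seq_len(n)), n - 2L))
  out <- vector("list", nrow(seqs))
  for (r in seq_len(nrow(seqs))) {
    pr <- as.integer(seqs[r, ])
    # standard Pruefer decode -> edge list
    degree <- rep(1L, n)
    for (v in pr) degree[v] <- degree[v] + 1L
    edges <- matrix(0L, n - 1L, 2L)
    ptr <- 0L
    deg <- degree
    avail <- rep(TRUE, n)
    for (v in pr) {
      leaf <- which(deg == 1L & avail)[1]
      ptr <- ptr + 1L
      edges[ptr, ] <- c(leaf, v)
      deg[leaf] <- 0L; avail[leaf] <- FALSE
      deg[v] <- deg[v] - 1L
    }
    last <- which(deg == 1L & avail)
    edges[n - 1L, ] <- last
    # orient away from the root (node n)
    adjl <- vector("list", n)
    for (e in seq_len(n - 1L)) {
      adjl[[edges[e, 1]]] <- c(adjl[[edges[e, 1]]], edges[e, 2])
      adjl[[edges[e, 2]]] <- c(adjl[[edges[e, 2]]], edges[e, 1])
    }
    parent <- integer(m)
    frontier <- n
    seen <- c(n)
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) for (w in adjl[[u]]) if (!(w %in% seen)) {
        parent[w] <- if (u == n) 0L else u
        seen <- c(seen, w)
        nxt <- c(nxt, w)
      }
      frontier <- nxt
    }
    out[[r]] <- parent
  }
  # Pruefer sequences biject onto labelled trees, so no duplicates
  out
}

# Naive per-tree constraint check and adjustment, loop form.
tree_ok_oracle <- function(parent, nest, no_anc) {
  m <- length(parent)
  anc_of <- function(d) {  # strict ancestors of d (node ids, 0 excluded)
    out <- integer(0); p <- parent[d]; steps <- 0
    while (p != 0L) {
      out <- c(out, p); p <- parent[p]
      steps <- steps + 1; if (steps > m) return(NULL)
    }
    out
  }
  ancs <- lapply(seq_len(m), anc_of)
  if (any(vapply(ancs, is.null, TRUE))) return(FALSE)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a == b) next
    if (a %in% ancs[[b]] && no_anc[a, b]) return(FALSE)
    if (a < b && nest[a, b] && !(a %in% ancs[[b]]) && !(b %in% ancs[[a]]))
      return(FALSE)
  }
  TRUE
}

adjustment_oracle <- function(parent, Fm) {
  total <- 0
  for (s in seq_len(ncol(Fm))) {
    for (v in c(0L, seq_len(nrow(Fm)))) {
      kids <- which(parent == v)
      if (!length(kids)) next
      pF <- if (v == 0L) 1 else Fm[v, s]
      excess <- sum(Fm[kids, s]) - pF
      if (excess > 0) total <- total + excess
    }
  }
  total
}

# Random synthetic subclone set with intervals (for tree-search tests).
random_subclone_set <- function(m, S, seed) {
  set.seed(seed)
  ids <- paste0("C", seq_len(m + 1))
  Fm <- rbind(rep(1, S), matrix(round(runif(m * S), 3), m, S))
  rownames(Fm) <- ids; colnames(Fm) <- paste0("s", seq_len(S))
  w <- matrix(runif((m + 1) * S, 0.02, 0.25), m + 1, S)
  L <- pmax(Fm - w, 0); H <- pmin(Fm + w, 1.2)
  L[1, ] <- 0.9; H[1, ] <- 1.2
  structure(list(members = setNames(as.list(ids), ids), founding = "C1",
                 F = Fm, L = L, H = H, k = 3),
            class = "metroute_subclones")
}
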