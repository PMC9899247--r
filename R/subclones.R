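# Subclonal reconstruction: density clustering of variants in per-sample CCF
# space, founding-clone normalisation, adjustable-interval algebra, pairwise
# containment constraints, and minimal-adjustment tree assembly.

# Plain DBSCAN on a points x dims matrix (Euclidean). minPts counts the
# point itself. Returns integer labels; 0 = noise (impossible at minPts 1).
dbscan_cluster <- function(X, eps, min_pts = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nb <- lapply(seq_len(n), function(i) which(D[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_pts
  labels <- integer(n)  # 0 = unassigned
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- nb[[i]]
    while (length(queue)) {
      q <- queue[1]; queue <- queue[-1]
      if (labels[q] == 0L) {
        labels[q] <- cl
        if (core[q]) queue <- c(queue, nb[[q]][labels[nb[[q]]] == 0L])
      }
    }
  }
  labels
}

#' Cluster variants into subclones in CCF space
#'
#' Runs DBSCAN (Euclidean distance in the per-sample CCF space, support
#' radius \code{eps}, \code{min_core} points per core) over all variants;
#' absent variants must enter with CCF 0 so cross-sample private clones
#' separate. Clusters with more than \code{min_size} mutations are retained
#' as subclones. The cluster whose per-sample median CCF exceeds
#' \code{founding_ccf} in every sample is the founding clone; it is exempt
#' from the size rule and is used to normalise all subclone CCFs.
#'
#' @param ccf_matrix Numeric matrix, variants x samples, of CCF point
#'   estimates (absent coded 0; NA coerced to 0).
#' @param eps DBSCAN support radius (default 0.05).
#' @param min_core DBSCAN core-point count (default 1, every point core).
#' @param min_size Retention threshold: clusters need strictly more than
#'   this many mutations (default 10).
#' @param founding_ccf Founding-clone median CCF threshold (default 0.9).
#' @return An object of class \code{metroute_subclones}: cluster membership,
#'   founding id, per-sample normalised CCF matrix \code{F} (subclones x
#'   samples, clamped to [0, 1]), and raw member CCFs for downstream algebra.
#' @export
cluster_variants <- function(ccf_matrix, eps = 0.05, min_core = 1L,
                             min_size = 10L, founding_ccf = 0.9) {
  X <- as.matrix(ccf_matrix)
  X[is.na(X)] <- 0
  if (is.null(rownames(X))) rownames(X) <- paste0("v", seq_len(nrow(X)))
  labels <- dbscan_cluster(X, eps = eps, min_pts = min_core)
  ids <- sort(unique(labels[labels > 0]))
  med <- t(vapply(ids, function(k)
    apply(X[labels == k, , drop = FALSE], 2, stats::median), numeric(ncol(X))))
  rownames(med) <- ids
  sizes <- vapply(ids, function(k) sum(labels == k), 1L)
  founding_like <- rowSums(med > founding_ccf) == ncol(X)
  if (!any(founding_like))
    stopf("cannot normalise: no founding clone (no cluster with median CCF > %.2g in all samples)",
          founding_ccf)
  fid <- ids[founding_like][which.max(sizes[founding_like])]
  keep <- ids[(sizes > min_size) | ids == fid]
  ord <- c(fid, setdiff(keep, fid))
  members <- lapply(ord, function(k) rownames(X)[labels == k])
  names(members) <- paste0("C", seq_along(ord))
  founding_med <- med[as.character(fid), ]
  Fm <- t(vapply(seq_along(ord), function(i)
    subclone_ccf(X[labels == ord[i], , drop = FALSE], founding_med),
    numeric(ncol(X))))
  dimnames(Fm) <- list(names(members), colnames(X))
  Fm[1, ] <- 1  # founding clone self-normalises exactly
  structure(list(members = members, founding = "C1", F = Fm,
                 assignment = setNames(labels, rownames(X)),
                 raw_ccf = X, eps = eps, min_core = min_core,
                 min_size = min_size, founding_ccf = founding_ccf,
                 L = NULL, H = NULL, k = NULL),
            class = "metroute_subclones")
}

#' Normalised subclone CCF in one sample
#'
#' The subclone CCF is the median over member-variant CCFs, divided by the
#' founding clone's median CCF in the same sample, clamped to [0, 1].
#'
#' @param member_ccf Matrix (members x samples) or vector of member CCFs.
#' @param founding_ccf Founding-clone median CCF per sample (> 0).
#' @return Numeric vector of normalised CCFs per sample.
#' @export
subclone_ccf <- function(member_ccf, founding_ccf) {
  m <- if (is.matrix(member_ccf)) apply(member_ccf, 2, stats::median)
       else stats::median(member_ccf)
  if (any(founding_ccf <= 0)) stopf("founding CCF is 0 in a sample; F undefined")
  pmin(pmax(m / founding_ccf, 0), 1)
}

#' @export
print.metroute_subclones <- function(x, ...) {
  cat(sprintf("<metroute_subclones> %d subclones (founding %s), %d clustered variants\n",
              length(x$members), x$founding, sum(lengths(x$members))))
  print(round(x$F, 3))
  invisible(x)
}

#' Adjustable CCF interval of a subclone in one sample
#'
#' Expands the subclone CCF \code{F} by \code{k} times the root-mean-square
#' gap between the member CCFs and their confidence bounds:
#' \deqn{H = F + k\sqrt{\sum_i (h_i - f_i)^2 / n}, \quad
#'       L = F - k\sqrt{\sum_i (l_i - f_i)^2 / n}}
#' with \code{L} clamped at 0 and \code{H} at 1.2.
#'
#' @param F Subclone CCF in the sample.
#' @param f Member-variant CCFs in the sample.
#' @param h,l Upper/lower CI bounds per member (same length as \code{f}).
#' @param k Expansion factor (default 3).
#' @param h_clamp Upper clamp for H (default 1.2).
#' @return Named numeric vector \code{c(L = , H = )}.
#' @export
adjustable_interval <- function(F, f, h, l, k = 3, h_clamp = 1.2) {
  n <- length(f)
  if (n == 0) stopf("subclone has no member variants in this sample")
  if (length(h) != n || length(l) != n) stopf("f, h, l must have equal length")
  H <- F + k * sqrt(sum((h - f)^2) / n)
  L <- F - k * sqrt(sum((l - f)^2) / n)
  c(L = max(L, 0), H = min(H, h_clamp))
}

#' Attach adjustable intervals to a subclone set
#'
#' Computes the per-sample \code{[L, H]} interval of every subclone from the
#' member-variant CCFs and their confidence bounds. Absent members (no CI)
#' contribute a zero-width interval at their CCF.
#'
#' @param sub A \code{metroute_subclones}.
#' @param ci_low,ci_high Matrices (variants x samples) of CI bounds aligned
#'   with the CCF matrix given to \code{\link{cluster_variants}}.
#' @param k Expansion factor (default 3).
#' @return The object with \code{$L} and \code{$H} matrices filled.
#' @export
subclone_intervals <- function(sub, ci_low, ci_high, k = 3) {
  stopifnot(inherits(sub, "metroute_subclones"))
  X <- sub$raw_ccf
  ci_low <- as.matrix(ci_low)[rownames(X), , drop = FALSE]
  ci_high <- as.matrix(ci_high)[rownames(X), , drop = FALSE]
  ci_low[is.na(ci_low)] <- X[is.na(ci_low)]
  ci_high[is.na(ci_high)] <- X[is.na(ci_high)]
  S <- ncol(X)
  L <- H <- matrix(NA_real_, length(sub$members), S,
                   dimnames = dimnames(sub$F))
  for (i in seq_along(sub$members)) {
    rows <- sub$members[[i]]
    for (s in seq_len(S)) {
      lh <- adjustable_interval(sub$F[i, s], X[rows, s],
                                ci_high[rows, s], ci_low[rows, s], k = k)
      L[i, s] <- lh["L"]; H[i, s] <- lh["H"]
    }
  }
  sub$L <- L; sub$H <- H; sub$k <- k
  sub$ci_low <- ci_low; sub$ci_high <- ci_high
  sub
}

#' Pairwise evolutionary constraint between two subclones
#'
#' Evaluated per sample, then aggregated: if in any sample
#' \code{L_i + L_j > 1}, the two subclones cannot occupy disjoint cell
#' populations, so one must be the other's ancestor (\code{must_nest},
#' pigeonhole on cell fractions). If in any sample \code{L_i > H_j},
#' subclone j is too small to contain i (\code{j_not_parent_of_i});
#' symmetrically for the other direction. Intervals that simultaneously
#' force nesting and exclude both directions are inconsistent and raise an
#' error.
#'
#' @param L_i,H_i,L_j,H_j Per-sample interval bounds of the two subclones.
#' @return One of \code{"must_nest"}, \code{"j_not_parent_of_i"},
#'   \code{"i_not_parent_of_j"}, \code{"undetermined"}, with the raw
#'   per-rule flags in attribute \code{"flags"}.
#' @export
infer_pairwise_relation <- function(L_i, H_i, L_j, H_j) {
  nest <- any(L_i + L_j > 1)
  no_j_anc_i <- any(L_i > H_j)   # j cannot contain i
  no_i_anc_j <- any(L_j > H_i)
  if (nest && no_j_anc_i && no_i_anc_j)
    stopf("inconsistent intervals: nesting forced but both directions excluded")
  out <- if (nest) "must_nest"
         else if (no_j_anc_i && !no_i_anc_j) "j_not_parent_of_i"
         else if (no_i_anc_j && !no_j_anc_i) "i_not_parent_of_j"
         else if (no_j_anc_i && no_i_anc_j) "j_not_parent_of_i"  # forced parallel; both flags set
         else "undetermined"
  attr(out, "flags") <- c(nest = nest, no_j_anc_i = no_j_anc_i,
                          no_i_anc_j = no_i_anc_j)
  out
}

# All-pairs constraint flags over non-root subclones (founding is always the
# unique root and ancestor of everything).
pair_constraints <- function(sub) {
  ids <- setdiff(names(sub$members), sub$founding)
  m <- length(ids)
  nest <- no_anc <- matrix(FALSE, m, m, dimnames = list(ids, ids))
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a >= b) next
    rel <- infer_pairwise_relation(sub$L[ids[a], ], sub$H[ids[a], ],
                                   sub$L[ids[b], ], sub$H[ids[b], ])
    fl <- attr(rel, "flags")
    nest[a, b] <- nest[b, a] <- fl["nest"]
    if (fl["no_j_anc_i"]) no_anc[b, a] <- TRUE  # b not ancestor of a
    if (fl["no_i_anc_j"]) no_anc[a, b] <- TRUE
  }
  list(ids = ids, nest = nest, no_anc = no_anc)
}

# Ancestor matrix (anc[a, d] TRUE when a is a strict ancestor of d) from a
# parent vector over nodes 1..n where parent 0 means the root.
ancestor_matrix <- function(parent) {
  m <- length(parent)
  anc <- matrix(FALSE, m, m)
  for (d in seq_len(m)) {
    p <- parent[d]
    steps <- 0L
    while (p != 0L) {
      anc[p, d] <- TRUE
      p <- parent[p]
      steps <- steps + 1L
      if (steps > m) return(NULL)  # cycle
    }
  }
  anc
}

# Total adjustment of a candidate tree: per sample and per node, the excess
# of summed child CCF over the parent's CCF (root has F = 1 everywhere).
tree_adjustment <- function(parent, Fm) {
  S <- ncol(Fm)
  m <- length(parent)
  total <- 0
  for (s in seq_len(S)) {
    child_sum <- numeric(m + 1L)  # index 1 = root, 1 + i = node i
    for (i in seq_len(m)) {
      pi <- parent[i] + 1L
      child_sum[pi] <- child_sum[pi] + Fm[i, s]
    }
    parent_F <- c(1, Fm[, s])
    total <- total + sum(pmax(0, child_sum - parent_F))
  }
  total
}

satisfies_constraints <- function(anc, cons) {
  if (is.null(anc)) return(FALSE)
  m <- nrow(anc)
  for (a in seq_len(m)) for (b in seq_len(m)) {
    if (a >= b) next
    if (cons$nest[a, b] && !anc[a, b] && !anc[b, a]) return(FALSE)
  }
  if (any(anc & cons$no_anc)) return(FALSE)
  TRUE
}

#' Assemble the subclone evolution tree with minimal CCF adjustment
#'
#' Searches rooted trees over the subclones (founding clone as the unique
#' root) that honour the pairwise constraints, scoring each candidate by its
#' adjustment value: the total CCF mass, summed over samples and nodes, by
#' which the children of a node exceed the node itself. The tree with the
#' smallest adjustment is returned; all co-minimal trees are reported. For
#' up to 6 non-root subclones the search is exhaustive over all rooted
#' trees; beyond that, a descending-mean-F insertion search is used.
#'
#' @param sub A \code{metroute_subclones} with intervals attached
#'   (\code{\link{subclone_intervals}}).
#' @param exhaustive_limit Maximum non-root subclone count for exhaustive
#'   enumeration (default 6).
#' @return An object of class \code{metroute_subclone_tree}: \code{$parent}
#'   (named character vector, NA for the root), \code{$adjustment},
#'   \code{$co_minimal} (list of co-minimal parent vectors),
#'   \code{$F_adjusted} (per-sample CCFs rescaled top-down so every sibling
#'   group sums to at most its parent).
#' @export
build_tree <- function(sub, exhaustive_limit = 6L) {
  stopifnot(inherits(sub, "metroute_subclones"))
  if (is.null(sub$L)) stopf("attach intervals with subclone_intervals() first")
  cons <- pair_constraints(sub)
  ids <- cons$ids
  m <- length(ids)
  Fm <- sub$F[ids, , drop = FALSE]
  if (m == 0) {
    parent <- setNames(NA_character_, sub$founding)
    return(structure(list(parent = parent, adjustment = 0,
                          co_minimal = list(parent), F = sub$F,
                          F_adjusted = sub$F, subclones = sub),
                     class = "metroute_subclone_tree"))
  }
  cand <- if (m <= exhaustive_limit) enumerate_trees(m)
          else insertion_trees(Fm, cons)
  best <- Inf; winners <- list()
  for (parent in cand) {
    anc <- ancestor_matrix(parent)
    if (!satisfies_constraints(anc, cons)) next
    adj <- tree_adjustment(parent, Fm)
    if (adj < best - 1e-12) { best <- adj; winners <- list(parent) }
    else if (abs(adj - best) <= 1e-12) winners <- c(winners, list(parent))
  }
  if (!length(winners)) {
    stopf("no feasible subclone tree: constraints %s cannot be satisfied jointly",
          paste(which(cons$nest | cons$no_anc), collapse = ","))
  }
  # dedupe (insertion search can propose the same tree twice)
  keys <- vapply(winners, paste, "", collapse = ",")
  winners <- winners[!duplicated(keys)]
  to_named <- function(parent) {
    p <- character(m)
    p[parent == 0L] <- sub$founding
    p[parent > 0L] <- ids[parent[parent > 0L]]
    setNames(c(NA_character_, p), c(sub$founding, ids))
  }
  parent_named <- to_named(winners[[1]])
  structure(list(parent = parent_named, adjustment = best,
                 co_minimal = lapply(winners, to_named),
                 F = sub$F, F_adjusted = adjust_ccf(parent_named, sub$F),
                 subclones = sub),
            class = "metroute_subclone_tree")
}

# Every rooted tree on m labelled non-root nodes under a fixed root:
# parent vectors (0 = root), acyclic only.
enumerate_trees <- function(m) {
  choices <- lapply(seq_len(m), function(i) c(0L, setdiff(seq_len(m), i)))
  grid <- do.call(expand.grid, choices)
  out <- vector("list", nrow(grid))
  n_ok <- 0L
  for (r in seq_len(nrow(grid))) {
    parent <- as.integer(grid[r, ])
    if (!is.null(ancestor_matrix(parent))) {
      n_ok <- n_ok + 1L
      out[[n_ok]] <- parent
    }
  }
  out[seq_len(n_ok)]
}

# Insertion search: nodes sorted by descending mean F (ties by id order) are
# attached at every existing node; all partial trees are kept, so the search
# is exhaustive over trees compatible with the insertion order.
insertion_trees <- function(Fm, cons) {
  m <- nrow(Fm)
  ord <- order(-rowMeans(Fm), seq_len(m))
  partial <- list(integer(0))
  placed <- integer(0)
  for (v in ord) {
    nxt <- list()
    for (tr in partial) {
      for (p in c(0L, placed)) {
        cand <- c(tr, setNames(p, NULL))
        nxt[[length(nxt) + 1L]] <- cand
      }
    }
    placed <- c(placed, v)
    partial <- nxt
  }
  # re-map: partial vectors are in insertion order; translate to node order
  lapply(partial, function(tr) {
    parent <- integer(m)
    for (k in seq_along(ord)) {
      p <- tr[k]
      parent[ord[k]] <- if (p == 0L) 0L else p
    }
    parent
  })
}

# Top-down proportional rescaling so sibling CCFs never exceed their parent.
adjust_ccf <- function(parent_named, Fm) {
  out <- Fm
  root <- names(parent_named)[is.na(parent_named)]
  kids_of <- function(v) names(parent_named)[!is.na(parent_named) & parent_named == v]
  walk <- function(v) {
    pF <- if (v == root) rep(1, ncol(Fm)) else out[v, ]
    kids <- kids_of(v)
    if (length(kids)) {
      ksum <- colSums(out[kids, , drop = FALSE])
      over <- ksum > pF & ksum > 0
      if (any(over)) {
        fac <- ifelse(over, pF / ksum, 1)
        out[kids, ] <<- sweep(out[kids, , drop = FALSE], 2, fac, `*`)
      }
      for (k in kids) walk(k)
    }
  }
  walk(root)
  out
}

#' @export
print.metroute_subclone_tree <- function(x, ...) {
  cat(sprintf("<metroute_subclone_tree> %d subclones, adjustment %.4g, %d co-minimal tree(s)\n",
              length(x$parent), x$adjustment, length(x$co_minimal)))
  df <- data.frame(subclone = names(x$parent), parent = unname(x$parent))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Bootstrap concordance of the subclone tree
#'
#' Resamples, within each subclone, the member mutations with replacement;
#' recomputes subclone CCFs and intervals; rebuilds the tree; and reports
#' the fraction of replicates whose parent map equals the original tree's.
#' Replicate r is seeded with \code{seed + r}.
#'
#' @param tree A \code{metroute_subclone_tree}.
#' @param B Replicates (default 1000).
#' @param seed Master seed.
#' @return Concordance fraction in [0, 1].
#' @export
bootstrap_subclone_tree <- function(tree, B = 1000L, seed = 1L) {
  stopifnot(inherits(tree, "metroute_subclone_tree"))
  sub <- tree$subclones
  if (is.null(sub$ci_low)) stopf("subclone intervals (with CIs) are required")
  B <- as.integer(B)
  if (B < 1) stopf("need >= 1 replicate")
  orig <- tree$parent
  hits <- 0L
  for (r in seq_len(B)) {
    sub_r <- with_seed(seed + r, resample_members(sub))
    tr <- tryCatch(build_tree(sub_r), error = function(e) NULL)
    if (!is.null(tr) && identical(tr$parent[names(orig)], orig)) hits <- hits + 1L
  }
  hits / B
}

resample_members <- function(sub) {
  X <- sub$raw_ccf; lo <- sub$ci_low; hi <- sub$ci_high
  S <- ncol(X)
  founding_rows <- sample(sub$members[[sub$founding]],
                          length(sub$members[[sub$founding]]), replace = TRUE)
  founding_med <- apply(X[founding_rows, , drop = FALSE], 2, stats::median)
  founding_med[founding_med <= 0] <- 1e-9
  for (i in seq_along(sub$members)) {
    rows <- sub$members[[i]]
    rs <- if (names(sub$members)[i] == sub$founding) founding_rows
          else sample(rows, length(rows), replace = TRUE)
    Fv <- subclone_ccf(X[rs, , drop = FALSE], founding_med)
    if (names(sub$members)[i] == sub$founding) Fv <- rep(1, S)
    sub$F[i, ] <- Fv
    for (s in seq_len(S)) {
      lh <- adjustable_interval(Fv[s], X[rs, s], hi[rs, s], lo[rs, s], k = sub$k)
      sub$L[i, s] <- lh["L"]; sub$H[i, s] <- lh["H"]
    }
  }
  sub
}

#' Confirm the seeding route from shared private subclones
#'
#' A subclone is present in a sample when its normalised CCF is at least
#' \code{presence_threshold}. The lymphatic route is supported when at
#' least one non-founding subclone is present in a distant metastasis and a
#' regional lymph-node sample but in no primary sample; the hematogenous
#' route when no such lymph-met private subclone exists and at least one
#' subclone is shared privately between a metastasis and a primary sample;
#' otherwise the pattern is unresolved.
#'
#' @param Fm Subclone x sample matrix of normalised CCFs (e.g. \code{$F} of
#'   a subclone tree), founding clone in the first row or named by
#'   \code{founding}.
#' @param meta Sample metadata (\code{sample_id}, \code{site}, \code{timing}).
#' @param presence_threshold Presence cutoff on F (default 0.05).
#' @param founding Name of the founding-clone row (default first row).
#' @return \code{"lymphatic_supported"}, \code{"hematogenous_supported"} or
#'   \code{"unresolved"}, with the supporting subclone ids in attribute
#'   \code{"evidence"}.
#' @export
confirm_route <- function(Fm, meta, presence_threshold = 0.05,
                          founding = rownames(Fm)[1]) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  pre <- meta$timing == "pre_treatment"
  sites <- setNames(meta$site, meta$sample_id)
  use <- intersect(colnames(Fm), meta$sample_id[pre])
  Fm <- Fm[setdiff(rownames(Fm), founding), use, drop = FALSE]
  present <- Fm >= presence_threshold
  prim <- use[sites[use] == "primary"]
  lymph <- use[sites[use] == "regional_lymph_node"]
  mets <- use[sites[use] == "distant_metastasis"]
  in_any <- function(p, cols) if (length(cols)) rowSums(p[, cols, drop = FALSE]) > 0
                              else rep(FALSE, nrow(p))
  lym_met <- in_any(present, mets) & in_any(present, lymph) & !in_any(present, prim)
  hem_met <- in_any(present, mets) & in_any(present, prim) & !in_any(present, lymph)
  if (any(lym_met)) {
    out <- "lymphatic_supported"
    attr(out, "evidence") <- rownames(Fm)[lym_met]
  } else if (any(hem_met)) {
    out <- "hematogenous_supported"
    attr(out, "evidence") <- rownames(Fm)[hem_met]
  } else {
    out <- "unresolved"
    attr(out, "evidence") <- character(0)
  }
  out
}
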