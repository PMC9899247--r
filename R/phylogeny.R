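#' Remove mutations whose absence may be an artefact of LOH
#'
#' A copy-number loss of the mutant allele can erase a truly ancestral
#' mutation from a sample and thereby distort the presence/absence
#' phylogeny. A mutation is removed when (a) it is not present in all
#' samples of the patient AND (b) its locus falls inside an LOH segment of
#' at least one sample lacking it. Mutations present in every sample are
#' kept regardless of LOH.
#'
#' @param mat Binary presence matrix (samples x mutations) with mutation ids
#'   \code{chrom:pos:ref>alt} as column names.
#' @param loh_segments Data frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{sample_id}; 0-based half-open intervals.
#' @return The matrix with confounded mutation columns dropped.
#' @export
filter_loh_confounded <- function(mat, loh_segments) {
  if (is.null(loh_segments) || nrow(loh_segments) == 0) return(mat)
  ids <- colnames(mat)
  parts <- strsplit(ids, ":", fixed = TRUE)
  chrom <- vapply(parts, `[`, "", 1L)
  pos <- as.integer(vapply(parts, `[`, "", 2L))
  ubiquitous <- colSums(mat > 0) == nrow(mat)
  drop <- logical(ncol(mat))
  for (j in which(!ubiquitous)) {
    lacking <- rownames(mat)[mat[, j] == 0]
    seg <- loh_segments[loh_segments$sample_id %in% lacking &
                        loh_segments$chrom == chrom[j] &
                        loh_segments$start < pos[j] &
                        loh_segments$end >= pos[j], , drop = FALSE]
    drop[j] <- nrow(seg) > 0
  }
  mat[, !drop, drop = FALSE]
}

# Hamming distance between sample rows of a binary matrix, germline row added.
presence_dist <- function(mat) {
  aug <- rbind(mat, germline = 0L)
  stats::dist(aug, method = "manhattan")
}

# Rooted NJ tree over the rows of `aug` (which includes the germline row).
nj_rooted <- function(aug) {
  phy <- ape::nj(stats::dist(aug, method = "manhattan"))
  ape::root(phy, outgroup = "germline", resolve.root = TRUE)
}

# Tip-label sets of every internal node of a rooted tree, as canonical
# strings ("a|b|c", sorted). Named by node number for the original tree.
clade_sets <- function(phy) {
  ntip <- length(phy$tip.label)
  nodes <- (ntip + 1L):(ntip + phy$Nnode)
  labs <- lapply(nodes, function(nd) sort(ape::extract.clade(phy, nd)$tip.label))
  names(labs) <- nodes
  labs
}

clade_keys <- function(phy) {
  vapply(clade_sets(phy), function(x) paste(x, collapse = "|"), "")
}

# Mutation-count branch lengths: each edge is scored by the number of
# mutations carried by exactly the samples in the clade below it.
shared_mutation_lengths <- function(phy, aug) {
  ntip <- length(phy$tip.label)
  tipsets <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) tipsets[[i]] <- phy$tip.label[i]
  # post-order over edges so children are filled before parents
  ord <- rev(seq_len(nrow(phy$edge)))
  for (e in ord) {
    ch <- phy$edge[e, 2]
    if (ch > ntip && is.null(tipsets[[ch]])) {
      kids <- phy$edge[phy$edge[, 1] == ch, 2]
      tipsets[[ch]] <- unlist(lapply(kids, function(k) tipsets[[k]]))
    }
  }
  for (e in ord) {  # second pass for any order quirks
    ch <- phy$edge[e, 2]
    if (ch > ntip && is.null(tipsets[[ch]])) {
      kids <- phy$edge[phy$edge[, 1] == ch, 2]
      tipsets[[ch]] <- unlist(lapply(kids, function(k) tipsets[[k]]))
    }
  }
  lens <- numeric(nrow(phy$edge))
  rn <- rownames(aug)
  for (e in seq_len(nrow(phy$edge))) {
    clade <- tipsets[[phy$edge[e, 2]]]
    inside <- rn %in% clade
    sub <- aug[inside, , drop = FALSE]
    rest <- aug[!inside, , drop = FALSE]
    lens[e] <- sum(colSums(sub > 0) == nrow(sub) & colSums(rest > 0) == 0)
  }
  phy$edge.length <- lens
  phy
}

#' Neighbour-joining phylogeny from a binary mutation matrix
#'
#' Builds the sample tree from the samples x mutations presence matrix:
#' pairwise distances are Hamming distances between sample rows, an all-zero
#' germline row is appended and used as outgroup to root the tree, and each
#' branch length is re-expressed as the number of mutations uniquely shared
#' by the clade below that branch.
#'
#' @param mat Binary matrix (samples x mutations), >= 3 samples, no NA.
#' @return An object of class \code{metroute_phylo}: list with the rooted
#'   \code{ape} tree (\code{$tree}), the augmented matrix (\code{$matrix}),
#'   and empty support slots to be filled by \code{\link{bootstrap_supports}}.
#' @export
nj_tree <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 3) stopf("need >= 3 samples for a phylogeny, got %d", nrow(mat))
  if (anyNA(mat)) stopf("presence matrix must not contain NA")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("S", seq_len(nrow(mat)))
  aug <- rbind(mat, germline = 0L)
  phy <- shared_mutation_lengths(nj_rooted(aug), aug)
  structure(list(tree = phy, matrix = aug, support = NULL,
                 replicate_clades = NULL, B = 0L, seed = NULL),
            class = "metroute_phylo")
}

#' @export
print.metroute_phylo <- function(x, ...) {
  cat(sprintf("<metroute_phylo> %d samples, %d mutations\n",
              nrow(x$matrix) - 1L, ncol(x$matrix)))
  cat("  ", ape::write.tree(x$tree), "\n", sep = "")
  if (!is.null(x$support))
    cat(sprintf("  bootstrap: B=%d, node supports %s\n", x$B,
                paste(format(x$support, digits = 3), collapse = ", ")))
  invisible(x)
}

#' Mutation-resampling bootstrap supports
#'
#' Each replicate resamples the mutation columns with replacement (as many
#' draws as there are mutations), rebuilds the rooted NJ tree, and counts
#' for every internal node of the original tree whether its clade reappears.
#' Supports are reproduction fractions over \code{B} replicates. Replicate
#' \code{r} is seeded deterministically with \code{seed + r}.
#'
#' @param result A \code{metroute_phylo} from \code{\link{nj_tree}}.
#' @param B Number of replicates (default 1000).
#' @param seed Master seed.
#' @return The \code{metroute_phylo} with \code{$support} (per internal
#'   node, root included) and the per-replicate clade lists needed for route
#'   classification.
#' @export
bootstrap_supports <- function(result, B = 1000L, seed = 1L) {
  stopifnot(inherits(result, "metroute_phylo"))
  B <- as.integer(B)
  if (B < 1) stopf("need >= 1 bootstrap replicate")
  aug <- result$matrix
  M <- ncol(aug)
  orig_keys <- clade_keys(result$tree)
  counts <- setNames(numeric(length(orig_keys)), orig_keys)
  rep_clades <- vector("list", B)
  for (r in seq_len(B)) {
    cols <- with_seed(seed + r, sample.int(M, M, replace = TRUE))
    phy_r <- nj_rooted(aug[, cols, drop = FALSE])
    keys_r <- clade_keys(phy_r)
    rep_clades[[r]] <- clade_sets(phy_r)
    counts <- counts + (orig_keys %in% keys_r)
  }
  result$support <- unname(counts / B)
  names(result$support) <- names(orig_keys)
  result$replicate_clades <- rep_clades
  result$B <- B
  result$seed <- seed
  result
}

# Score one tree's clades for one metastasis sample: walk up from the leaf
# to the nearest ancestor containing at least one donor-site sample.
score_route_one <- function(clades, met, lymph, primary) {
  holding <- Filter(function(cl) met %in% cl, clades)
  if (!length(holding)) return("uninformative")
  holding <- holding[order(vapply(holding, length, 1L))]
  for (cl in holding) {
    has_l <- any(lymph %in% cl); has_p <- any(primary %in% cl)
    if (has_l || has_p) {
      if (has_l && !has_p) return("lymphatic")
      if (has_p && !has_l) return("hematogenous")
      return("uninformative")
    }
  }
  "uninformative"
}

#' Classify the seeding route of each distant metastasis
#'
#' Applies the topology rule across bootstrap replicates: in a replicate a
#' metastasis votes \emph{lymphatic} when its nearest ancestral split groups
#' it with at least one regional lymph-node sample to the exclusion of all
#' primary samples, \emph{hematogenous} when grouped with a primary to the
#' exclusion of all lymph samples, otherwise the replicate is
#' uninformative. The route is the majority class when its replicate
#' fraction exceeds \code{cutoff} (default 0.75), else \code{ambiguous}.
#' Only pre-treatment samples participate.
#'
#' @param result A \code{metroute_phylo} after \code{\link{bootstrap_supports}}.
#' @param meta Sample metadata data frame (\code{sample_id}, \code{site},
#'   \code{timing}).
#' @param cutoff Probability cutoff for an unambiguous call (default 0.75).
#' @return Data frame of class \code{metroute_routes}: one row per
#'   metastasis sample with \code{p_lymphatic}, \code{p_hematogenous},
#'   \code{p_uninformative} and \code{route}.
#' @export
classify_route <- function(result, meta, cutoff = 0.75) {
  stopifnot(inherits(result, "metroute_phylo"))
  if (is.null(result$replicate_clades))
    stopf("run bootstrap_supports() before classify_route()")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  pre <- meta$timing == "pre_treatment"
  prim <- meta$sample_id[pre & meta$site == "primary"]
  lymph <- meta$sample_id[pre & meta$site == "regional_lymph_node"]
  mets <- meta$sample_id[pre & meta$site == "distant_metastasis"]
  tips <- result$tree$tip.label
  prim <- intersect(prim, tips); lymph <- intersect(lymph, tips)
  mets <- intersect(mets, tips)
  if (!length(prim) || !length(lymph) || !length(mets))
    stopf("route classification needs >=1 pre-treatment primary, lymph and metastasis sample")
  B <- result$B
  out <- data.frame(metastasis_sample = mets, p_lymphatic = NA_real_,
                    p_hematogenous = NA_real_, p_uninformative = NA_real_,
                    route = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_along(mets)) {
    votes <- vapply(result$replicate_clades, score_route_one,
                    "", met = mets[i], lymph = lymph, primary = prim)
    pl <- mean(votes == "lymphatic"); ph <- mean(votes == "hematogenous")
    out$p_lymphatic[i] <- pl; out$p_hematogenous[i] <- ph
    out$p_uninformative[i] <- 1 - pl - ph
    out$route[i] <- if (max(pl, ph) > cutoff) {
      if (pl >= ph) "lymphatic" else "hematogenous"
    } else "ambiguous"
  }
  class(out) <- c("metroute_routes", class(out))
  out
}

#' @export
print.metroute_routes <- function(x, ...) {
  cat("<metroute_routes>\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
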