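cluster_fixture <- function(seed = 1, n1 = 15, n2 = 15, jitter = 0.01) {
  set.seed(seed)
  X <- rbind(
    matrix(rep(c(1, 1, 1), each = n1), n1) + runif(n1 * 3, -jitter, jitter),
    matrix(rep(c(0.4, 0, 0), each = n2), n2) + runif(n2 * 3, -jitter, jitter))
  X <- pmax(X, 0)
  rownames(X) <- paste0("v", seq_len(nrow(X)))
  colnames(X) <- c("Pri1", "Lyn1", "Met1")
  X
}

test_that("DBSCAN separates founding and subclone and applies the size rules", {
  X <- cluster_fixture()
  sub <- cluster_variants(X)
  expect_length(sub$members, 2)
  expect_identical(sub$founding, "C1")
  expect_equal(unname(sub$F["C1", ]), c(1, 1, 1))
  expect_equal(unname(sub$F["C2", ]), c(0.4, 0, 0), tolerance = 0.05)

  # a non-founding cluster of 8 is discarded
  X8 <- rbind(cluster_fixture(), matrix(rep(c(0, 0.7, 0), each = 8), 8) +
                runif(24, -0.01, 0.01))
  rownames(X8) <- paste0("v", seq_len(nrow(X8)))
  sub8 <- cluster_variants(X8)
  expect_length(sub8$members, 2)

  # a founding-like cluster of 5 is retained as founding
  Xf <- rbind(matrix(rep(c(0.97, 0.97, 0.97), each = 5), 5) + runif(15, -0.005, 0.005),
              matrix(rep(c(0.4, 0, 0), each = 15), 15) + runif(45, -0.01, 0.01))
  rownames(Xf) <- paste0("v", seq_len(nrow(Xf)))
  subf <- cluster_variants(Xf)
  expect_identical(subf$founding, "C1")
  expect_length(subf$members[["C1"]], 5)

  # no founding cluster at all
  expect_error(cluster_variants(X * 0.5), "no founding clone")
})

test_that("subclone CCF normalises by the founding clone and clamps", {
  expect_equal(unname(subclone_ccf(c(0.4, 0.4, 0.4), 0.8)), 0.5)
  expect_equal(unname(subclone_ccf(c(0.9, 0.9), 0.8)), 1.0)   # clamped
  expect_error(subclone_ccf(c(0.2), 0), "founding CCF is 0")
})

test_that("adjustable intervals match the closed form and the brute-force oracle", {
  # constant upper gaps 0.1, k = 3: H = F + 3 * 0.1
  lh <- adjustable_interval(F = 0.5, f = rep(0.5, 4), h = rep(0.6, 4),
                            l = rep(0.5, 4))
  expect_equal(unname(lh["H"]), 0.8)
  expect_equal(unname(lh["L"]), 0.5)
  # zero-width CIs collapse the interval
  lh0 <- adjustable_interval(F = 0.3, f = rep(0.3, 6), h = rep(0.3, 6),
                             l = rep(0.3, 6))
  expect_equal(unname(lh0), c(0.3, 0.3))
  # random gaps vs term-by-term evaluation
  set.seed(7)
  for (rep in 1:20) {
    n <- 25
    f <- runif(n); h <- f + runif(n, 0, 0.2); l <- pmax(f - runif(n, 0, 0.2), 0)
    F <- median(f); k <- 3
    Hor <- F + k * sqrt(sum((h - f)^2) / n)
    Lor <- F - k * sqrt(sum((l - f)^2) / n)
    lh <- adjustable_interval(F, f, h, l, k = k)
    expect_equal(unname(lh["H"]), min(Hor, 1.2), tolerance = 1e-12)
    expect_equal(unname(lh["L"]), max(Lor, 0), tolerance = 1e-12)
  }
  expect_error(adjustable_interval(0.5, numeric(0), numeric(0), numeric(0)),
               "no member variants")
})

test_that("interval width is non-decreasing in the expansion factor", {
  set.seed(3)
  f <- runif(10); h <- f + runif(10, 0, 0.1); l <- pmax(f - runif(10, 0, 0.1), 0)
  widths <- vapply(1:6, function(k) {
    lh <- adjustable_interval(median(f), f, h, l, k = k)
    lh["H"] - lh["L"]
  }, numeric(1))
  expect_true(all(diff(widths) >= -1e-12))
})

test_that("pairwise relations follow the pigeonhole and containment rules", {
  r1 <- infer_pairwise_relation(L_i = 0.6, H_i = 0.9, L_j = 0.5, H_j = 0.9)
  expect_identical(as.character(r1), "must_nest")
  r2 <- infer_pairwise_relation(L_i = 0.7, H_i = 0.9, L_j = 0.1, H_j = 0.6)
  expect_identical(as.character(r2), "j_not_parent_of_i")
  r3 <- infer_pairwise_relation(L_i = 0.3, H_i = 0.5, L_j = 0.1, H_j = 0.9)
  expect_identical(as.character(r3), "undetermined")
  # conflict: nesting forced but both containments excluded across samples
  expect_error(infer_pairwise_relation(L_i = c(0.6, 0.8), H_i = c(0.9, 0.9),
                                       L_j = c(0.5, 0.95), H_j = c(0.55, 1.0)),
               "inconsistent")
})

make_sub <- function(Fm, width = 0.02) {
  ids <- rownames(Fm)
  L <- pmax(Fm - width, 0); H <- pmin(Fm + width, 1.2)
  L[1, ] <- 0.9; H[1, ] <- 1.2
  structure(list(members = setNames(as.list(ids), ids), founding = ids[1],
                 F = Fm, L = L, H = H, k = 3),
            class = "metroute_subclones")
}

test_that("tree assembly prefers zero-adjustment placements and forced chains", {
  # two children fitting side by side under the root: star, adjustment 0
  Fm <- rbind(C1 = c(1, 1), C2 = c(0.6, 0.0), C3 = c(0.3, 0.9))
  colnames(Fm) <- c("s1", "s2")
  tr <- build_tree(make_sub(Fm))
  expect_equal(tr$adjustment, 0)
  expect_identical(unname(tr$parent[c("C2", "C3")]), c("C1", "C1"))

  # 0.7 + 0.6 in one sample force a chain (parallel costs 0.3)
  Fm2 <- rbind(C1 = c(1), C2 = c(0.7), C3 = c(0.6))
  colnames(Fm2) <- "s1"
  tr2 <- build_tree(make_sub(Fm2, width = 0.01))
  expect_equal(tr2$adjustment, 0)
  expect_identical(unname(tr2$parent["C3"]), "C2")

  # single subclone: unique two-node chain
  Fm3 <- rbind(C1 = c(1, 1), C2 = c(0.5, 0.4))
  colnames(Fm3) <- c("s1", "s2")
  tr3 <- build_tree(make_sub(Fm3))
  expect_identical(unname(tr3$parent["C2"]), "C1")
  expect_length(tr3$co_minimal, 1)
})

test_that("adjusted CCFs satisfy the sum rule after rescaling", {
  Fm <- rbind(C1 = c(1), C2 = c(0.8), C3 = c(0.75))
  colnames(Fm) <- "s1"
  tr <- build_tree(make_sub(Fm, width = 0.01))
  adj <- tr$F_adjusted
  for (v in rownames(adj)) {
    kids <- names(tr$parent)[!is.na(tr$parent) & tr$parent == v]
    if (length(kids)) {
      pF <- if (v == tr$subclones$founding) 1 else adj[v, ]
      expect_true(all(colSums(adj[kids, , drop = FALSE]) <= pF + 1e-9))
    }
  }
})

test_that("nesting is never forced for truly parallel clones on clean simulations", {
  for (seed in 1:5) {
    sim <- simulate_patient(sim_config(seed = seed, depth_mean = 500,
      n_regions = c(primary = 1, regional_lymph_node = 1, distant_metastasis = 1)))
    pd <- suppressWarnings(impute_across_regions(apply_detection_filter(sim$dataset)))
    ccf <- patient_ccf(pd)
    x <- ccf$ccf; x[is.na(x)] <- 0
    sub <- tryCatch(cluster_variants(x), error = function(e) NULL)
    if (is.null(sub)) next
    sub <- subclone_intervals(sub, ccf$ci_low, ccf$ci_high)
    cl_of <- sim$truth$clone_of_variant
    map <- vapply(sub$members, function(m) {
      tb <- table(cl_of[m]); as.integer(names(tb)[which.max(tb)]) }, 1L)
    truep <- sim$truth$clone_parent
    is_anc <- function(a, d) { p <- truep[d]
      while (!is.na(p)) { if (p == a) return(TRUE); p <- truep[p] }; FALSE }
    ids <- setdiff(names(sub$members), sub$founding)
    for (a in seq_along(ids)) for (b in seq_along(ids)) {
      if (a >= b) next
      i <- ids[a]; j <- ids[b]
      rel <- tryCatch(infer_pairwise_relation(sub$L[i, ], sub$H[i, ],
                                              sub$L[j, ], sub$H[j, ]),
                      error = function(e) "error")
      parallel <- !is_anc(map[[i]], map[[j]]) && !is_anc(map[[j]], map[[i]])
      if (parallel) expect_false(identical(as.character(rel), "must_nest"))
    }
  }
})

test_that("subclone bootstrap is reproducible and saturates on clean signal", {
  sim <- simulate_patient(sim_config(seed = 5, depth_mean = 600,
    n_regions = c(primary = 1, regional_lymph_node = 1, distant_metastasis = 1)))
  pd <- suppressWarnings(impute_across_regions(apply_detection_filter(sim$dataset)))
  ccf <- patient_ccf(pd)
  x <- ccf$ccf; x[is.na(x)] <- 0
  sub <- subclone_intervals(cluster_variants(x), ccf$ci_low, ccf$ci_high)
  tr <- build_tree(sub)
  c1 <- bootstrap_subclone_tree(tr, B = 30, seed = 4)
  c2 <- bootstrap_subclone_tree(tr, B = 30, seed = 4)
  expect_identical(c1, c2)
  expect_gte(c1, 0.9)
  cb1 <- bootstrap_subclone_tree(tr, B = 1, seed = 4)
  expect_true(cb1 %in% c(0, 1))
})

test_that("shared private subclones confirm the seeding route", {
  meta <- data.frame(sample_id = c("Pri1", "Lyn1", "Met1"),
                     site = c("primary", "regional_lymph_node", "distant_metastasis"),
                     timing = "pre_treatment", stringsAsFactors = FALSE)
  Fm <- rbind(C1 = c(1, 1, 1), C2 = c(0.0, 0.4, 0.7))
  colnames(Fm) <- meta$sample_id
  expect_identical(as.character(confirm_route(Fm, meta)), "lymphatic_supported")
  Fm2 <- rbind(C1 = c(1, 1, 1), C2 = c(0.5, 0.0, 0.3))
  colnames(Fm2) <- meta$sample_id
  expect_identical(as.character(confirm_route(Fm2, meta)), "hematogenous_supported")
  Fm3 <- rbind(C1 = c(1, 1, 1), C2 = c(0.5, 0.0, 0.0))
  colnames(Fm3) <- meta$sample_id
  expect_identical(as.character(confirm_route(Fm3, meta)), "unresolved")
})

test_that("the true clone tree is recovered on dense, well-separated simulations", {
  # Depth chosen so per-variant CCF noise is small against the 0.05 support
  # radius; DBSCAN chaining needs dense clusters (see the methods vignette).
  ok <- 0; n <- 20
  for (i in seq_len(n)) {
    route <- if (i %% 2) "lymphatic" else "hematogenous"
    sim <- simulate_patient(sim_config(seed = 700 + i, route = route,
      depth_mean = 400,
      n_regions = c(primary = 1, regional_lymph_node = 1, distant_metastasis = 1)))
    good <- tryCatch({
      pd <- suppressWarnings(impute_across_regions(apply_detection_filter(sim$dataset)))
      ccf <- patient_ccf(pd)
      x <- ccf$ccf; x[is.na(x)] <- 0
      sub <- subclone_intervals(cluster_variants(x), ccf$ci_low, ccf$ci_high)
      tr <- build_tree(sub)
      cl_of <- sim$truth$clone_of_variant
      map <- vapply(sub$members, function(m) {
        tb <- table(cl_of[m]); as.integer(names(tb)[which.max(tb)]) }, 1L)
      rec <- vapply(names(tr$parent), function(id) {
        p <- tr$parent[[id]]; if (is.na(p)) NA_integer_ else map[[p]] }, 1L)
      names(rec) <- map[names(tr$parent)]
      truep <- sim$truth$clone_parent
      length(rec) == 5 && length(unique(names(rec))) == 5 &&
        all(vapply(seq_along(rec), function(j) {
          cl <- as.integer(names(rec)[j])
          if (cl == 1) is.na(rec[j]) else identical(rec[[j]], truep[cl])
        }, TRUE))
    }, error = function(e) FALSE)
    if (isTRUE(good)) ok <- ok + 1
  }
  expect_gte(ok / n, 0.9)
})
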