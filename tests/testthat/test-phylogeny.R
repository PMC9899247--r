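nested_matrix <- function() {
  # trunk 10; A,B-shared 6; privates A 3, B 2, C 4, D 5
  mk <- function(n, rows) { m <- matrix(0L, 4, n); m[rows, ] <- 1L; m }
  D <- cbind(mk(10, 1:4), mk(6, 1:2), mk(3, 1), mk(2, 2), mk(4, 3), mk(5, 4))
  dimnames(D) <- list(c("A", "B", "C", "D"), sprintf("chr1:%d:A>T", seq_len(ncol(D))))
  D
}

test_that("LOH-aware filtering removes only confounded mutations", {
  D <- rbind(Pri1 = c(1L, 1L, 1L),
             Lyn1 = c(0L, 1L, 0L),   # v1/v3 absent here; LOH covers chr1 only
             Met1 = c(1L, 1L, 1L))
  colnames(D) <- c("chr1:150:A>T", "chr1:160:A>T", "chr2:150:A>T")
  loh <- data.frame(chrom = "chr1", start = 100L, end = 200L, sample_id = "Lyn1")
  out <- filter_loh_confounded(D, loh)
  expect_identical(colnames(out), c("chr1:160:A>T", "chr2:150:A>T"))
  expect_identical(filter_loh_confounded(D, NULL), D)
  expect_identical(filter_loh_confounded(D, loh[0, ]), D)
})

test_that("NJ recovers the hand-computed 4-taxon topology with mutation-count lengths", {
  D <- nested_matrix()
  # Hamming distances, by hand: AB 5, AC 13, BC 12, AD 14, BD 13, CD 9,
  # A-germ 19, B-germ 18, C-germ 14, D-germ 15; NJ joins (A,B) first.
  expect_equal(unname(as.matrix(dist(rbind(D, germline = 0L),
                                     method = "manhattan"))["A", "B"]), 5)
  ph <- nj_tree(D)
  tr <- ph$tree
  clades <- lapply((length(tr$tip.label) + 1):(length(tr$tip.label) + tr$Nnode),
                   function(n) sort(ape::extract.clade(tr, n)$tip.label))
  has_clade <- function(x) any(vapply(clades, identical, logical(1), x))
  expect_true(has_clade(c("A", "B")))
  expect_true(has_clade(c("A", "B", "C")))
  expect_true(has_clade(c("A", "B", "C", "D")))
  # branch lengths are uniquely-shared mutation counts
  edge_len <- function(tips) {
    nd <- ape::getMRCA(tr, tips)
    if (length(tips) == 1) nd <- which(tr$tip.label == tips)
    tr$edge.length[tr$edge[, 2] == nd]
  }
  expect_equal(edge_len("A"), 3)
  expect_equal(edge_len("B"), 2)
  expect_equal(edge_len("C"), 4)
  expect_equal(edge_len("D"), 5)
  expect_equal(edge_len(c("A", "B")), 6)
  expect_equal(edge_len(c("A", "B", "C", "D")), 10)
})

test_that("degenerate matrices behave: identical rows, trunk-only, too few samples", {
  D <- nested_matrix()
  D["B", ] <- D["A", ]
  ph <- nj_tree(D)
  nd <- ape::getMRCA(ph$tree, c("A", "B"))
  kids_edges <- ph$tree$edge[, 1] == nd
  expect_true(all(ph$tree$edge.length[ph$tree$edge[, 2] %in%
    which(ph$tree$tip.label %in% c("A", "B"))] == 0))

  Dt <- matrix(1L, 3, 7, dimnames = list(c("A", "B", "C"),
                                         sprintf("chr1:%d:A>T", 1:7)))
  pht <- nj_tree(Dt)
  lens <- pht$tree$edge.length
  expect_equal(sum(lens), 7)  # trunk carries all mutations, others zero
  expect_equal(sort(lens, decreasing = TRUE)[1], 7)

  expect_error(nj_tree(D[1:2, ]), ">= 3 samples")
  Dna <- D; Dna[1, 1] <- NA
  expect_error(nj_tree(Dna), "NA")
})

test_that("bootstrap supports are deterministic and saturate on clean signal", {
  D <- nested_matrix()
  ph1 <- bootstrap_supports(nj_tree(D), B = 100, seed = 3)
  ph2 <- bootstrap_supports(nj_tree(D), B = 100, seed = 3)
  expect_identical(ph1$support, ph2$support)
  expect_true(all(ph1$support >= 0 & ph1$support <= 1))
  # >= 2 mutations per discriminating branch here; supports need not be 1,
  # but with 20+ per branch they must saturate (checked in acceptance too)
  wide <- nested_matrix()[, rep(seq_len(30), 3)]
  colnames(wide) <- sprintf("chr1:%d:A>T", seq_len(ncol(wide)))
  phw <- bootstrap_supports(nj_tree(wide), B = 100, seed = 3)
  expect_true(all(phw$support == 1))
  expect_error(bootstrap_supports(nj_tree(D), B = 0), ">= 1 bootstrap")
})

test_that("route classification applies the clade rule and the 0.75 cutoff", {
  meta <- data.frame(sample_id = c("Pri1", "Lyn1", "Met1"),
                     site = c("primary", "regional_lymph_node", "distant_metastasis"),
                     timing = "pre_treatment", stringsAsFactors = FALSE)
  sim <- simulate_patient(sim_config(seed = 21, route = "lymphatic",
    n_regions = c(primary = 1, regional_lymph_node = 1, distant_metastasis = 1)))
  pd <- impute_across_regions(apply_detection_filter(sim$dataset))
  ph <- bootstrap_supports(nj_tree(presence_matrix(pd)), B = 50, seed = 2)
  rc <- classify_route(ph, pd$samples)
  expect_identical(rc$route, "lymphatic")
  expect_gt(rc$p_lymphatic, 0.75)
  expect_equal(rc$p_lymphatic + rc$p_hematogenous + rc$p_uninformative, 1)

  simh <- simulate_patient(sim_config(seed = 22, route = "hematogenous",
    n_regions = c(primary = 1, regional_lymph_node = 1, distant_metastasis = 1)))
  pdh <- impute_across_regions(apply_detection_filter(simh$dataset))
  phh <- bootstrap_supports(nj_tree(presence_matrix(pdh)), B = 50, seed = 2)
  rch <- classify_route(phh, pdh$samples)
  expect_identical(rch$route, "hematogenous")

  # synthetic replicate votes straddling the cutoff -> ambiguous
  fake <- ph
  lymclade <- list(`1` = c("Lyn1", "Met1"), `2` = c("Lyn1", "Met1", "Pri1"))
  hemclade <- list(`1` = c("Met1", "Pri1"), `2` = c("Lyn1", "Met1", "Pri1"))
  fake$replicate_clades <- c(rep(list(lymclade), 6), rep(list(hemclade), 4))
  fake$B <- 10L
  rcf <- classify_route(fake, meta)
  expect_identical(rcf$route, "ambiguous")
  expect_equal(rcf$p_lymphatic, 0.6)
  expect_equal(rcf$p_hematogenous, 0.4)

  expect_error(classify_route(ph, meta[meta$site != "primary", ]),
               "needs >=\\s?1")
})
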