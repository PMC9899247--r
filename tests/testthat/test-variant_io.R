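test_that("TSV reader builds a rectangular dataset and round-trips", {
  sim <- simulate_patient(sim_config(seed = 11, n_clones = 3,
                                     mutations_per_clone = 5, depth_mean = 80))
  pd <- sim$dataset
  path <- tempfile(fileext = ".tsv")
  write_variant_table(pd, path)
  rt <- read_variant_table(path, format = "tsv")
  expect_identical(dim(rt$alt_reads), dim(pd$alt_reads))
  expect_equal(rt$alt_reads, pd$alt_reads)
  expect_equal(rt$depth, pd$depth)
  expect_equal(rt$status, pd$status)
  expect_identical(rt$samples$site, pd$samples$site)
  expect_identical(rt$variants$variant_id, pd$variants$variant_id)
})

test_that("TSV shape follows the input and malformed input is rejected", {
  tab <- data.frame(patient = "P1",
                    sample = rep(c("Pri1", "Lyn1", "Met1"), each = 5),
                    site = rep(c("primary", "regional_lymph_node",
                                 "distant_metastasis"), each = 5),
                    region = 1L, timing = "pre_treatment",
                    chrom = "chr1", pos = rep(1:5 * 100L, 3),
                    ref = "A", alt = "G",
                    alt_reads = 10L, depth = 50L)
  path <- tempfile(fileext = ".tsv")
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  pd <- read_variant_table(path)
  expect_identical(dim(pd$alt_reads), c(5L, 3L))

  # empty file
  empty <- tempfile(); writeLines(paste(names(tab), collapse = "\t"), empty)
  expect_error(read_variant_table(empty), "no variants")

  # alt_reads > depth names the line
  bad <- tab; bad$alt_reads[3] <- 99L
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_variant_table(path), "alt_reads > depth at line 4")

  # unknown site label
  bad <- tab; bad$site[1] <- "liver"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_variant_table(path), "unknown site")

  # malformed numeric names the line
  bad <- tab; bad$pos <- as.character(bad$pos); bad$pos[2] <- "oops"
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_variant_table(path), "line 3")
})

test_that("VCF route reproduces the TSV observation matrix", {
  samples <- c("Pri1", "Lyn1", "Met1")
  pos <- c(100L, 200L, 300L, 400L)
  alt <- matrix(c(10, 0, 5, 7,
                  8, 3, 0, 7,
                  0, 4, 6, 7), 4, 3)
  dp <- matrix(50L, 4, 3)
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  for (i in seq_along(pos)) {
    cells <- vapply(1:3, function(s)
      sprintf("0/1:%d,%d:%d", dp[i, s] - alt[i, s], alt[i, s], dp[i, s]), "")
    vcf_lines <- c(vcf_lines,
      paste(c("chr1", pos[i], ".", "A", "T", ".", "PASS", ".", "GT:AD:DP", cells),
            collapse = "\t"))
  }
  vpath <- tempfile(fileext = ".vcf")
  writeLines(vcf_lines, vpath)
  meta <- data.frame(sample_id = samples,
                     site = c("primary", "regional_lymph_node", "distant_metastasis"),
                     region = 1L, timing = "pre_treatment",
                     stringsAsFactors = FALSE)
  pd <- read_variant_table(vpath, format = "vcf", meta = meta)
  expect_identical(unname(pd$alt_reads), matrix(as.integer(alt), 4, 3))
  expect_identical(unname(pd$depth), matrix(50L, 4, 3))
  expect_identical(pd$variants$variant_id, sprintf("chr1:%d:A>T", pos))
})

test_that("detection filter applies the read-support and Fisher rules", {
  pd <- make_tiny_patient(n_var = 4)  # 20/100 vs 0/100 in columns 2 and 3
  pd$alt_reads[, 1] <- 0L
  pd$alt_reads[1, 1] <- 6L   # 6/100 vs 0/100 -> significant
  pd$alt_reads[2, 1] <- 4L   # below the >= 5 support rule
  pd$alt_reads[3, 1] <- 5L   # 5/100 vs 0/100: check against the oracle
  pd$alt_reads[4, 1] <- 30L
  out <- apply_detection_filter(pd)
  p6 <- fisher_p_oracle(6, 94, 0, 100)
  expect_lt(p6, 0.05)
  expect_equal(p6, fisher.test(matrix(c(6, 94, 0, 100), 2, byrow = TRUE))$p.value,
               tolerance = 1e-10)
  expect_identical(out$status[1, 1], "detected")
  expect_identical(out$status[2, 1], "absent")
  p5 <- fisher_p_oracle(5, 95, 0, 100)
  expect_identical(out$status[3, 1], if (p5 < 0.05) "detected" else "absent")
  expect_identical(out$status[4, 1], "detected")
  expect_true(all(out$status[, 2:3] == "detected"))  # 20/100 vs 0/100
})

test_that("detection is monotone in supporting reads at fixed depth", {
  pd <- make_tiny_patient(n_var = 1)
  states <- vapply(0:40, function(a) {
    pd$alt_reads[1, 1] <- a
    apply_detection_filter(pd)$status[1, 1] == "detected"
  }, logical(1))
  expect_false(any(diff(states) < 0))  # never detected -> not detected
})

test_that("detection filter demands matched-normal counts", {
  pd <- make_tiny_patient(with_normal = FALSE)
  expect_error(apply_detection_filter(pd), "normal")
})

test_that("newick output round-trips and escapes awkward names", {
  D <- matrix(c(1, 1, 0,
                1, 1, 0,
                0, 0, 1,
                1, 0, 0), 3, 4,
              dimnames = list(c("A", "B", "C"), sprintf("chr1:%d:A>T", 1:4)))
  ph <- bootstrap_supports(nj_tree(D), B = 20, seed = 5)
  path <- tempfile(fileext = ".nwk")
  write_newick(ph, path)
  rt <- ape::read.tree(path)
  expect_true(ape::all.equal.phylo(rt, ph$tree, use.edge.length = FALSE))
  expect_identical(sort(as.numeric(rt$node.label)), sort(unname(ph$support)))

  rownames(D) <- c("Pri 1", "B", "C")
  ph2 <- nj_tree(D)
  write_newick(ph2, path)
  rt2 <- ape::read.tree(path)
  expect_true("Pri_1" %in% rt2$tip.label)  # newick space escaping convention
})
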