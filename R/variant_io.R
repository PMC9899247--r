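#' Assemble a multi-region patient dataset
#'
#' The central container of the package: all tumour samples of one patient
#' together with the rectangular variant-by-sample observation matrices.
#' Variant coordinates are 1-based inclusive (VCF convention) and encoded in
#' the canonical variant id \code{chrom:pos:ref>alt}; LOH intervals use
#' 0-based half-open BED coordinates.
#'
#' @param patient_id Patient identifier.
#' @param samples Data frame with columns \code{sample_id}, \code{site}
#'   (\code{primary}, \code{regional_lymph_node} or \code{distant_metastasis}),
#'   \code{region} (integer region index >= 1), \code{timing}
#'   (\code{pre_treatment}/\code{post_treatment}) and optionally \code{purity}
#'   in (0, 1].
#' @param variants Data frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} and optionally matched-normal counts
#'   \code{normal_alt}, \code{normal_depth}.
#' @param alt_reads,depth Integer matrices (variants x samples) of supporting
#'   and total read counts; every variant must have a slot in every sample
#'   (use depth 0 for sites with no pileup).
#' @param status Optional character matrix of per-cell detection status
#'   (\code{detected}, \code{rescued}, \code{absent}, \code{NA}); defaults to
#'   \code{detected} wherever \code{alt_reads > 0}, \code{absent} otherwise.
#' @param copy_number Optional integer matrix of per-variant total copy
#'   number per sample (default 2).
#' @param multiplicity Optional integer matrix of mutation multiplicity
#'   (default 1, diploid heterozygous baseline).
#' @param loh Optional data frame of LOH segments with columns \code{chrom},
#'   \code{start}, \code{end}, \code{sample_id} (BED convention).
#' @return An object of class \code{metroute_patient}.
#' @export
patient_dataset <- function(patient_id, samples, variants, alt_reads, depth,
                            status = NULL, copy_number = NULL,
                            multiplicity = NULL, loh = NULL) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("sample_id", "site", "region", "timing")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stopf("samples is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id))
    stopf("duplicate sample_id within patient %s", patient_id)
  check_site(samples$site); check_timing(samples$timing)
  if (is.null(samples$purity)) samples$purity <- NA_real_
  if (any(!is.na(samples$purity) & (samples$purity <= 0 | samples$purity > 1)))
    stopf("purity must lie in (0, 1]")

  if (is.null(variants$variant_id))
    variants$variant_id <- sprintf("%s:%d:%s>%s", variants$chrom,
                                   as.integer(variants$pos), variants$ref, variants$alt)
  if (anyDuplicated(variants$variant_id))
    stopf("duplicate variant ids in patient %s", patient_id)

  V <- nrow(variants); S <- nrow(samples)
  shape <- function(m, what) {
    m <- as.matrix(m)
    if (!all(dim(m) == c(V, S)))
      stopf("%s must be a %d x %d matrix (variants x samples)", what, V, S)
    dimnames(m) <- list(variants$variant_id, samples$sample_id)
    m
  }
  alt_reads <- shape(alt_reads, "alt_reads")
  depth <- shape(depth, "depth")
  if (any(alt_reads < 0) || any(depth < 0)) stopf("read counts must be non-negative")
  if (any(alt_reads > depth))
    stopf("alt_reads exceeds depth for %d cell(s)", sum(alt_reads > depth))
  if (is.null(status)) {
    status <- matrix(ifelse(alt_reads > 0, "detected", "absent"), V, S)
  }
  status <- shape(status, "status")
  bad <- setdiff(unique(as.vector(status)), STATUS_LEVELS)
  if (length(bad)) stopf("unknown status value(s): %s", paste(bad, collapse = ", "))
  copy_number <- if (is.null(copy_number)) shape(matrix(2L, V, S), "copy_number")
                 else shape(copy_number, "copy_number")
  multiplicity <- if (is.null(multiplicity)) shape(matrix(1L, V, S), "multiplicity")
                  else shape(multiplicity, "multiplicity")
  if (!is.null(loh)) {
    loh <- as.data.frame(loh, stringsAsFactors = FALSE)
    lmiss <- setdiff(c("chrom", "start", "end", "sample_id"), names(loh))
    if (length(lmiss)) stopf("loh is missing column(s): %s", paste(lmiss, collapse = ", "))
  }
  structure(list(patient_id = patient_id, samples = samples, variants = variants,
                 alt_reads = alt_reads, depth = depth, status = status,
                 copy_number = copy_number, multiplicity = multiplicity,
                 loh = loh),
            class = "metroute_patient")
}

#' @export
print.metroute_patient <- function(x, ...) {
  cat(sprintf("<metroute_patient> %s: %d variants x %d samples\n",
              x$patient_id, nrow(x$variants), nrow(x$samples)))
  tab <- table(factor(x$samples$site, levels = SITE_LEVELS))
  cat(sprintf("  sites: %s\n",
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  st <- table(factor(x$status, levels = STATUS_LEVELS))
  cat(sprintf("  status: %s\n",
              paste(sprintf("%s=%d", names(st), st), collapse = ", ")))
  invisible(x)
}

#' Read a per-patient multi-sample variant table
#'
#' Reads either the package's TSV dialect (long format, one row per variant
#' per sample) or a multi-sample VCF with \code{AD}/\code{DP} FORMAT fields,
#' and assembles a rectangular \code{\link{patient_dataset}}. Variants
#' observed in no sample are dropped. Cells with no row in the TSV are
#' filled with \code{alt_reads = 0, depth = 0} (no pileup; they become
#' \code{NA} at imputation).
#'
#' @param path Path to the input file.
#' @param format \code{"tsv"} (default) or \code{"vcf"}.
#' @param meta For VCF input (which cannot carry site annotations), a data
#'   frame of sample metadata with columns \code{sample_id}, \code{site},
#'   \code{region}, \code{timing} and optionally \code{purity}. Ignored for
#'   TSV input, where the columns are part of the table.
#' @return A \code{metroute_patient}.
#' @details The TSV dialect has columns \code{patient}, \code{sample},
#'   \code{site}, \code{region}, \code{timing}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{alt_reads}, \code{depth}, and optionally
#'   \code{normal_alt}, \code{normal_depth}, \code{purity}, \code{total_cn},
#'   \code{multiplicity}, \code{status}. Coordinates are 1-based.
#' @export
read_variant_table <- function(path, format = c("tsv", "vcf"), meta = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "tsv") read_variant_tsv(path) else read_variant_vcf(path, meta)
}

read_variant_tsv <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stopf("failed to parse %s: %s", path, conditionMessage(e)))
  if (nrow(tab) == 0) stopf("no variants in %s", path)
  need <- c("patient", "sample", "site", "region", "timing",
            "chrom", "pos", "ref", "alt", "alt_reads", "depth")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stopf("TSV is missing column(s): %s", paste(miss, collapse = ", "))
  for (col in c("pos", "region", "alt_reads", "depth")) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    if (anyNA(v)) {
      line <- which(is.na(v))[1] + 1L  # +1 for header
      stopf("malformed value in column '%s' at line %d of %s", col, line, path)
    }
    tab[[col]] <- v
  }
  bad <- which(tab$alt_reads > tab$depth)
  if (length(bad)) stopf("alt_reads > depth at line %d of %s", bad[1] + 1L, path)
  pid <- unique(tab$patient)
  if (length(pid) != 1)
    stopf("expected one patient per table, found %d (%s)", length(pid),
          paste(pid, collapse = ", "))

  first <- !duplicated(tab$sample)
  samples <- data.frame(sample_id = tab$sample[first], site = tab$site[first],
                        region = tab$region[first], timing = tab$timing[first],
                        stringsAsFactors = FALSE)
  if (!is.null(tab$purity)) samples$purity <- as.numeric(tab$purity[first])
  vid <- sprintf("%s:%d:%s>%s", tab$chrom, tab$pos, tab$ref, tab$alt)
  vfirst <- !duplicated(vid)
  variants <- data.frame(variant_id = vid[vfirst], chrom = tab$chrom[vfirst],
                         pos = tab$pos[vfirst], ref = tab$ref[vfirst],
                         alt = tab$alt[vfirst], stringsAsFactors = FALSE)
  if (!is.null(tab$normal_alt)) variants$normal_alt <- as.integer(tab$normal_alt[vfirst])
  if (!is.null(tab$normal_depth)) variants$normal_depth <- as.integer(tab$normal_depth[vfirst])

  V <- nrow(variants); S <- nrow(samples)
  ii <- match(vid, variants$variant_id)
  jj <- match(tab$sample, samples$sample_id)
  fill <- function(col, default) {
    m <- matrix(default, V, S)
    m[cbind(ii, jj)] <- tab[[col]]
    m
  }
  alt_m <- fill("alt_reads", 0L)
  dp_m <- fill("depth", 0L)
  cn_m <- if (!is.null(tab$total_cn)) fill("total_cn", 2L) else NULL
  mult_m <- if (!is.null(tab$multiplicity)) fill("multiplicity", 1L) else NULL
  status_m <- if (!is.null(tab$status)) {
    m <- matrix("absent", V, S); m[cbind(ii, jj)] <- tab$status; m
  } else NULL

  keep <- rowSums(alt_m > 0) > 0
  if (!any(keep)) stopf("no variants observed in any sample in %s", path)
  pd <- patient_dataset(pid, samples, variants[keep, , drop = FALSE],
                        alt_m[keep, , drop = FALSE], dp_m[keep, , drop = FALSE],
                        status = if (is.null(status_m)) NULL else status_m[keep, , drop = FALSE],
                        copy_number = if (is.null(cn_m)) NULL else cn_m[keep, , drop = FALSE],
                        multiplicity = if (is.null(mult_m)) NULL else mult_m[keep, , drop = FALSE])
  pd
}

read_variant_vcf <- function(path, meta) {
  if (is.null(meta))
    stopf("VCF input needs a 'meta' data frame (sample_id, site, region, timing)")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) stopf("no variants in %s", path)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  dp <- vcfR::extract.gt(vcf, element = "DP", as.numeric = TRUE)
  if (is.null(ad) || is.null(dp)) stopf("VCF must carry AD and DP FORMAT fields")
  alt_m <- apply(ad, 2, function(col) {
    vapply(strsplit(col, ","), function(p)
      if (length(p) >= 2) suppressWarnings(as.integer(p[2])) else NA_integer_, 1L)
  })
  alt_m[is.na(alt_m)] <- 0L
  dp[is.na(dp)] <- 0L
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  ord <- match(colnames(alt_m), meta$sample_id)
  if (anyNA(ord))
    stopf("meta lacks sample(s): %s",
          paste(setdiff(colnames(alt_m), meta$sample_id), collapse = ", "))
  meta <- meta[ord, , drop = FALSE]
  keep <- rowSums(alt_m > 0) > 0
  if (!any(keep)) stopf("no variants observed in any sample in %s", path)
  pid <- meta$patient_id %||% meta$patient %||% "patient"
  patient_dataset(pid[1], meta, variants[keep, , drop = FALSE],
                  alt_m[keep, , drop = FALSE],
                  matrix(as.integer(dp[keep, , drop = FALSE]), sum(keep), ncol(dp)))
}

#' Read LOH segments from a 4-column BED-like file
#'
#' Columns: chrom, start, end, sample_id; 0-based half-open intervals.
#' @param path Path to the BED file (no header).
#' @return Data frame with columns chrom, start, end, sample_id.
#' @export
read_loh_bed <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "sample_id"))
  bed$start <- as.integer(bed$start); bed$end <- as.integer(bed$end)
  if (any(bed$end <= bed$start)) stopf("LOH intervals must satisfy start < end")
  bed
}

#' Apply the somatic detection filter
#'
#' A variant is marked \code{detected} in a sample when it has at least
#' \code{min_alt} supporting reads and the two-sided Fisher exact test on the
#' 2x2 table (tumour alt/ref vs matched-normal alt/ref) gives
#' \code{P < p_cutoff}; all other cells are set \code{absent}, pending
#' cross-region imputation. The 2x2 orientation and sidedness are the
#' standard somatic-call construction and are configurable.
#'
#' @param dataset A \code{metroute_patient} whose \code{variants} carry
#'   \code{normal_alt} and \code{normal_depth} columns.
#' @param min_alt Minimum supporting reads (default 5).
#' @param p_cutoff Fisher test threshold (default 0.05).
#' @param alternative Sidedness of the Fisher test (default two-sided).
#' @return The dataset with an updated \code{status} matrix.
#' @export
apply_detection_filter <- function(dataset, min_alt = 5L, p_cutoff = 0.05,
                                   alternative = "two.sided") {
  stopifnot(inherits(dataset, "metroute_patient"))
  v <- dataset$variants
  if (is.null(v$normal_alt) || is.null(v$normal_depth))
    stopf(paste("matched-normal counts (normal_alt, normal_depth) are missing;",
                "supply them or skip apply_detection_filter()"))
  alt <- dataset$alt_reads; dp <- dataset$depth
  V <- nrow(alt); S <- ncol(alt)
  det <- matrix(FALSE, V, S)
  cand <- which(alt >= min_alt, arr.ind = TRUE)
  if (nrow(cand)) {
    # Fisher P depends only on the 2x2 table; cache repeated tables.
    key <- sprintf("%d|%d|%d|%d", alt[cand], dp[cand],
                   v$normal_alt[cand[, 1]], v$normal_depth[cand[, 1]])
    uniq <- !duplicated(key)
    pv_u <- vapply(which(uniq), function(k) {
      i <- cand[k, 1]; j <- cand[k, 2]
      tab <- matrix(c(alt[i, j], dp[i, j] - alt[i, j],
                      v$normal_alt[i], v$normal_depth[i] - v$normal_alt[i]),
                    2, 2, byrow = TRUE)
      stats::fisher.test(tab, alternative = alternative)$p.value
    }, numeric(1))
    pv <- pv_u[match(key, key[uniq])]
    det[cand] <- pv < p_cutoff
  }
  dataset$status <- matrix(ifelse(det, "detected", "absent"), V, S,
                           dimnames = dimnames(alt))
  dataset
}

#' Write a phylogeny with bootstrap supports as newick
#'
#' Branch lengths carry shared-mutation counts; internal node labels carry
#' bootstrap support fractions. The file round-trips through standard newick
#' readers (\code{ape::read.tree}).
#'
#' @param tree A \code{metroute_phylo} (see \code{\link{nj_tree}}) or an
#'   \code{ape} \code{phylo} object.
#' @param path Output file path.
#' @return Invisibly, the newick string written.
#' @export
write_newick <- function(tree, path) {
  phy <- if (inherits(tree, "metroute_phylo")) tree$tree else tree
  if (!inherits(phy, "phylo")) stopf("not a phylogeny")
  if (inherits(tree, "metroute_phylo") && !is.null(tree$support)) {
    phy$node.label <- ifelse(is.na(tree$support), "", format(tree$support, trim = TRUE))
  }
  ok <- tryCatch({ ape::write.tree(phy, file = path); TRUE },
                 error = function(e) stopf("cannot write %s: %s", path, conditionMessage(e)))
  invisible(ape::write.tree(phy))
}
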