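#' Cross-region variant imputation ("fetch-back")
#'
#' Multi-region sampling lets a mutation confidently called in one region be
#' recovered in sibling regions where it fell below the caller's threshold.
#' For every cell not already \code{detected}: the variant is \code{rescued}
#' when the mutant read count is >= \code{min_alt} and the depth is
#' > \code{min_depth}; the cell is \code{NA} when depth <= \code{min_depth}
#' (too shallow to decide); otherwise it is \code{absent} (adequate depth,
#' insufficient support). Imputation runs per patient across all of that
#' patient's tumour samples. Variants detected in no sample are dropped.
#'
#' @param dataset A \code{metroute_patient} with the detection filter already
#'   applied (or simulator output, where detected status is emitted).
#' @param min_alt Rescue support threshold (default 3).
#' @param min_depth Depth above which a site is decidable (default 10;
#'   rescue requires depth > 10, depth <= 10 gives NA).
#' @return The dataset with an updated status matrix; idempotent.
#' @export
impute_across_regions <- function(dataset, min_alt = 3L, min_depth = 10L) {
  stopifnot(inherits(dataset, "metroute_patient"))
  st <- dataset$status
  alt <- dataset$alt_reads; dp <- dataset$depth
  open <- st != "detected"
  rescued <- open & alt >= min_alt & dp > min_depth
  shallow <- open & !rescued & dp <= min_depth
  st[rescued] <- "rescued"
  st[shallow] <- "NA"
  st[open & !rescued & !shallow] <- "absent"
  keep <- rowSums(st == "detected") > 0
  n_na <- sum(st[keep, , drop = FALSE] == "NA" & dp[keep, , drop = FALSE] == 0)
  if (n_na > 0)
    warnf("%d cell(s) had no pileup (depth 0) and were marked NA", n_na)
  dataset$status <- st[keep, , drop = FALSE]
  dataset$alt_reads <- alt[keep, , drop = FALSE]
  dataset$depth <- dp[keep, , drop = FALSE]
  dataset$copy_number <- dataset$copy_number[keep, , drop = FALSE]
  dataset$multiplicity <- dataset$multiplicity[keep, , drop = FALSE]
  dataset$variants <- dataset$variants[keep, , drop = FALSE]
  dataset
}

#' Binary presence matrix for phylogeny construction
#'
#' Builds the samples x mutations 0/1 matrix D used by the neighbour-joining
#' step: \code{D[i, j] = 1} iff mutation j is \code{detected} or
#' \code{rescued} in sample i. Under the default \code{drop_variant} policy
#' any mutation with an undecidable (\code{NA}) cell is removed, so only
#' mutations whose information is available across all samples enter the
#' tree; \code{treat_absent} instead codes NA cells as 0.
#'
#' @param dataset An imputed \code{metroute_patient}.
#' @param na_policy \code{"drop_variant"} (default) or \code{"treat_absent"}.
#' @return Integer matrix, samples in rows, mutations in columns.
#' @export
presence_matrix <- function(dataset, na_policy = c("drop_variant", "treat_absent")) {
  stopifnot(inherits(dataset, "metroute_patient"))
  na_policy <- match.arg(na_policy)
  st <- dataset$status
  if (na_policy == "drop_variant") {
    keep <- rowSums(st == "NA") == 0
    st <- st[keep, , drop = FALSE]
  }
  if (nrow(st) == 0) stopf("no informative mutations after NA filtering")
  D <- t((st == "detected" | st == "rescued") * 1L)
  dimnames(D) <- list(colnames(dataset$status), rownames(st))
  D
}
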