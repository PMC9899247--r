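#' Estimate cancer cell fraction (CCF) from read counts
#'
#' A deliberately simple purity/copy-number CCF estimator: the variant allele
#' fraction is mapped through
#' \deqn{CCF = VAF \cdot \frac{\rho C_t + (1-\rho) 2}{\rho m}}
#' with tumour purity \eqn{\rho}, locus total copy number \eqn{C_t} and
#' mutation multiplicity \eqn{m} (default 1, the diploid heterozygous
#' baseline). The point estimate is clamped to [0, 1.5]. The 95\% interval is
#' the exact binomial (Clopper-Pearson) interval on the VAF pushed through
#' the same linear map. Variants with zero supporting reads (or
#' \code{status = "absent"}) are \code{absent} with CCF 0.
#'
#' Vectorised over its arguments.
#'
#' @param alt_reads,depth Read counts (depth 0 gives an absent call with
#'   undefined CCF).
#' @param purity Tumour purity in (0, 1].
#' @param total_cn Total copy number at the locus (>= 1).
#' @param multiplicity Mutation multiplicity (>= 1).
#' @param conf Confidence level (default 0.95).
#' @param clamp Upper clamp on CCF and its bounds (default 1.5).
#' @return Data frame with columns \code{ccf}, \code{ci_low}, \code{ci_high},
#'   \code{clonality} (\code{clonal}/\code{subclonal}/\code{absent}).
#' @export
estimate_ccf <- function(alt_reads, depth, purity, total_cn = 2L,
                         multiplicity = 1L, conf = 0.95, clamp = 1.5) {
  n <- max(length(alt_reads), length(depth), length(purity),
           length(total_cn), length(multiplicity))
  alt_reads <- rep_len(alt_reads, n); depth <- rep_len(depth, n)
  purity <- rep_len(purity, n); total_cn <- rep_len(total_cn, n)
  multiplicity <- rep_len(multiplicity, n)
  if (any(purity <= 0 | purity > 1)) stopf("purity must lie in (0, 1]")
  if (any(multiplicity < 1) || any(total_cn < 1))
    stopf("total_cn and multiplicity must be >= 1")

  alpha <- (1 - conf) / 2
  vaf <- ifelse(depth > 0, alt_reads / depth, NA_real_)
  # Clopper-Pearson bounds on the VAF
  lo <- ifelse(alt_reads == 0, 0, stats::qbeta(alpha, alt_reads, depth - alt_reads + 1))
  hi <- ifelse(alt_reads == depth & depth > 0, 1,
               stats::qbeta(1 - alpha, alt_reads + 1, pmax(depth - alt_reads, 1)))
  scale <- (purity * total_cn + (1 - purity) * 2) / (purity * multiplicity)
  cl <- function(x) pmin(pmax(x, 0), clamp)
  ccf <- cl(vaf * scale); ci_low <- cl(lo * scale); ci_high <- cl(hi * scale)

  clonality <- rep("subclonal", n)
  clonality[ci_high >= 1] <- "clonal"   # CI overlaps 1, or lies entirely above it
  absent <- depth == 0 | alt_reads == 0
  clonality[absent] <- "absent"
  ccf[alt_reads == 0 & depth > 0] <- 0
  ci_low[absent] <- NA_real_; ci_high[absent] <- NA_real_
  ccf[depth == 0] <- NA_real_
  data.frame(ccf = ccf, ci_low = ci_low, ci_high = ci_high,
             clonality = clonality, stringsAsFactors = FALSE)
}

#' Clonality from a CCF confidence interval
#'
#' A variant is \code{clonal} when the 95\% CI of its CCF overlaps 1 (which,
#' with the lower bound never above the upper, reduces to \code{ci_high >= 1};
#' intervals lying entirely above 1 also count as clonal), \code{subclonal}
#' otherwise; \code{absent} calls are preserved.
#'
#' @param est Data frame with columns \code{ci_low}, \code{ci_high} and
#'   optionally \code{clonality} carrying prior \code{absent} flags.
#' @return Character vector of clonality labels.
#' @export
classify_clonality <- function(est) {
  out <- ifelse(est$ci_high >= 1, "clonal", "subclonal")
  if (!is.null(est$clonality)) out[est$clonality == "absent"] <- "absent"
  out[is.na(est$ci_high) & (is.null(est$clonality) | is.na(est$clonality))] <- "absent"
  out
}

#' CCF estimates for a whole patient
#'
#' Applies \code{\link{estimate_ccf}} cell-wise to the observation matrices,
#' honouring detection status: cells whose status is \code{absent} or
#' \code{NA} are treated as absent regardless of residual reads.
#'
#' @param dataset An imputed \code{metroute_patient} with per-sample purity.
#' @inheritParams estimate_ccf
#' @return List of variants x samples matrices \code{ccf}, \code{ci_low},
#'   \code{ci_high} and character matrix \code{clonality}.
#' @export
patient_ccf <- function(dataset, conf = 0.95, clamp = 1.5) {
  stopifnot(inherits(dataset, "metroute_patient"))
  pur <- dataset$samples$purity
  if (anyNA(pur)) stopf("per-sample purity is required for CCF estimation")
  V <- nrow(dataset$alt_reads); S <- ncol(dataset$alt_reads)
  est <- estimate_ccf(as.vector(dataset$alt_reads), as.vector(dataset$depth),
                      purity = rep(pur, each = V),
                      total_cn = as.vector(dataset$copy_number),
                      multiplicity = as.vector(dataset$multiplicity),
                      conf = conf, clamp = clamp)
  dm <- dimnames(dataset$alt_reads)
  shape <- function(v) matrix(v, V, S, dimnames = dm)
  clon <- shape(est$clonality)
  off <- dataset$status %in% c("absent", "NA")
  ccf <- shape(est$ccf); ccf[off & !is.na(ccf)] <- 0
  clon[off] <- "absent"
  list(ccf = ccf, ci_low = shape(est$ci_low), ci_high = shape(est$ci_high),
       clonality = clon)
}

#' Donor-side clonality under the larger-CCF rule
#'
#' When a metastasis has several candidate seeding donors (e.g. two primary
#' regions, or primary vs lymph), the donor-side clonality of each variant is
#' taken from the candidate sample with the larger CCF. Ties are broken
#' deterministically by sample order (column order of the CCF matrix).
#'
#' @param ccf Numeric matrix (variants x candidate donor samples) of CCFs;
#'   NA treated as 0.
#' @param clonality Character matrix of matching shape with labels
#'   \code{clonal}/\code{subclonal}/\code{absent}.
#' @return Data frame with the chosen \code{donor_sample}, \code{ccf} and
#'   \code{clonality} per variant.
#' @export
choose_seeding_donor <- function(ccf, clonality) {
  ccf <- as.matrix(ccf); clonality <- as.matrix(clonality)
  if (ncol(ccf) < 1) stopf("no candidate donor samples")
  ccf0 <- ccf; ccf0[is.na(ccf0)] <- 0
  pick <- max.col(ccf0, ties.method = "first")
  idx <- cbind(seq_len(nrow(ccf)), pick)
  out <- data.frame(donor_sample = colnames(ccf)[pick] %||% pick,
                    ccf = ccf0[idx], clonality = clonality[idx],
                    stringsAsFactors = FALSE)
  all_absent <- rowSums(clonality != "absent") == 0
  out$clonality[all_absent] <- "absent"
  rownames(out) <- rownames(ccf)
  out
}

#' Selection class of a variant during metastatic seeding
#'
#' Classifies each variant by how its clonality changes from the seeding
#' donor to the metastasis:
#' \itemize{
#'   \item \code{selected}: clonal in the metastasis, subclonal or absent in
#'     the donor (swept to fixation during seeding);
#'   \item \code{novel}: subclonal in the metastasis, absent in the donor
#'     (arose after seeding);
#'   \item \code{founding}: clonal in both;
#'   \item \code{unselected}: absent in the metastasis, clonal or subclonal
#'     in the donor (left behind);
#'   \item \code{persistent_subclonal}: subclonal in the metastasis and
#'     present in the donor — a case outside the four canonical classes,
#'     labelled separately so the five labels partition all variants.
#' }
#'
#' @param donor_clonality,met_clonality Character vectors of labels in
#'   \code{clonal}/\code{subclonal}/\code{absent}; recycled to equal length.
#' @return Character vector of selection classes.
#' @export
classify_selection <- function(donor_clonality, met_clonality) {
  n <- max(length(donor_clonality), length(met_clonality))
  d <- rep_len(donor_clonality, n); m <- rep_len(met_clonality, n)
  ok <- c("clonal", "subclonal", "absent")
  if (!all(d %in% ok) || !all(m %in% ok)) stopf("clonality labels must be clonal/subclonal/absent")
  if (any(d == "absent" & m == "absent"))
    stopf("variant absent in both donor and metastasis is not in this patient")
  out <- character(n)
  out[m == "clonal" & d != "clonal"] <- "selected"
  out[m == "clonal" & d == "clonal"] <- "founding"
  out[m == "subclonal" & d == "absent"] <- "novel"
  out[m == "subclonal" & d != "absent"] <- "persistent_subclonal"
  out[m == "absent"] <- "unselected"
  out
}

#' Per-metastasis selection classes for a patient
#'
#' For every pre-treatment distant metastasis sample, derives the donor-side
#' clonality over all candidate donor samples (primary and regional lymph
#' node, pre-treatment) by the larger-CCF rule and applies
#' \code{\link{classify_selection}}. Variants absent on both sides of a
#' given metastasis are reported as NA for that metastasis.
#'
#' @param dataset An imputed \code{metroute_patient}.
#' @param ccf_est Output of \code{\link{patient_ccf}} (computed if NULL).
#' @return Data frame: one row per variant, one column per metastasis sample.
#' @export
selection_classes <- function(dataset, ccf_est = NULL) {
  stopifnot(inherits(dataset, "metroute_patient"))
  if (is.null(ccf_est)) ccf_est <- patient_ccf(dataset)
  sm <- dataset$samples
  pre <- sm$timing == "pre_treatment"
  donors <- sm$sample_id[pre & sm$site %in% c("primary", "regional_lymph_node")]
  mets <- sm$sample_id[pre & sm$site == "distant_metastasis"]
  if (!length(donors) || !length(mets))
    stopf("selection classes need >=1 donor (primary/lymph) and >=1 metastasis sample")
  donor <- choose_seeding_donor(ccf_est$ccf[, donors, drop = FALSE],
                                ccf_est$clonality[, donors, drop = FALSE])
  out <- data.frame(row.names = rownames(ccf_est$ccf))
  for (ms in mets) {
    mc <- ccf_est$clonality[, ms]
    lab <- rep(NA_character_, length(mc))
    in_pat <- !(donor$clonality == "absent" & mc == "absent")
    lab[in_pat] <- classify_selection(donor$clonality[in_pat], mc[in_pat])
    out[[ms]] <- lab
  }
  out
}
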