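# Ground-truth clonal-evolution simulator: clone trees, multi-region read
# counts under lymphatic or hematogenous seeding, and class-conditioned
# textured ROI images. Every output feeds directly into the pipeline.

#' Simulation configuration
#'
#' Defaults encode the reference study conditions used throughout the test
#' suite: 5 clones, 30 mutations per clone, mean depth 150, purity 0.8,
#' CCF jitter 0.02, two primary regions plus one regional lymph node and
#' one distant metastasis sample.
#'
#' @param seed Master seed (same config gives identical output).
#' @param n_clones Number of clones including the founding clone (>= 2).
#' @param mutations_per_clone Mutations private to each clone branch.
#' @param depth_mean Mean sequencing depth (Poisson).
#' @param purity Tumour purity, recycled per sample.
#' @param route \code{"lymphatic"} or \code{"hematogenous"}.
#' @param n_regions Named integer vector of samples per site.
#' @param noise_sd CCF jitter standard deviation applied to present cells.
#' @param overdispersion Optional beta-binomial overdispersion rho in (0,1);
#'   NULL for pure binomial reads.
#' @param normal_depth Matched-normal depth (normal alt reads are 0).
#' @return A list of class \code{metroute_sim_config}.
#' @export
sim_config <- function(seed = 1L, n_clones = 5L, mutations_per_clone = 30L,
                       depth_mean = 150L, purity = 0.8,
                       route = c("lymphatic", "hematogenous"),
                       n_regions = c(primary = 2L, regional_lymph_node = 1L,
                                     distant_metastasis = 1L),
                       noise_sd = 0.02, overdispersion = NULL,
                       normal_depth = 150L) {
  route <- match.arg(route)
  if (n_clones < 2) stopf("need >= 2 clones (founding + at least one subclone)")
  for (site in SITE_LEVELS)
    if (is.na(n_regions[site]) || n_regions[site] < 1)
      stopf("infeasible config: route simulation needs >= 1 %s sample", site)
  structure(list(seed = as.integer(seed), n_clones = as.integer(n_clones),
                 mutations_per_clone = as.integer(mutations_per_clone),
                 depth_mean = depth_mean, purity = purity, route = route,
                 n_regions = n_regions, noise_sd = noise_sd,
                 overdispersion = overdispersion,
                 normal_depth = as.integer(normal_depth)),
            class = "metroute_sim_config")
}

# Clone roles: 1 founding; 2 seeding clone (shared lymph+met under the
# lymphatic route, shared primary+met under the hematogenous route; it
# sweeps to fixation in the metastasis, which is what makes its mutations
# "selected" — clonal in the metastasis, subclonal in the donor);
# 3 metastasis-private child of the seeding clone; 4 private to the
# non-seeding donor site; 5 child of the seeding clone private to the
# seeding site; further clones cycle through site-private positions.
clone_design <- function(n_clones, route) {
  parent <- rep(1L, n_clones); parent[1] <- NA_integer_
  seed_site <- if (route == "lymphatic") "regional_lymph_node" else "primary"
  other_site <- if (route == "lymphatic") "primary" else "regional_lymph_node"
  sites <- vector("list", n_clones)
  sites[[1]] <- SITE_LEVELS
  sites[[2]] <- c(seed_site, "distant_metastasis")
  if (n_clones >= 3) { parent[3] <- 2L; sites[[3]] <- "distant_metastasis" }
  if (n_clones >= 4) sites[[4]] <- other_site
  if (n_clones >= 5) { parent[5] <- 2L; sites[[5]] <- seed_site }
  if (n_clones >= 6) {
    cyc <- rep(c("primary", "regional_lymph_node", "distant_metastasis"),
               length.out = n_clones - 5L)
    for (i in 6:n_clones) {
      sites[[i]] <- cyc[i - 5L]
      # metastasis-private extras nest inside the metastatic lineage, whose
      # swept seeding clone leaves no room for parallel root children there
      if (cyc[i - 5L] == "distant_metastasis")
        parent[i] <- if (n_clones >= 3) 3L else 2L
    }
  }
  list(parent = parent, sites = sites, sweep_clone = 2L,
       sweep_site = "distant_metastasis")
}

# Stick-breaking clone fractions for one sample: each present child takes a
# uniform fraction of what remains of its parent's CCF, so the sum rule
# holds by construction. The stick range is deliberately high so that a
# child and its parent jointly exceed one cell fraction unit, which makes
# the true nesting identifiable from CCF algebra (parallel placement would
# require adjustment); with small fractions no method could distinguish a
# chain from a star.
draw_clone_ccf <- function(parent, present, full_take = NULL,
                           stick = c(0.65, 0.85)) {
  n <- length(parent)
  if (is.null(full_take)) full_take <- logical(n)
  ccf <- numeric(n)
  ccf[1] <- 1
  for (v in seq_len(n)) {
    kids <- which(!is.na(parent) & parent == v & present)
    remaining <- ccf[v]
    for (k in kids) {
      frac <- if (full_take[k]) remaining
              else stats::runif(1, stick[1], stick[2]) * remaining
      ccf[k] <- frac
      remaining <- remaining - frac
    }
  }
  ccf * present
}

#' Simulate one multi-region patient
#'
#' Draws a clone tree whose site occupancy encodes the requested seeding
#' route (lymphatic: every metastasis-seeding clone descends from a clone
#' present in the regional lymph node and absent from all primaries;
#' hematogenous: the seeding lineage is present in the primary and absent
#' from the lymph node), assigns \code{mutations_per_clone} mutations to
#' each branch, draws per-sample clone fractions by stick-breaking, and
#' emits binomial read counts through the purity/copy-number map.
#'
#' @param config A \code{\link{sim_config}}.
#' @param patient_id Patient identifier (default \code{"SIM"}).
#' @return List with \code{dataset} (a \code{metroute_patient}) and
#'   \code{truth} (clone tree, clone occupancy, true CCFs, true route and
#'   per-metastasis selection classes).
#' @export
simulate_patient <- function(config = sim_config(), patient_id = "SIM") {
  stopifnot(inherits(config, "metroute_sim_config"))
  with_seed(config$seed, simulate_patient_impl(config, patient_id))
}

simulate_patient_impl <- function(config, patient_id) {
  des <- clone_design(config$n_clones, config$route)
  nc <- config$n_clones
  reg <- config$n_regions
  samples <- do.call(rbind, lapply(SITE_LEVELS, function(site) {
    k <- reg[[site]]
    data.frame(sample_id = sprintf("%s%d", c(primary = "Pri",
                                             regional_lymph_node = "Lyn",
                                             distant_metastasis = "Met")[site],
                                   seq_len(k)),
               site = site, region = seq_len(k), timing = "pre_treatment",
               stringsAsFactors = FALSE)
  }))
  samples$purity <- rep_len(config$purity, nrow(samples))
  S <- nrow(samples)
  present <- vapply(seq_len(S), function(s)
    vapply(des$sites, function(ss) samples$site[s] %in% ss, TRUE), logical(nc))
  clone_ccf <- vapply(seq_len(S), function(s) {
    full <- seq_len(nc) == des$sweep_clone & samples$site[s] == des$sweep_site
    draw_clone_ccf(des$parent, present[, s], full_take = full)
  }, numeric(nc))
  dimnames(clone_ccf) <- list(paste0("clone", seq_len(nc)), samples$sample_id)

  mpc <- config$mutations_per_clone
  clone_of <- rep(seq_len(nc), each = mpc)
  V <- length(clone_of)
  variants <- data.frame(chrom = paste0("chr", 1 + (seq_len(V) - 1L) %% 22L),
                         pos = 1000L * seq_len(V) + sample.int(999L, V, replace = TRUE),
                         ref = sample(c("A", "C", "G", "T"), V, replace = TRUE),
                         stringsAsFactors = FALSE)
  variants$alt <- vapply(variants$ref, function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  variants$normal_alt <- 0L
  variants$normal_depth <- config$normal_depth
  vid <- sprintf("%s:%d:%s>%s", variants$chrom, variants$pos, variants$ref, variants$alt)
  variants$variant_id <- vid

  true_ccf <- clone_ccf[clone_of, , drop = FALSE]
  rownames(true_ccf) <- vid
  obs_ccf <- true_ccf
  if (config$noise_sd > 0) {
    jit <- matrix(stats::rnorm(V * S, 0, config$noise_sd), V, S)
    obs_ccf[true_ccf > 0] <- pmin(pmax(true_ccf[true_ccf > 0] + jit[true_ccf > 0], 0.01), 1)
  }
  pur <- rep(samples$purity, each = V)
  vaf <- obs_ccf * pur / (pur * 2 + (1 - pur) * 2) # total CN 2, multiplicity 1
  depth <- matrix(stats::rpois(V * S, config$depth_mean), V, S)
  alt <- matrix(0L, V, S)
  pos_cells <- which(vaf > 0 & depth > 0)
  if (!is.null(config$overdispersion)) {
    rho <- config$overdispersion
    a <- vaf[pos_cells] * (1 - rho) / rho
    b <- (1 - vaf[pos_cells]) * (1 - rho) / rho
    p <- stats::rbeta(length(pos_cells), a, b)
    alt[pos_cells] <- stats::rbinom(length(pos_cells), depth[pos_cells], p)
  } else {
    alt[pos_cells] <- stats::rbinom(length(pos_cells), depth[pos_cells], vaf[pos_cells])
  }
  status <- matrix(ifelse(true_ccf > 0, "detected", "absent"), V, S)

  dataset <- patient_dataset(patient_id, samples, variants, alt, depth,
                             status = status)
  truth <- list(clone_parent = des$parent,
                clone_sites = des$sites,
                clone_of_variant = setNames(clone_of, vid),
                clone_ccf = clone_ccf,
                present = present,
                true_ccf = true_ccf,
                route = config$route,
                selection_class = true_selection_classes(true_ccf, samples))
  list(dataset = dataset, truth = truth)
}

# Ground-truth selection classes from noise-free CCFs, written as an
# explicit per-case decision (independent of classify_selection's
# vectorised truth table). Clonal means true CCF 1.
true_selection_classes <- function(true_ccf, samples) {
  donors <- samples$sample_id[samples$site %in% c("primary", "regional_lymph_node") &
                              samples$timing == "pre_treatment"]
  mets <- samples$sample_id[samples$site == "distant_metastasis" &
                            samples$timing == "pre_treatment"]
  lab_of <- function(x) if (x >= 1 - 1e-9) "clonal" else if (x > 0) "subclonal" else "absent"
  cols <- lapply(mets, function(ms) {
    vapply(rownames(true_ccf), function(v) {
      donor <- lab_of(max(true_ccf[v, donors]))
      met <- lab_of(true_ccf[v, ms])
      if (met == "absent" && donor == "absent") return(NA_character_)
      if (met == "clonal") {
        if (donor == "clonal") "founding" else "selected"
      } else if (met == "subclonal") {
        if (donor == "absent") "novel" else "persistent_subclonal"
      } else "unselected"
    }, "")
  })
  out <- as.data.frame(cols, col.names = mets, stringsAsFactors = FALSE)
  rownames(out) <- rownames(true_ccf)
  out
}

#' Simulate a cohort of patients
#'
#' Independent patients with per-patient seeds derived from the master
#' seed; the route mix fixes how many patients follow each route.
#'
#' @param n_patients Number of patients.
#' @param route_mix Named counts, e.g. \code{c(lymphatic = 8, hematogenous = 5)};
#'   must sum to \code{n_patients}.
#' @param config Base \code{\link{sim_config}} (its seed acts as master seed).
#' @return List with \code{patients} (list of simulate_patient outputs) and
#'   \code{truth} (data frame of true routes).
#' @export
simulate_cohort <- function(n_patients,
                            route_mix = c(lymphatic = ceiling(n_patients / 2),
                                          hematogenous = floor(n_patients / 2)),
                            config = sim_config()) {
  if (n_patients < 1) stopf("need >= 1 patient")
  if (sum(route_mix) != n_patients) stopf("route_mix must sum to n_patients")
  routes <- rep(names(route_mix), times = route_mix)
  patients <- lapply(seq_len(n_patients), function(i) {
    cfg <- config
    cfg$seed <- config$seed + i
    cfg$route <- routes[i]
    simulate_patient(cfg, patient_id = sprintf("P%02d", i))
  })
  truth <- data.frame(patient_id = sprintf("P%02d", seq_len(n_patients)),
                      route = routes, stringsAsFactors = FALSE)
  list(patients = patients, truth = truth)
}

#' Write a patient dataset to the package's TSV dialect
#'
#' Long format, one row per variant per sample, including matched-normal
#' counts, purity and detection status; \code{\link{read_variant_table}}
#' round-trips it.
#'
#' @param dataset A \code{metroute_patient}.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_variant_table <- function(dataset, path) {
  stopifnot(inherits(dataset, "metroute_patient"))
  V <- nrow(dataset$variants); S <- nrow(dataset$samples)
  idx <- expand.grid(v = seq_len(V), s = seq_len(S))
  tab <- data.frame(patient = dataset$patient_id,
                    sample = dataset$samples$sample_id[idx$s],
                    site = dataset$samples$site[idx$s],
                    region = dataset$samples$region[idx$s],
                    timing = dataset$samples$timing[idx$s],
                    chrom = dataset$variants$chrom[idx$v],
                    pos = dataset$variants$pos[idx$v],
                    ref = dataset$variants$ref[idx$v],
                    alt = dataset$variants$alt[idx$v],
                    alt_reads = dataset$alt_reads[cbind(idx$v, idx$s)],
                    depth = dataset$depth[cbind(idx$v, idx$s)],
                    status = dataset$status[cbind(idx$v, idx$s)],
                    purity = dataset$samples$purity[idx$s],
                    total_cn = dataset$copy_number[cbind(idx$v, idx$s)],
                    multiplicity = dataset$multiplicity[cbind(idx$v, idx$s)],
                    stringsAsFactors = FALSE)
  if (!is.null(dataset$variants$normal_alt)) {
    tab$normal_alt <- dataset$variants$normal_alt[idx$v]
    tab$normal_depth <- dataset$variants$normal_depth[idx$v]
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Periodic Gaussian random field: white noise smoothed by FFT with an
# isotropic Gaussian kernel of bandwidth `sigma` (pixels).
gaussian_field <- function(nr, nc, sigma) {
  noise <- matrix(stats::rnorm(nr * nc), nr, nc)
  if (sigma <= 0) return(noise)
  r <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))
  c0 <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))
  k <- outer(exp(-r^2 / (2 * sigma^2)), exp(-c0^2 / (2 * sigma^2)))
  k <- k / sum(k)
  sm <- Re(stats::fft(stats::fft(noise) * stats::fft(k), inverse = TRUE)) / (nr * nc)
  (sm - mean(sm)) / stats::sd(sm)
}

#' Simulate textured ROI images with class-dependent texture
#'
#' Generates grey-level images whose texture depends on the route class:
#' both classes are Gaussian random fields, but the class margin shifts the
#' correlation length, contrast and mean intensity between them. At margin
#' 0 the two classes are drawn from the identical distribution; a margin of
#' 1 gives textures separable by the radiomics features by construction.
#' Each image carries an elliptical ROI mask.
#'
#' @param n_per_class Images per class.
#' @param margin Class separation in [0, 1].
#' @param size Image size (rows, cols), default 25 x 25.
#' @param roi_radii Ellipse radii (rows, cols) of the ROI, default c(4, 6).
#' @param seed Master seed.
#' @return List with \code{images}, \code{masks} (lists of matrices) and
#'   \code{labels} (character vector, \code{lymphatic}/\code{hematogenous}).
#' @export
simulate_roi_images <- function(n_per_class = 10L, margin = 1,
                                size = c(25L, 25L), roi_radii = c(4, 6),
                                seed = 1L) {
  nr <- size[1]; nc <- size[2]
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  mask <- outer(seq_len(nr), seq_len(nc), function(r, c)
    ((r - ctr[1]) / roi_radii[1])^2 + ((c - ctr[2]) / roi_radii[2])^2 <= 1) * 1L
  params <- list(
    lymphatic = list(sigma = 1.0 + 1.5 * margin, contrast = 1 + margin,
                     shift = 2 * margin),
    hematogenous = list(sigma = 1.0, contrast = 1, shift = 0))
  labels <- rep(c("lymphatic", "hematogenous"), each = n_per_class)
  images <- with_seed(seed, lapply(seq_along(labels), function(i) {
    p <- params[[labels[i]]]
    p$shift + p$contrast * gaussian_field(nr, nc, p$sigma)
  }))
  list(images = images, masks = rep(list(mask), length(labels)), labels = labels)
}
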