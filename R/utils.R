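# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

SITE_LEVELS <- c("primary", "regional_lymph_node", "distant_metastasis")
TIMING_LEVELS <- c("pre_treatment", "post_treatment")
STATUS_LEVELS <- c("detected", "rescued", "absent", "NA")

check_site <- function(site) {
  bad <- setdiff(unique(site), SITE_LEVELS)
  if (length(bad))
    stopf("unknown site label(s): %s (expected one of %s)",
          paste(bad, collapse = ", "), paste(SITE_LEVELS, collapse = ", "))
  site
}

check_timing <- function(timing) {
  bad <- setdiff(unique(timing), TIMING_LEVELS)
  if (length(bad))
    stopf("unknown timing label(s): %s", paste(bad, collapse = ", "))
  timing
}
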