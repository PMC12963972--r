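#' Simple baseline subtraction
#'
#' Subtracts the background spectrum from the observed spectrum channel by
#' channel and clips negative values to zero (the most basic cleaning
#' method). When the background is a `signature_vector` it is scaled to the
#' observed burden before subtraction (proportion-comparable mode); a
#' count-scale `mutation_profile` background is subtracted directly.
#'
#' @param observed A `mutation_profile`.
#' @param background A `mutation_profile` (counts) or `signature_vector`
#'   (scaled by the observed burden).
#' @return A `baseline_result` with `method = "subtraction"`,
#'   `exposure_profile` (elementwise >= 0) and `clipped_channels` (number
#'   of channels truncated to zero).
#' @export
simple_subtraction <- function(observed, background) {
  stopifnot(inherits(observed, "mutation_profile"))
  if (!schemas_identical(observed$schema, background$schema))
    stop_schema_mismatch(observed$schema, background$schema)
  bg <- if (inherits(background, "signature_vector"))
    observed$burden * background$proportions
  else background$counts
  raw <- observed$counts - bg
  clipped <- sum(raw < 0)
  structure(list(method = "subtraction",
                 sample_id = observed$sample_id,
                 schema = observed$schema,
                 exposure_profile = pmax(raw, 0),
                 clipped_channels = as.integer(clipped),
                 background_activity = NA_real_),
            class = "baseline_result")
}

#' NNLS baseline removal with shrinkage
#'
#' Fits the observed counts as a non-negative combination of the background
#' signatures (Lawson-Hanson NNLS), then removes only a `shrinkage`
#' fraction of the fitted baseline — the 90% default counteracts NNLS's
#' propensity to overfit the baseline — and clips negative channels to
#' zero. Mutations not explained by the background form the residual,
#' i.e. the exposure-associated profile.
#'
#' @param observed A `mutation_profile`.
#' @param backgrounds `signature_vector`/`mutation_profile` or list of them.
#' @param shrinkage Fraction of the fitted baseline to subtract, in (0, 1]
#'   (default 0.9).
#' @return A `baseline_result` with `method = "nnls"`, the exposure
#'   profile, clipped channel count, fitted activities `beta` (count
#'   scale), and `background_activity` (shrunk baseline fraction of the
#'   burden).
#' @export
nnls_subtraction <- function(observed, backgrounds, shrinkage = 0.9) {
  stopifnot(inherits(observed, "mutation_profile"),
            shrinkage > 0, shrinkage <= 1)
  if (inherits(backgrounds, c("signature_vector", "mutation_profile")))
    backgrounds <- list(backgrounds)
  if (length(backgrounds) == 0L) stop("no backgrounds supplied", call. = FALSE)
  backgrounds <- lapply(backgrounds, normalize)
  for (b in backgrounds)
    if (!schemas_identical(observed$schema, b$schema))
      stop_schema_mismatch(observed$schema, b$schema)
  B <- vapply(backgrounds, `[[`, numeric(observed$schema$size), "proportions")
  if (all(B == 0)) stop("degenerate background matrix", call. = FALSE)
  beta <- pracma::lsqnonneg(B, as.numeric(observed$counts))$x
  fitted <- as.numeric(B %*% beta)
  raw <- observed$counts - shrinkage * fitted
  clipped <- sum(raw < 0)
  structure(list(method = "nnls",
                 sample_id = observed$sample_id,
                 schema = observed$schema,
                 exposure_profile = pmax(raw, 0),
                 clipped_channels = as.integer(clipped),
                 beta = beta,
                 background_activity = shrinkage * sum(beta) / observed$burden),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat("<baseline_result> ", x$method, " on ", x$sample_id,
      ": exposure total ", format(sum(x$exposure_profile), digits = 6),
      ", ", x$clipped_channels, " clipped channel(s)", sep = "")
  if (!is.na(x$background_activity))
    cat(sprintf(", background activity %.3f", x$background_activity))
  cat("\n")
  invisible(x)
}
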