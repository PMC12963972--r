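#' Export a per-sample rescue breakdown as TSV
#'
#' Columns: channel, observed, background-attributed and
#' exposure-attributed counts at the posterior point estimates.
#'
#' @param result A `rescue_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_rescue_profile <- function(result, path) {
  stopifnot(inherits(result, "rescue_result"))
  exposure <- as.numeric(result$rescued_profile)
  df <- data.frame(
    channel = result$schema$labels,
    observed = as.numeric(result$observed),
    background = as.numeric(result$reconstructed) - exposure,
    exposure = exposure
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an activity summary table for one or more rescue results
#'
#' One row per sample: activities with 95% credible bounds, relative
#' activities, reconstruction cosine and max split-R-hat.
#'
#' @param results A `rescue_result` or list of them.
#' @param path Output file (optional; when `NULL` the data frame is
#'   returned without writing).
#' @return The summary data frame, invisibly when written.
#' @export
write_activity_summary <- function(results, path = NULL) {
  if (inherits(results, "rescue_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(r) data.frame(
    sample = r$sample_id,
    burden = r$burden,
    theta_b = r$theta_b_hat,
    theta_e = r$theta_e_hat,
    theta_e_lo = r$theta_credible["exposure", 1],
    theta_e_hi = r$theta_credible["exposure", 2],
    rel_background = r$relative_activities[["background"]],
    rel_exposure = r$relative_activities[["exposure"]],
    nu = r$nu_hat,
    fit_cosine = r$fit_cosine,
    max_rhat = r$max_rhat
  )))
  if (is.null(path)) return(df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Export full posterior draws in a columnar text format
#'
#' One row per draw with chain id, activities, dispersion, log posterior,
#' and every exposure-signature channel, for external posterior
#' exploration.
#'
#' @param draws A `posterior_draws`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  stopifnot(inherits(draws, "posterior_draws"))
  df <- data.frame(chain = draws$chain_ids, draws$theta_b,
                   theta_e = draws$theta_e, nu = draws$nu, lp = draws$lp,
                   check.names = FALSE)
  se <- as.data.frame(draws$s_e)
  names(se) <- paste0("s_e[", colnames(draws$s_e), "]")
  utils::write.table(cbind(df, se), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a baseline-method result in the same TSV layout
#'
#' @param result A `baseline_result`.
#' @param observed The observed `mutation_profile`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_baseline_profile <- function(result, observed, path) {
  stopifnot(inherits(result, "baseline_result"))
  df <- data.frame(
    channel = result$schema$labels,
    observed = as.numeric(observed$counts),
    background = as.numeric(observed$counts) -
      as.numeric(result$exposure_profile),
    exposure = as.numeric(result$exposure_profile)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
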