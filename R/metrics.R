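#' Cosine similarity between two spectra
#'
#' `dot(a, b) / (||a|| ||b||)`; scale-invariant, and in `[0, 1]` for
#' non-negative inputs.
#'
#' @param a,b Numeric vectors of equal length, not both zero.
#' @return Cosine similarity.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch", call. = FALSE)
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector",
                               call. = FALSE)
  sum(a * b) / (na * nb)
}

#' Jensen-Shannon divergence
#'
#' `0.5 KL(p || m) + 0.5 KL(q || m)` with `m = (p + q)/2`. With base-2
#' logarithms (the default) the divergence lies in `[0, 1]`, is symmetric,
#' and is 0 iff `p == q`. Count vectors are normalized automatically.
#'
#' @param p,q Non-negative vectors of equal length (normalized internally).
#' @param base Logarithm base (default 2).
#' @return JSD value.
#' @export
jsd <- function(p, q, base = 2) {
  if (length(p) != length(q)) stop("length mismatch", call. = FALSE)
  if (any(p < 0) || any(q < 0)) stop("negative inputs are not distributions", call. = FALSE)
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log(a[i], base = base) - log(b[i], base = base)))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

#' Count accuracy: signed total-count difference
#'
#' `sum(reconstructed) - sum(observed)`. Values near 0 indicate minimal
#' deviation from the original mutation count; negative values mean
#' under-reconstruction (mutations left unassigned), positive values mean
#' count inflation (e.g. from clipping negative channels to zero).
#'
#' @param reconstructed Numeric vector of reconstructed counts, or a
#'   `mutation_profile`.
#' @param observed A `mutation_profile` (or numeric vector).
#' @return Signed difference in total counts.
#' @export
count_accuracy <- function(reconstructed, observed) {
  rec <- if (inherits(reconstructed, "mutation_profile")) reconstructed$counts
         else reconstructed
  obs <- if (inherits(observed, "mutation_profile")) observed$counts
         else observed
  if (length(rec) != length(obs)) stop("schema mismatch", call. = FALSE)
  sum(rec) - sum(obs)
}

#' Precision/sensitivity/F1 of synthetic-injection removal
#'
#' Count-level matching per channel: `TP = sum(min(removed, injected))`,
#' `FP = sum(max(removed - injected, 0))`, `FN = sum(max(injected -
#' removed, 0))`. Then `precision = TP/(TP+FP)`, `sensitivity =
#' TP/(TP+FN)`, `f1 = 2 P S / (P + S)`; zero denominators give 0 with
#' `degenerate = TRUE` rather than NaN.
#'
#' @param removed Per-channel non-negative removed counts
#'   (post-injection observed minus rescued exposure profile, floored at 0).
#' @param injected Per-channel non-negative injected counts.
#' @return An `injection_score` list with `tp`, `fp`, `fn`, `precision`,
#'   `sensitivity`, `f1`, `degenerate`.
#' @export
injection_score <- function(removed, injected) {
  if (length(removed) != length(injected)) stop("schema mismatch", call. = FALSE)
  if (any(removed < 0) || any(injected < 0))
    stop("removed/injected counts must be non-negative", call. = FALSE)
  tp <- sum(pmin(removed, injected))
  fp <- sum(pmax(removed - injected, 0))
  fn <- sum(pmax(injected - removed, 0))
  degenerate <- FALSE
  precision <- if (tp + fp > 0) tp / (tp + fp) else { degenerate <- TRUE; 0 }
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else { degenerate <- TRUE; 0 }
  f1 <- if (precision + sensitivity > 0)
    2 * precision * sensitivity / (precision + sensitivity)
  else { degenerate <- TRUE; 0 }
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 sensitivity = sensitivity, f1 = f1, degenerate = degenerate),
            class = "injection_score")
}

#' @export
print.injection_score <- function(x, ...) {
  cat(sprintf("<injection_score> P=%.3f S=%.3f F1=%.3f (TP=%.1f FP=%.1f FN=%.1f)%s\n",
              x$precision, x$sensitivity, x$f1, x$tp, x$fp, x$fn,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Side-by-side metric report
#'
#' Computes the evaluation metrics between matched columns of two profile
#' lists (e.g. reconstructed vs observed) and returns a data frame suitable
#' for TSV export.
#'
#' @param reconstructed,observed Lists of `mutation_profile`s (paired by
#'   position).
#' @param method Label recorded in the `method` column.
#' @return A data frame with columns sample, method, cosine, jsd,
#'   count_accuracy.
#' @export
metric_report <- function(reconstructed, observed, method = "model") {
  stopifnot(length(reconstructed) == length(observed))
  rows <- Map(function(r, o) {
    rc <- if (inherits(r, "mutation_profile")) r$counts else r
    oc <- if (inherits(o, "mutation_profile")) o$counts else o
    data.frame(sample = if (inherits(o, "mutation_profile")) o$sample_id else NA,
               method = method,
               cosine = cosine_similarity(rc, oc),
               jsd = jsd(rc, oc),
               count_accuracy = count_accuracy(rc, oc))
  }, reconstructed, observed)
  do.call(rbind, rows)
}
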