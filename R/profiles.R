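#' Mutation-count profile for one sample
#'
#' Holds per-channel mutation counts under a fixed channel schema. The
#' total mutation burden (TMB) is the sum of counts. Burden-weighted
#' aggregates (see [weighted_profile()]) may carry non-integer counts and
#' are flagged `weighted`; count likelihoods require integer profiles.
#'
#' @param sample_id Sample name.
#' @param counts Numeric vector of non-negative counts, one per channel.
#' @param schema A [channel_schema()]; defaults to auto-sizing a CUSTOM
#'   schema is not attempted — a schema must be supplied.
#' @param weighted Logical; `TRUE` marks real-valued weighted profiles.
#' @return A `mutation_profile` with fields `sample_id`, `schema`,
#'   `counts`, `burden`, `weighted`.
#' @export
mutation_profile <- function(sample_id, counts, schema, weighted = FALSE) {
  stopifnot(inherits(schema, "channel_schema"))
  counts <- as.numeric(counts)
  if (length(counts) != schema$size)
    stop("counts length (", length(counts), ") != schema size (",
         schema$size, ")", call. = FALSE)
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("counts contain NA or non-finite values", call. = FALSE)
  if (any(counts < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (!weighted && any(abs(counts - round(counts)) > 1e-8))
    stop("non-integer counts in an unweighted profile; use weighted = TRUE ",
         "for burden-weighted aggregates", call. = FALSE)
  if (!weighted) counts <- round(counts)
  names(counts) <- schema$labels
  structure(list(sample_id = as.character(sample_id), schema = schema,
                 counts = counts, burden = sum(counts), weighted = weighted),
            class = "mutation_profile")
}

#' @export
print.mutation_profile <- function(x, ...) {
  cat("<mutation_profile> ", x$sample_id, ": ", x$schema$name,
      ", burden ", format(x$burden), if (x$weighted) " (weighted)", "\n",
      sep = "")
  invisible(x)
}

#' Signature vector: proportions over channels
#'
#' A mutational signature: non-negative proportions over the channels of a
#' schema, summing to one. Inputs summing to anything within `tol` of 1 are
#' renormalized exactly; use [normalize()] to convert a count profile.
#'
#' @param name Signature name.
#' @param proportions Non-negative numeric vector over the schema channels.
#' @param schema A [channel_schema()].
#' @param tol Tolerance on `sum(proportions) - 1` before erroring.
#' @return A `signature_vector` with fields `name`, `schema`, `proportions`.
#' @export
signature_vector <- function(name, proportions, schema, tol = 1e-6) {
  stopifnot(inherits(schema, "channel_schema"))
  proportions <- as.numeric(proportions)
  if (length(proportions) != schema$size)
    stop("proportions length != schema size", call. = FALSE)
  if (anyNA(proportions) || any(proportions < 0))
    stop("proportions must be non-negative and non-missing", call. = FALSE)
  s <- sum(proportions)
  if (s <= 0) stop("proportions sum to zero", call. = FALSE)
  if (abs(s - 1) > tol)
    stop("proportions sum to ", format(s), ", not 1 (tol ", tol, ")",
         call. = FALSE)
  proportions <- proportions / s
  names(proportions) <- schema$labels
  structure(list(name = as.character(name), schema = schema,
                 proportions = proportions),
            class = "signature_vector")
}

#' @export
print.signature_vector <- function(x, ...) {
  top <- sort(x$proportions, decreasing = TRUE)[1:3]
  cat("<signature_vector> ", x$name, ": ", x$schema$name,
      "; top channels ", paste(names(top), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Normalize a mutation profile to a signature vector
#'
#' @param x A `mutation_profile` (burden must be positive).
#' @param ... Unused.
#' @return A `signature_vector` with `proportions = counts / burden`.
#' @export
normalize <- function(x, ...) UseMethod("normalize")

#' @rdname normalize
#' @export
normalize.mutation_profile <- function(x, ...) {
  if (x$burden <= 0)
    stop("cannot normalize a profile with zero burden (degenerate profile)",
         call. = FALSE)
  signature_vector(x$sample_id, x$counts / x$burden, x$schema)
}

#' @rdname normalize
#' @export
normalize.signature_vector <- function(x, ...) x

#' Burden-weighted aggregate profile
#'
#' Combines replicate profiles so each sample contributes proportionally to
#' its total mutation burden: weights \eqn{w_i = TMB_i / \sum_j TMB_j} and
#' aggregate counts \eqn{\sum_i w_i m_i}. The result carries real-valued
#' counts and is flagged `weighted`.
#'
#' @param profiles List of `mutation_profile`s sharing one schema.
#' @param sample_id Name for the aggregate profile.
#' @return A weighted `mutation_profile`.
#' @export
weighted_profile <- function(profiles, sample_id = "weighted") {
  if (length(profiles) == 0L) stop("no profiles supplied", call. = FALSE)
  stopifnot(all(vapply(profiles, inherits, logical(1), "mutation_profile")))
  sch <- profiles[[1L]]$schema
  for (p in profiles[-1L])
    if (!schemas_identical(sch, p$schema)) stop_schema_mismatch(sch, p$schema)
  tmb <- vapply(profiles, `[[`, numeric(1), "burden")
  if (sum(tmb) <= 0) stop("all profiles have zero burden", call. = FALSE)
  w <- tmb / sum(tmb)
  counts <- Reduce(`+`, Map(function(p, wi) wi * p$counts, profiles, w))
  mutation_profile(sample_id, counts, sch, weighted = TRUE)
}

#' Read a SigProfiler-style mutation matrix
#'
#' Reads a tab-separated matrix whose first column holds channel labels
#' (header `MutationType`) and remaining columns hold per-sample values.
#' Rows are reordered to the canonical schema order regardless of file
#' order.
#'
#' @param path File path.
#' @param schema_hint Optional schema name (`"SBS96"`, ..., `"CUSTOM"`) to
#'   force instead of auto-detection.
#' @param type `"counts"` returns `mutation_profile`s; `"proportions"`
#'   returns `signature_vector`s (for reference-signature matrices).
#' @return A named list of profiles or signatures, one per sample column.
#' @export
read_matrix <- function(path, schema_hint = NULL,
                        type = c("counts", "proportions")) {
  type <- match.arg(type)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L)
    stop("matrix file needs a label column plus >= 1 sample column: ", path,
         call. = FALSE)
  labels <- as.character(df[[1L]])
  if (anyDuplicated(labels))
    stop("duplicate channel labels in ", path, ": ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  sch <- if (is.null(schema_hint)) detect_schema(labels)
         else channel_schema(schema_hint,
                             labels = if (schema_hint == "CUSTOM") labels)
  if (sch$name != "CUSTOM") {
    missing <- setdiff(sch$labels, labels)
    extra <- setdiff(labels, sch$labels)
    if (length(missing) || length(extra))
      stop("labels do not match schema ", sch$name,
           if (length(missing)) paste0("; missing: ",
                                       paste(missing, collapse = ", ")),
           if (length(extra)) paste0("; unknown: ",
                                     paste(extra, collapse = ", ")),
           call. = FALSE)
  }
  ord <- match(sch$labels, labels)
  out <- vector("list", ncol(df) - 1L)
  names(out) <- colnames(df)[-1L]
  for (j in seq_along(out)) {
    v <- df[[j + 1L]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1L]
      stop("non-numeric value in column '", names(out)[j], "', row ",
           bad, " of ", path, call. = FALSE)
    }
    if (anyNA(v) || any(v < 0)) {
      bad <- which(is.na(v) | v < 0)[1L]
      stop("negative or missing value in column '", names(out)[j],
           "', row ", bad, " of ", path, call. = FALSE)
    }
    v <- v[ord]
    out[[j]] <- if (type == "counts")
      mutation_profile(names(out)[j], v, sch,
                       weighted = any(abs(v - round(v)) > 1e-8))
    else signature_vector(names(out)[j], v, sch)
  }
  out
}

#' Write profiles or signatures to a SigProfiler-style matrix
#'
#' Inverse of [read_matrix()]: integer counts round-trip exactly, weighted
#' (real-valued) profiles are written at full precision.
#'
#' @param x List of `mutation_profile`s or `signature_vector`s (one schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  if (length(x) == 0L) stop("nothing to write", call. = FALSE)
  if (inherits(x, c("mutation_profile", "signature_vector"))) x <- list(x)
  sch <- x[[1L]]$schema
  cols <- lapply(x, function(e) {
    if (!schemas_identical(sch, e$schema)) stop_schema_mismatch(sch, e$schema)
    if (inherits(e, "mutation_profile")) e$counts else e$proportions
  })
  nm <- vapply(x, function(e)
    if (inherits(e, "mutation_profile")) e$sample_id else e$name,
    character(1))
  df <- data.frame(MutationType = sch$labels, check.names = FALSE)
  df[nm] <- cols
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
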