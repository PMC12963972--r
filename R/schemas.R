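#' Channel schemas for mutation classifications
#'
#' A channel schema fixes the ordered set of mutation-type channels over
#' which spectra and signatures are defined. The standard SBS96, SBS288,
#' DBS78 and ID83 classifications are built in (SigProfiler label dialect
#' and canonical ordering); any other consistent label set is handled as a
#' `CUSTOM` schema.
#'
#' @param name One of `"SBS96"`, `"SBS288"`, `"DBS78"`, `"ID83"`, or
#'   `"CUSTOM"`.
#' @param labels Character vector of channel labels; required for `CUSTOM`,
#'   ignored otherwise.
#' @return A `channel_schema` object with fields `name`, `labels`, `size`.
#' @examples
#' sch <- channel_schema("SBS96")
#' sch$size
#' head(sch$labels)
#' @export
channel_schema <- function(name = c("SBS96", "SBS288", "DBS78", "ID83", "CUSTOM"),
                           labels = NULL) {
  name <- match.arg(name)
  if (name == "CUSTOM") {
    if (is.null(labels) || length(labels) == 0L)
      stop("CUSTOM schema requires a non-empty `labels` vector", call. = FALSE)
    labels <- as.character(labels)
  } else {
    labels <- switch(name,
      SBS96  = sbs96_labels(),
      SBS288 = sbs288_labels(),
      DBS78  = dbs78_labels(),
      ID83   = id83_labels()
    )
  }
  if (anyDuplicated(labels))
    stop("duplicate channel labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "),
         call. = FALSE)
  structure(list(name = name, labels = labels, size = length(labels)),
            class = "channel_schema")
}

#' @export
print.channel_schema <- function(x, ...) {
  cat("<channel_schema> ", x$name, " (", x$size, " channels)\n", sep = "")
  cat("  ", paste(utils::head(x$labels, 4L), collapse = ", "), ", ...\n", sep = "")
  invisible(x)
}

sbs96_labels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  bases <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s)
    unlist(lapply(bases, function(f) paste0(f, "[", s, "]", bases)))))
}

sbs288_labels <- function() {
  # strand prefix major: T (transcribed), U (untranscribed), N (non-transcribed)
  unlist(lapply(c("T", "U", "N"), function(p) paste0(p, ":", sbs96_labels())))
}

dbs78_labels <- function() {
  alts <- list(
    AC = c("CA", "CG", "CT", "GA", "GG", "GT", "TA", "TG", "TT"),
    AT = c("CA", "CC", "CG", "GA", "GC", "TA"),
    CC = c("AA", "AG", "AT", "GA", "GG", "GT", "TA", "TG", "TT"),
    CG = c("AT", "GC", "GT", "TA", "TC", "TT"),
    CT = c("AA", "AC", "AG", "GA", "GC", "GG", "TA", "TC", "TG"),
    GC = c("AA", "AG", "AT", "CA", "CG", "TA"),
    TA = c("AT", "CG", "CT", "GC", "GG", "GT"),
    TC = c("AA", "AG", "AT", "CA", "CG", "CT", "GA", "GG", "GT"),
    TG = c("AA", "AC", "AT", "CA", "CC", "CT", "GA", "GC", "GT"),
    TT = c("AA", "AC", "AG", "CA", "CC", "CG", "GA", "GC", "GG")
  )
  unlist(lapply(names(alts), function(r) paste0(r, ">", alts[[r]])))
}

id83_labels <- function() {
  sz <- as.character(0:5)
  lab <- c(
    paste0("1:Del:C:", sz), paste0("1:Del:T:", sz),
    paste0("1:Ins:C:", sz), paste0("1:Ins:T:", sz),
    unlist(lapply(2:5, function(n) paste0(n, ":Del:R:", sz))),
    unlist(lapply(2:5, function(n) paste0(n, ":Ins:R:", sz))),
    "2:Del:M:1",
    paste0("3:Del:M:", 1:2),
    paste0("4:Del:M:", 1:3),
    paste0("5:Del:M:", 1:5)
  )
  lab
}

#' Detect the channel schema of a set of labels
#'
#' Matches a label set (order-insensitively) against the built-in SBS96,
#' SBS288, DBS78 and ID83 catalogues; anything else becomes a `CUSTOM`
#' schema in the order given.
#'
#' @param labels Character vector of channel labels.
#' @return A `channel_schema`.
#' @export
detect_schema <- function(labels) {
  labels <- as.character(labels)
  for (nm in c("SBS96", "SBS288", "DBS78", "ID83")) {
    sch <- channel_schema(nm)
    if (length(labels) == sch$size && setequal(labels, sch$labels))
      return(sch)
  }
  channel_schema("CUSTOM", labels = labels)
}

schemas_identical <- function(a, b) {
  identical(a$labels, b$labels)
}

stop_schema_mismatch <- function(a, b, what = "inputs") {
  stop("schema mismatch between ", what, ": ", a$name, " (", a$size,
       " channels) vs ", b$name, " (", b$size, " channels)", call. = FALSE)
}
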