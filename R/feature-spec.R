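#' Define a feature coding rule
#'
#' A feature spec maps one raw clinical feature onto the 0/1
#' "disease-promoting" indicator that the item-response model consumes.
#' Four kinds are supported:
#'
#' \describe{
#'   \item{\code{range}}{a normal interval \code{[low, high]}; values strictly
#'     outside it (too low or too high) are coded 1. Values exactly at an
#'     endpoint are in range and coded 0.}
#'   \item{\code{threshold}}{a cut point; values strictly greater than
#'     \code{threshold} are coded 1 (e.g. age, demarcated at 65 years).}
#'   \item{\code{binary}}{a set of raw values (\code{positive_codes}) that are
#'     coded 1, e.g. a pre-existing diagnosis coded "present", or male sex.}
#'   \item{\code{categorical}}{alias for \code{binary}, for multi-level raw
#'     codes collapsed to one disease-promoting level (e.g. admission type
#'     "emergency" vs anything else).}
#' }
#'
#' @param name feature (column) name in the cohort table.
#' @param kind one of \code{"range"}, \code{"threshold"}, \code{"binary"},
#'   \code{"categorical"}.
#' @param low,high normal-range bounds (kind \code{"range"} only);
#'   \code{low <= high} required.
#' @param threshold cut point (kind \code{"threshold"} only).
#' @param positive_codes vector of raw values mapped to 1 (kinds
#'   \code{"binary"}/\code{"categorical"}).
#' @param units free-text units, carried for reporting only.
#'
#' @return An object of class \code{"feature_spec"}.
#' @seealso [feature_spec_list()], [dichotomize()]
#' @examples
#' feature_spec("sodium_min", "range", low = 135, high = 145,
#'              units = "mmol/L")
#' feature_spec("age", "threshold", threshold = 65, units = "years")
#' feature_spec("aids", "binary", positive_codes = 1)
#' @export
feature_spec <- function(name, kind = c("range", "threshold", "binary",
                                        "categorical"),
                         low = NULL, high = NULL, threshold = NULL,
                         positive_codes = NULL, units = "") {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (kind == "range") {
    if (is.null(low) || is.null(high))
      stop("range spec '", name, "' needs both `low` and `high`")
    low <- as.numeric(low); high <- as.numeric(high)
    if (!is.finite(low) || !is.finite(high) || low > high)
      stop("range spec '", name, "' needs finite low <= high")
  } else if (kind == "threshold") {
    if (is.null(threshold))
      stop("threshold spec '", name, "' needs `threshold`")
    threshold <- as.numeric(threshold)
    if (!is.finite(threshold))
      stop("threshold spec '", name, "' needs a finite threshold")
  } else {
    if (is.null(positive_codes) || length(positive_codes) == 0L)
      stop(kind, " spec '", name, "' needs non-empty `positive_codes`")
  }
  structure(
    list(name = name, kind = kind, low = low, high = high,
         threshold = threshold, positive_codes = positive_codes,
         units = as.character(units)),
    class = "feature_spec"
  )
}

#' @export
print.feature_spec <- function(x, ...) {
  rule <- switch(x$kind,
    range       = sprintf("out of [%g, %g] -> 1", x$low, x$high),
    threshold   = sprintf("> %g -> 1", x$threshold),
    binary      = ,
    categorical = paste0("in {", paste(x$positive_codes, collapse = ", "),
                         "} -> 1"))
  cat(sprintf("<feature_spec> %s (%s): %s%s\n", x$name, x$kind, rule,
              if (nzchar(x$units)) paste0("  [", x$units, "]") else ""))
  invisible(x)
}

#' Bundle feature specs into a named collection
#'
#' @param ... \code{feature_spec} objects, or a single list of them.
#' @return A named list of class \code{"feature_spec_list"}.
#' @export
feature_spec_list <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1L]], "feature_spec"))
    specs <- specs[[1L]]
  ok <- vapply(specs, inherits, logical(1), "feature_spec")
  if (!all(ok)) stop("all elements must be feature_spec objects")
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  if (anyDuplicated(names(specs)))
    stop("duplicated feature names: ",
         paste(unique(names(specs)[duplicated(names(specs))]), collapse = ", "))
  structure(specs, class = "feature_spec_list")
}

#' @export
print.feature_spec_list <- function(x, ...) {
  cat("<feature_spec_list> ", length(x), " features\n", sep = "")
  for (s in x) print(s)
  invisible(x)
}

#' Read / write feature-spec collections
#'
#' Specs are stored as YAML (or JSON) — a list of records with fields
#' \code{name}, \code{kind} and the kind's parameters, mirroring a
#' normal-values table.
#'
#' @param path file path; format chosen by extension (\code{.json} is JSON,
#'   anything else is parsed as YAML).
#' @return \code{read_feature_specs()}: a [feature_spec_list()].
#' @export
read_feature_specs <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  specs <- lapply(raw, function(r) {
    feature_spec(name = r$name, kind = r$kind,
                 low = r$low, high = r$high, threshold = r$threshold,
                 positive_codes = r$positive_codes,
                 units = if (is.null(r$units)) "" else r$units)
  })
  feature_spec_list(specs)
}

#' @rdname read_feature_specs
#' @param specs a [feature_spec_list()].
#' @export
write_feature_specs <- function(specs, path) {
  stopifnot(inherits(specs, "feature_spec_list"))
  recs <- lapply(unname(specs), function(s) {
    r <- s[!vapply(s, is.null, logical(1))]
    class(r) <- NULL
    r
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(recs, path)
  }
  invisible(path)
}

# Apply one spec to a raw vector -> 0/1 integer (NA preserved).
apply_spec <- function(spec, x) {
  if (spec$kind %in% c("binary", "categorical")) {
    out <- as.integer(x %in% spec$positive_codes)
    out[is.na(x)] <- NA_integer_
    return(out)
  }
  xn <- suppressWarnings(as.numeric(x))
  if (any(!is.na(x) & is.na(xn)))
    stop("feature '", spec$name, "': non-numeric value for a ", spec$kind,
         " spec")
  if (spec$kind == "range") {
    as.integer(xn < spec$low | xn > spec$high)
  } else {
    as.integer(xn > spec$threshold)
  }
}
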