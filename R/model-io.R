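# Versioned JSON serialization for fitted models.
#
# Doubles are written as "%.17g" strings (not JSON numbers) because 17
# significant digits are guaranteed to round-trip IEEE doubles exactly;
# reloaded models therefore re-predict bit-identically.

MODEL_FORMAT_VERSION <- 1L

#' Write a fitted model to a JSON file
#'
#' Serializes an [mlda_fit()] or [mpclr_fit()] model to a versioned JSON
#' file. Numeric payloads are stored at full precision, so a reloaded model
#' reproduces predictions bit-identically.
#'
#' @param model An `mlda_model` or `mpclr_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  kind <- if (inherits(model, "mlda_model")) "mlda_model"
          else if (inherits(model, "mpclr_model")) "mpclr_model"
          else stopf("`model` must be an mlda_model or mpclr_model.")
  payload <- list(
    format = "modlda-model",
    version = MODEL_FORMAT_VERSION,
    kind = kind,
    model = encode_values(unclass(model))
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, null = "null", digits = NA)
  writeLines(json, path)
  invisible(path)
}

#' Read a fitted model from a JSON file
#'
#' @param path A file written by [write_model()].
#' @return The deserialized `mlda_model` or `mpclr_model`.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stopf("Model file not found: %s", path)
  payload <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) {
      stopf("Cannot deserialize '%s': not valid model JSON (%s).",
            path, conditionMessage(e))
    }
  )
  if (!is.list(payload) || !identical(payload$format, "modlda-model")) {
    stopf("Cannot deserialize '%s': not a modlda model file.", path)
  }
  if (!identical(as.integer(payload$version), MODEL_FORMAT_VERSION)) {
    stopf("Model format version %s in '%s' is not supported (expected %d).",
          payload$version, path, MODEL_FORMAT_VERSION)
  }
  if (!payload$kind %in% c("mlda_model", "mpclr_model")) {
    stopf("Unknown model kind '%s' in '%s'.", payload$kind, path)
  }
  structure(decode_values(payload$model), class = payload$kind)
}

# ---- numeric-exact encoding ----------------------------------------------

# Recursively convert numeric leaves to tagged full-precision string form.
encode_values <- function(x) {
  if (is.list(x)) {
    lapply(x, encode_values)
  } else if (is.matrix(x) && is.numeric(x)) {
    list(
      .t = "matrix",
      dim = dim(x),
      dimnames = if (is.null(dimnames(x))) NULL else dimnames(x),
      data = sprintf("%.17g", as.vector(x))
    )
  } else if (is.numeric(x)) {
    list(
      .t = "numeric",
      names = if (is.null(names(x))) NULL else names(x),
      int = is.integer(x),
      data = sprintf("%.17g", as.vector(x))
    )
  } else if ((is.character(x) || is.logical(x)) && length(x) != 1L) {
    # keep vector-ness through fromJSON(simplifyVector = FALSE)
    list(.t = if (is.character(x)) "character" else "logical",
         names = if (is.null(names(x))) NULL else names(x),
         data = as.list(x))
  } else {
    x
  }
}

decode_values <- function(x) {
  if (!is.list(x)) return(simplify_atomic(x))
  tag <- x[[".t"]]
  # as.numeric("NA") maps to NA correctly but warns; silence it
  if (identical(tag, "matrix")) {
    m <- matrix(suppressWarnings(as.numeric(unlist(x$data))),
                nrow = x$dim[[1L]], ncol = x$dim[[2L]])
    if (!is.null(x$dimnames)) {
      dimnames(m) <- lapply(x$dimnames, function(d) as.character(unlist(d)))
    }
    return(m)
  }
  if (identical(tag, "numeric")) {
    v <- suppressWarnings(as.numeric(unlist(x$data)))
    if (isTRUE(x$int)) v <- as.integer(v)
    if (!is.null(x$names)) names(v) <- as.character(unlist(x$names))
    return(v)
  }
  if (identical(tag, "character") || identical(tag, "logical")) {
    v <- unlist(x$data)
    if (is.null(v)) v <- character(0)
    v <- if (identical(tag, "character")) as.character(v) else as.logical(v)
    if (!is.null(x$names)) names(v) <- as.character(unlist(x$names))
    return(v)
  }
  lapply(x, decode_values)
}

# fromJSON(simplifyVector = FALSE) returns scalars as length-1 vectors;
# non-tagged leaves pass through unchanged
simplify_atomic <- function(x) x
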