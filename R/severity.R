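#' Define an ordinal severity scale
#'
#' A scale is a strictly increasing vector of k-1 cut-offs plus k level
#' labels. Intervals are closed on the left and open on the right, read
#' directly from the published phrasing ("mild >= 3.5 and < 6.25"): a value
#' exactly equal to a cut-off takes the higher level.
#'
#' @param name scale name.
#' @param cutoffs strictly increasing numeric vector of thresholds.
#' @param labels character vector of level names, `length(cutoffs) + 1` long,
#'   ordered from least to most severe.
#' @return Object of class `severity_scale`.
#' @export
severity_scale <- function(name, cutoffs, labels) {
  cutoffs <- as.numeric(cutoffs)
  if (any(!is.finite(cutoffs)) || is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoffs must be finite and strictly increasing")
  labels <- as.character(labels)
  if (length(labels) != length(cutoffs) + 1L)
    stop("need exactly length(cutoffs) + 1 labels")
  structure(list(name = as.character(name), cutoffs = cutoffs,
                 labels = labels),
            class = "severity_scale")
}

#' @export
print.severity_scale <- function(x, ...) {
  cat("severity_scale '", x$name, "': ", sep = "")
  k <- length(x$labels)
  parts <- character(k)
  parts[1] <- paste0(x$labels[1], " < ", x$cutoffs[1])
  if (k > 2)
    for (i in 2:(k - 1))
      parts[i] <- paste0(x$labels[i], " [", x$cutoffs[i - 1], ", ",
                         x$cutoffs[i], ")")
  parts[k] <- paste0(x$labels[k], " >= ", x$cutoffs[k - 1])
  cat(paste(parts, collapse = "; "), "\n")
  invisible(x)
}

#' Classify an index value on a severity scale
#'
#' Values are classified at full precision; no rounding is applied first
#' (very small differences in the exact value can change the level, so any
#' rounding policy is left to the caller).
#'
#' @param value finite index value (percent).
#' @param scale a `severity_scale`.
#' @return Object of class `severity_level`: `scale_name`, `label`, and
#'   zero-based `ordinal` (0 = least severe).
#' @export
classify_severity <- function(value, scale) {
  stopifnot(inherits(scale, "severity_scale"))
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value))
    stop("value must be a single finite number")
  ord <- findInterval(value, scale$cutoffs)  # closed-left by default
  structure(list(scale_name = scale$name, label = scale$labels[ord + 1L],
                 ordinal = ord),
            class = "severity_level")
}

#' @export
print.severity_level <- function(x, ...) {
  cat(x$scale_name, ": ", x$label, " (ordinal ", x$ordinal, ")\n", sep = "")
  invisible(x)
}

#' Reduce a 5-level scale to 4 levels
#'
#' The middle level is split in half and each half is merged into the
#' adjacent level: with cutoffs `c1 < c2 < c3 < c4` the reduced scale has
#' cutoffs `(c1, (c2 + c3)/2, c4)`. Applied to the 5-level CVAI scale
#' (3.5, 6.25, 8.75, 11) this yields the 4-level "New CVAI" scale
#' (3.5, 7.5, 11) used for comparison against ODDI.
#'
#' @param scale5 a `severity_scale` with exactly 5 levels.
#' @param name name for the reduced scale (default `"New <name>"`).
#' @return A 4-level `severity_scale` labelled normal/mild/moderate/severe.
#' @export
reduce_five_to_four <- function(scale5, name = paste("New", scale5$name)) {
  stopifnot(inherits(scale5, "severity_scale"))
  if (length(scale5$labels) != 5L)
    stop("reduce_five_to_four requires a 5-level scale, got ",
         length(scale5$labels), " levels")
  cc <- scale5$cutoffs
  severity_scale(name, c(cc[1], (cc[2] + cc[3]) / 2, cc[4]),
                 c("normal", "mild", "moderate", "severe"))
}

#' Built-in severity scales
#'
#' The five published cut-off scales: the 5-level CVAI scale, its 4-level
#' reduction ("New CVAI"), the 4-level ODDI, CI and CPI scales (CI and CPI
#' share their cut-offs).
#'
#' @return Named list of `severity_scale` objects: `CVAI-5`, `NewCVAI-4`,
#'   `ODDI-4`, `CI-4`, `CPI-4`.
#' @export
builtin_scales <- function() {
  four <- c("normal", "mild", "moderate", "severe")
  cvai5 <- severity_scale("CVAI-5", c(3.5, 6.25, 8.75, 11),
                          c("normal", "mild", "moderate", "severe",
                            "very severe"))
  list(
    "CVAI-5"    = cvai5,
    "NewCVAI-4" = reduce_five_to_four(cvai5, name = "NewCVAI-4"),
    "ODDI-4"    = severity_scale("ODDI-4", c(104, 108, 112), four),
    "CI-4"      = severity_scale("CI-4", c(90, 95, 100), four),
    "CPI-4"     = severity_scale("CPI-4", c(90, 95, 100), four)
  )
}

#' Export / import severity scales as JSON
#'
#' Allows users to add custom scales; the JSON carries `name`, `cutoffs`
#' and `labels`.
#'
#' @param scale a `severity_scale`.
#' @param path file path.
#' @return `write_scale_json` returns `path` invisibly; `read_scale_json`
#'   returns a `severity_scale`.
#' @export
write_scale_json <- function(scale, path) {
  stopifnot(inherits(scale, "severity_scale"))
  jsonlite::write_json(list(name = scale$name, cutoffs = scale$cutoffs,
                            labels = scale$labels),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scale_json
#' @export
read_scale_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  severity_scale(x$name, x$cutoffs, x$labels)
}
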