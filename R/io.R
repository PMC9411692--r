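#' Read a skull case from disk
#'
#' Two layouts are accepted: a single JSON file
#' `{"units": str, "contour": [[x, y], ...], "landmarks": {"nose": [x, y],
#' "ear_left": [x, y], "ear_right": [x, y]}}`, or a two-column CSV of contour
#' vertices plus a landmark sidecar JSON (same `landmarks` object) given via
#' `landmarks_path`. The contour is validated and re-oriented
#' counterclockwise; landmarks are checked to lie inside the contour.
#'
#' @param path contour JSON or CSV file.
#' @param landmarks_path landmark sidecar JSON (required for CSV input;
#'   ignored for JSON input that already carries landmarks).
#' @return list with `contour` (`skull_contour`) and `landmarks`
#'   (`landmark_set`).
#' @export
read_case <- function(path, landmarks_path = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.null(x$contour)) stop("parse error at 'contour': field missing")
    contour <- skull_contour(x$contour,
                             units_label = if (is.null(x$units)) "" else x$units)
    lm_raw <- x$landmarks
    if (is.null(lm_raw) && !is.null(landmarks_path))
      lm_raw <- jsonlite::read_json(landmarks_path,
                                    simplifyVector = TRUE)$landmarks
    if (is.null(lm_raw)) stop("parse error at 'landmarks': field missing")
  } else if (ext == "csv") {
    v <- utils::read.csv(path)
    if (ncol(v) < 2L) stop("parse error at 'contour': need two columns x, y")
    contour <- skull_contour(as.matrix(v[, 1:2]))
    if (is.null(landmarks_path))
      stop("CSV contour requires a landmark sidecar JSON")
    lm_raw <- jsonlite::read_json(landmarks_path,
                                  simplifyVector = TRUE)$landmarks
    if (is.null(lm_raw))
      stop("parse error at 'landmarks': field missing in sidecar")
  } else stop("unsupported contour format: .", ext)

  for (nm in c("nose", "ear_left", "ear_right"))
    if (is.null(lm_raw[[nm]]))
      stop("parse error at 'landmarks.", nm, "': field missing")
  landmarks <- landmark_set(unlist(lm_raw$nose), unlist(lm_raw$ear_left),
                            unlist(lm_raw$ear_right), contour = contour)
  list(contour = contour, landmarks = landmarks)
}

#' Write a skull case to a contour JSON file
#'
#' @param contour a `skull_contour`.
#' @param landmarks a `landmark_set`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_case <- function(contour, landmarks, path) {
  stopifnot(inherits(contour, "skull_contour"),
            inherits(landmarks, "landmark_set"))
  obj <- list(units = contour$units_label,
              contour = unname(apply(contour$vertices, 1, c, simplify = FALSE)),
              landmarks = list(nose = landmarks$nose,
                               ear_left = landmarks$ear_left,
                               ear_right = landmarks$ear_right))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Extract a skull contour from a binary mask
#'
#' Finds the sub-pixel boundary of the single foreground component at the
#' 0.5 iso-level (marching squares), maps it through the affine transform
#' into model units, and resamples it uniformly by arc length.
#'
#' @param mask integer/logical matrix in image convention (row 1 = top),
#'   foreground > 0. Exactly one connected foreground component of at least
#'   500 px is required, and no foreground pixel may touch the image border.
#' @param transform affine transform as produced by [rasterize_mask()]
#'   (list `x0`, `y0`, `ppu`): pixel centers map to model units.
#' @param n_vertices number of resampled contour vertices (>= 256).
#' @return A `skull_contour` in model units.
#' @export
extract_contour_from_mask <- function(mask, transform, n_vertices = 512L) {
  mask <- (as.matrix(mask) > 0) * 1L
  nr <- nrow(mask); nc <- ncol(mask)
  area <- sum(mask)
  if (area == 0) stop("segmentation error: 0 foreground components")
  if (any(mask[1, ] > 0) || any(mask[nr, ] > 0) ||
      any(mask[, 1] > 0) || any(mask[, nc] > 0))
    stop("framing error: foreground touches the image border")
  labels <- EBImage::bwlabel(mask)
  ncomp <- max(labels)
  if (ncomp != 1L)
    stop("segmentation error: ", ncomp, " foreground components, expected 1")
  if (area < 500)
    stop("segmentation error: component area ", area, " px < 500 px")

  # reindex so contourLines x = column index, y = row index from the bottom
  z <- t(mask)[, nr:1, drop = FALSE]
  cls <- grDevices::contourLines(x = seq_len(nc), y = seq_len(nr), z = z,
                                 levels = 0.5)
  if (!length(cls)) stop("segmentation error: no boundary found")
  # largest boundary loop by enclosed area (holes give smaller loops)
  areas <- vapply(cls, function(cl) abs(pracma::polyarea(cl$x, cl$y)), 0)
  cl <- cls[[which.max(areas)]]
  mx <- transform$x0 + (cl$x - 0.5) / transform$ppu
  my <- transform$y0 + (cl$y - 0.5) / transform$ppu
  v <- .resample_closed(cbind(mx, my), max(256L, as.integer(n_vertices)))
  skull_contour(v)
}

# uniform arc-length resampling of a closed polyline
.resample_closed <- function(v, n_out) {
  if (sqrt(sum((v[1, ] - v[nrow(v), ])^2)) > 0) v <- rbind(v, v[1, ])
  seg <- sqrt(rowSums(diff(v)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  keep <- c(TRUE, seg > 0)
  v <- v[keep, , drop = FALSE]; s <- s[keep]
  target <- total * (seq_len(n_out) - 1) / n_out
  cbind(x = stats::approx(s, v[, 1], xout = target)$y,
        y = stats::approx(s, v[, 2], xout = target)$y)
}

#' Write / read a binary mask PNG
#'
#' The affine transform is stored in a JSON sidecar next to the PNG
#' (`<path>.transform.json`) so masks round-trip to model units.
#'
#' @param raster result of [rasterize_mask()].
#' @param path PNG output path.
#' @return `write_mask_png` returns `path` invisibly; `read_mask_png`
#'   returns a list `mask`, `transform`.
#' @export
write_mask_png <- function(raster, path) {
  png::writePNG(raster$mask * 1.0, path)
  jsonlite::write_json(raster$transform, paste0(path, ".transform.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  tr_path <- paste0(path, ".transform.json")
  if (!file.exists(tr_path)) stop("missing transform sidecar: ", tr_path)
  list(mask = (img > 0.5) * 1L,
       transform = jsonlite::read_json(tr_path, simplifyVector = TRUE))
}

#' Measure a batch of cases
#'
#' Runs the full measurement pipeline over a list of inputs and classifies
#' every index on the built-in severity scales. Failures are logged per case
#' and the batch continues.
#'
#' @param cases named list; each element is either a list with `contour` and
#'   `landmarks` (e.g. from [read_case()] or a `synthetic_case`), or a file
#'   path passed to [read_case()].
#' @param scales severity scales to apply (default [builtin_scales()]).
#' @return Object of class `measure_report`: `records` (list of per-case
#'   results), `failures` (named character vector of error messages),
#'   `table` (data frame, one row per successful case), and `status`
#'   (0 = all ok, 2 = partial, 1 = all failed).
#' @export
run_measure <- function(cases, scales = builtin_scales()) {
  if (is.null(names(cases)) || any(!nzchar(names(cases))))
    names(cases) <- paste0("case", seq_along(cases))
  records <- list(); failures <- character()
  for (id in names(cases)) {
    rec <- tryCatch({
      x <- cases[[id]]
      if (is.character(x)) x <- read_case(x)
      idx <- measure_all(x$contour, x$landmarks)
      levels <- list(
        "CVAI-5"    = classify_severity(idx$cvai, scales[["CVAI-5"]]),
        "NewCVAI-4" = classify_severity(idx$cvai, scales[["NewCVAI-4"]]),
        "ODDI-4"    = classify_severity(idx$oddi, scales[["ODDI-4"]]),
        "CI-4"      = classify_severity(idx$ci, scales[["CI-4"]]),
        "CPI-4"     = classify_severity(idx$cpi, scales[["CPI-4"]])
      )
      list(case_id = id, indices = idx, levels = levels)
    }, error = function(e) e)
    if (inherits(rec, "error")) failures[id] <- conditionMessage(rec)
    else records[[id]] <- rec
  }
  tab <- do.call(rbind, lapply(records, function(r) {
    data.frame(case_id = r$case_id,
               cvai = r$indices$cvai, ci = r$indices$ci,
               oddi = r$indices$oddi, cpi = r$indices$cpi,
               ear_ear = r$indices$ear_ear,
               nose_occiput = r$indices$nose_occiput,
               diag30_long = r$indices$diag30$long,
               diag30_short = r$indices$diag30$short,
               diag40_long = r$indices$diag40$long,
               diag40_short = r$indices$diag40$short,
               cvai5_level = r$levels[["CVAI-5"]]$label,
               newcvai4_level = r$levels[["NewCVAI-4"]]$label,
               oddi4_level = r$levels[["ODDI-4"]]$label,
               ci4_level = r$levels[["CI-4"]]$label,
               cpi4_level = r$levels[["CPI-4"]]$label,
               row.names = NULL)
  }))
  status <- if (!length(failures)) 0L else if (length(records)) 2L else 1L
  structure(list(records = records, failures = failures, table = tab,
                 status = status),
            class = "measure_report")
}

#' @export
print.measure_report <- function(x, ...) {
  cat("measure_report:", length(x$records), "measured,",
      length(x$failures), "failed\n")
  if (!is.null(x$table)) print(utils::head(x$table))
  invisible(x)
}

#' Published agreement tables
#'
#' The two packaged 4 x 4 severity cross-tabulations from the
#' method-comparison study of the photographic vertex-view method against
#' plagiocephalometry (n = 60 infants): `"plagiocephaly"` compares the
#' 4-level New CVAI against ODDI, `"brachycephaly"` compares CI against CPI.
#'
#' @param which `"plagiocephaly"` or `"brachycephaly"`.
#' @return A `crosstab` built from the packaged fixture.
#' @export
published_crosstab <- function(which = c("plagiocephaly", "brachycephaly")) {
  which <- match.arg(which)
  fname <- if (which == "plagiocephaly") "table1_newcvai_vs_oddi.csv"
           else "table2_ci_vs_cpi.csv"
  path <- system.file("extdata", fname, package = "cranioview")
  if (!nzchar(path)) stop("packaged fixture not found: ", fname)
  m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  crosstab_from_counts(m)
}
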