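#' @importFrom jsonlite fromJSON write_json
#' @importFrom stats prcomp pf pt p.adjust oneway.test rnorm runif sd uniroot
#' @importFrom utils read.csv write.csv
NULL

CERVICAL_LABELS <- c("C3", "C4", "C5", "C6", "C7")

#' Construct a radiograph annotation
#'
#' A radiograph annotation holds the labeled polygon outlines of the C3-C7
#' vertebral bodies on one lateral cervical radiograph, in image pixel
#' coordinates (x rightward, y downward, origin at the top-left corner).
#'
#' @param image_id Character identifier for the radiograph.
#' @param width,height Image dimensions in pixels.
#' @param vertebrae Named list mapping vertebra labels (`"C3"` ... `"C7"`)
#'   to n x 2 vertex matrices. Labels are normalized to upper case.
#' @return An object of class `radiograph_annotation`.
#' @export
radiograph_annotation <- function(image_id, width, height, vertebrae) {
  if (is.null(names(vertebrae)) || any(!nzchar(names(vertebrae))))
    stop("vertebrae must be a named list keyed by vertebra label")
  labels <- toupper(names(vertebrae))
  unknown <- setdiff(labels, CERVICAL_LABELS)
  if (length(unknown))
    stop("unknown vertebra label(s): ", paste(unknown, collapse = ", "))
  if (anyDuplicated(labels))
    stop("duplicate vertebra label(s): ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  vertebrae <- lapply(vertebrae, as_polygon)
  names(vertebrae) <- labels
  structure(
    list(image_id = as.character(image_id), width = as.numeric(width),
         height = as.numeric(height), vertebrae = vertebrae),
    class = "radiograph_annotation")
}

#' @export
print.radiograph_annotation <- function(x, ...) {
  cat("<radiograph_annotation> ", x$image_id, " (", x$width, " x ", x$height,
      " px)\n", sep = "")
  for (lab in names(x$vertebrae))
    cat("  ", lab, ": ", nrow(x$vertebrae[[lab]]), " vertices\n", sep = "")
  invisible(x)
}

#' Read polygon vertebral annotations from JSON
#'
#' The native annotation format is
#' `{"images": [{"image_id": str, "width": int, "height": int,
#' "vertebrae": {"C3": [[x, y], ...], ..., "C7": [[x, y], ...]}}]}`.
#' Vertebra labels are normalized to upper case; polygon coordinates are
#' preserved verbatim. Structural problems (missing fields, unknown or
#' duplicated labels, polygons with fewer than three listed vertices in a
#' malformed sense) raise an error naming the offending record; geometric
#' validity is the job of [validate_annotation()], which reports rather
#' than raises.
#'
#' @param path Path to an annotation JSON file.
#' @return List of [radiograph_annotation()] objects, in file order.
#' @seealso [write_annotations()], [validate_annotation()]
#' @export
load_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed annotation JSON in '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  if (!is.list(doc) || is.null(doc$images))
    stop("annotation JSON must contain a top-level \"images\" array")
  lapply(seq_along(doc$images), function(i) {
    rec <- doc$images[[i]]
    for (f in c("image_id", "width", "height", "vertebrae"))
      if (is.null(rec[[f]]))
        stop(sprintf("record %d ('%s'): missing field \"%s\"",
                     i, rec$image_id %||% "?", f))
    polys <- lapply(rec$vertebrae, function(v)
      do.call(rbind, lapply(v, function(pt) as.numeric(unlist(pt)))))
    names(polys) <- names(rec$vertebrae)
    tryCatch(
      radiograph_annotation(rec$image_id, rec$width, rec$height, polys),
      error = function(e)
        stop(sprintf("record %d ('%s'): %s", i, rec$image_id,
                     conditionMessage(e)), call. = FALSE))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write annotations to the native JSON format
#'
#' Inverse of [load_annotations()]: `load_annotations(write_annotations(x))`
#' reproduces the polygon coordinates exactly.
#'
#' @param annotations List of `radiograph_annotation` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  if (inherits(annotations, "radiograph_annotation"))
    annotations <- list(annotations)
  images <- lapply(annotations, function(a) {
    list(image_id = a$image_id, width = a$width, height = a$height,
         vertebrae = lapply(a$vertebrae, function(p)
           lapply(seq_len(nrow(p)), function(i) as.numeric(p[i, ]))))
  })
  jsonlite::write_json(list(images = images), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate a radiograph annotation
#'
#' Checks that all five labels C3-C7 are present, that each polygon is a
#' simple polygon with positive enclosed area, and that all vertices lie
#' within the image frame. Reports issues; never raises.
#'
#' @param a A `radiograph_annotation`.
#' @return Character vector of issue codes, e.g. `"MISSING_LABEL(C4)"`,
#'   `"DEGENERATE_POLYGON(C5)"`, `"NON_SIMPLE_POLYGON(C3)"`,
#'   `"OUT_OF_BOUNDS(C7)"`. Empty when the record is measurable.
#' @export
validate_annotation <- function(a) {
  stopifnot(inherits(a, "radiograph_annotation"))
  issues <- character()
  for (lab in CERVICAL_LABELS) {
    p <- a$vertebrae[[lab]]
    if (is.null(p)) {
      issues <- c(issues, sprintf("MISSING_LABEL(%s)", lab))
      next
    }
    if (nrow(p) < 3L) {
      issues <- c(issues, sprintf("DEGENERATE_POLYGON(%s)", lab))
      next
    }
    if (!is_simple_polygon(p)) {
      # a self-intersecting outline is reported as such even when its
      # signed area also cancels to zero (e.g. a symmetric bow-tie)
      issues <- c(issues, sprintf("NON_SIMPLE_POLYGON(%s)", lab))
      next
    }
    if (abs(polygon_area_signed(p)) < 1e-12) {
      issues <- c(issues, sprintf("DEGENERATE_POLYGON(%s)", lab))
      next
    }
    if (any(p[, 1] < 0 | p[, 1] > a$width | p[, 2] < 0 | p[, 2] > a$height))
      issues <- c(issues, sprintf("OUT_OF_BOUNDS(%s)", lab))
  }
  issues
}

#' Write an alignment-parameter table to CSV
#'
#' @param rows Data frame with columns `image_id`, `sva`, `lordosis_deg`,
#'   `vertical_length`, `curved_length` (as produced by [run_measure()]),
#'   or a list of `(image_id, alignment_parameters)` pairs.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_parameters_table <- function(rows, path) {
  if (is.list(rows) && !is.data.frame(rows))
    rows <- do.call(rbind, lapply(rows, function(r)
      data.frame(image_id = r[[1]], as.data.frame(r[[2]]))))
  cols <- c("image_id", "sva", "lordosis_deg", "vertical_length",
            "curved_length")
  if (!is.data.frame(rows) || nrow(rows) == 0L)
    stop("no parameter rows to write")
  if (!all(cols %in% names(rows)))
    stop("parameter table must have columns: ", paste(cols, collapse = ", "))
  utils::write.csv(rows[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read an alignment-parameter table written by [write_parameters_table()]
#' @param path CSV path.
#' @return Data frame.
#' @export
read_parameters_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
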