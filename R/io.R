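ANNOTATION_SCHEMA_VERSION <- 1L

#' Annotation file object
#'
#' In-memory form of the JSON annotation format: image filename, image size,
#' the ten named landmarks, and optionally the fiducial circle and a rater
#' identifier.
#'
#' @param image Image filename (basename).
#' @param image_size `c(width, height)` in px.
#' @param landmarks A [landmark_set()]; coordinates must lie within the
#'   image bounds.
#' @param sticker Optional list `(cx, cy, radius)` in px.
#' @param rater Optional rater identifier string.
#' @param strict Enforce the lid-ordering invariant as an error; raw
#'   detector output may violate it, in which case `strict = FALSE` keeps it
#'   as a warning.
#' @return A list of class `annotation_file`.
#' @export
annotation_file <- function(image, image_size, landmarks, sticker = NULL,
                            rater = NULL, strict = TRUE) {
  lm <- landmark_set(landmarks, strict = strict)
  validate_landmarks_in_bounds(lm, image_size[1], image_size[2])
  structure(list(schema_version = ANNOTATION_SCHEMA_VERSION,
                 image = as.character(image),
                 image_size = as.integer(image_size),
                 landmarks = lm, sticker = sticker, rater = rater),
            class = "annotation_file")
}

#' Write an annotation file
#'
#' Serialises to a canonical JSON form: fixed key order, landmarks as an
#' ordered array of `{name, x, y}` objects. Writing then re-reading
#' reproduces the coordinates, and re-writing a read file is byte-stable.
#'
#' @param ann An [annotation_file()] (or a bare [landmark_set()] plus
#'   `image_size` via [annotation_file()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_file"))
  lm <- ann$landmarks
  obj <- list(
    schema_version = ann$schema_version,
    image = ann$image,
    image_size = list(width = ann$image_size[1], height = ann$image_size[2]),
    landmarks = lapply(seq_len(nrow(lm)), function(i)
      list(name = rownames(lm)[i], x = lm[i, "x"], y = lm[i, "y"]))
  )
  if (!is.null(ann$sticker))
    obj$sticker <- list(cx = ann$sticker$cx, cy = ann$sticker$cy,
                        radius = ann$sticker$radius)
  if (!is.null(ann$rater)) obj$rater <- ann$rater
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

schema_stop <- function(key, why) {
  stop("annotation schema error at '", key, "': ", why, call. = FALSE)
}

#' Read an annotation file
#'
#' Validates the schema strictly: all required keys present, exactly the ten
#' canonical landmark names, and coordinates within the stated image bounds.
#'
#' @param path Path to a JSON annotation file.
#' @return An [annotation_file()].
#' @export
read_annotations <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  for (key in c("schema_version", "image", "image_size", "landmarks"))
    if (is.null(obj[[key]])) schema_stop(key, "missing required field")
  sz <- obj$image_size
  if (is.null(sz$width) || is.null(sz$height))
    schema_stop("image_size", "needs width and height")
  lms <- obj$landmarks
  if (length(lms) != 10)
    schema_stop("landmarks", paste0("expected 10 landmarks, found ",
                                    length(lms)))
  nm <- vapply(lms, function(l) {
    if (is.null(l$name)) schema_stop("landmarks.name", "missing")
    l$name
  }, "")
  canon <- landmark_names()
  if (!setequal(nm, canon) || anyDuplicated(nm))
    schema_stop("landmarks.name",
                paste0("names must be exactly the canonical roles; got: ",
                       paste(nm, collapse = ", ")))
  xy <- matrix(NA_real_, 10, 2)
  for (l in lms) {
    i <- match(l$name, canon)
    if (is.null(l$x) || is.null(l$y))
      schema_stop(paste0("landmarks[", l$name, "]"), "missing x or y")
    xy[i, ] <- c(l$x, l$y)
  }
  w <- sz$width; h <- sz$height
  bad <- which(xy[, 1] < 0 | xy[, 1] > w - 1 | xy[, 2] < 0 | xy[, 2] > h - 1)
  if (length(bad))
    schema_stop(paste0("landmarks[", canon[bad[1]], "]"),
                "coordinate outside image bounds")
  sticker <- if (!is.null(obj$sticker))
    list(cx = obj$sticker$cx, cy = obj$sticker$cy, radius = obj$sticker$radius)
  annotation_file(obj$image, c(w, h), xy, sticker = sticker,
                  rater = obj$rater, strict = FALSE)
}

#' Write a dataset to disk
#'
#' Writes each scene as a PNG plus a JSON annotation file, and a manifest
#' CSV recording the true millimetre values, scale and per-sample seed.
#'
#' @param dataset A [make_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "annotations"), showWarnings = FALSE)
  for (s in dataset) {
    img_name <- paste0(s$id, ".png")
    png::writePNG(s$image, file.path(dir, "images", img_name))
    ann <- annotation_file(img_name, s$params$image_size, s$landmarks_true,
                           sticker = list(cx = s$sticker_circle_true$centre[1],
                                          cy = s$sticker_circle_true$centre[2],
                                          radius = s$sticker_circle_true$radius),
                           rater = "synthetic-truth")
    write_annotations(ann, file.path(dir, "annotations",
                                     paste0(s$id, ".json")))
  }
  manifest <- attr(dataset, "manifest")
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = attr(dataset, "seed"),
                            n = length(dataset),
                            schema_version = ANNOTATION_SCHEMA_VERSION),
                       file.path(dir, "dataset.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Dataset directory.
#' @return List of `list(image, landmarks, id)` elements usable by
#'   [train_detector()].
#' @export
read_dataset <- function(dir) {
  ann_files <- sort(list.files(file.path(dir, "annotations"),
                               full.names = TRUE, pattern = "\\.json$"))
  if (!length(ann_files)) stop("no annotation files under ", dir)
  lapply(ann_files, function(f) {
    ann <- read_annotations(f)
    img <- png::readPNG(file.path(dir, "images", ann$image))
    if (length(dim(img)) == 3 && dim(img)[3] > 3) img <- img[, , 1:3]
    list(image = img, landmarks = ann$landmarks,
         id = sub("\\.json$", "", basename(f)))
  })
}

#' Write measurement records to CSV
#'
#' Millimetre columns are written with two decimal places; the scale column
#' keeps full precision.
#'
#' @param records Data frame of stacked `measurement_record` rows (a column
#'   `id` is kept first if present).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  df <- as.data.frame(records)
  mm_cols <- intersect(c("mrd1_right", "mrd1_left", "mrd2_right", "mrd2_left",
                         "pfh_right", "pfh_left", "hpa_right", "hpa_left",
                         "ipd", "iicd", "oicd"), names(df))
  for (cc in mm_cols) df[[cc]] <- round(df[[cc]], 2)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a measurement CSV
#'
#' @param path CSV written by [write_measurements()].
#' @return Data frame.
#' @export
read_measurements <- function(path) {
  df <- read.csv(path)
  need <- c("mrd1_right", "mrd1_left", "mrd2_right", "mrd2_left",
            "pfh_right", "pfh_left", "hpa_right", "hpa_left",
            "ipd", "iicd", "oicd")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("measurement CSV is missing column(s): ",
         paste(missing, collapse = ", "))
  df
}
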