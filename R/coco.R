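# COCO-dialect annotation JSON and index-CSV I/O. Boxes are stored as
# (x, y, width, height) per the COCO convention; in-memory boxes are corner
# format (x_min, y_min, x_max, y_max), half-open on the max edge.

#' Convert between corner and COCO box formats
#'
#' @param box Numeric length-4 vector or a 4-column matrix.
#' @return The converted box(es): `box_to_coco()` gives `(x, y, w, h)`,
#'   `box_from_coco()` gives `(x_min, y_min, x_max, y_max)`.
#' @export
box_to_coco <- function(box) {
  if (is.matrix(box))
    return(cbind(x = box[, 1], y = box[, 2],
                 width = box[, 3] - box[, 1], height = box[, 4] - box[, 2]))
  c(x = box[1], y = box[2], width = box[3] - box[1], height = box[4] - box[2])
}

#' @rdname box_to_coco
#' @export
box_from_coco <- function(box) {
  if (is.matrix(box))
    return(cbind(x_min = box[, 1], y_min = box[, 2],
                 x_max = box[, 1] + box[, 3], y_max = box[, 2] + box[, 4]))
  c(x_min = box[1], y_min = box[2],
    x_max = box[1] + box[3], y_max = box[2] + box[4])
}

#' Write a COCO-style annotation file
#'
#' @param annotations Data frame with columns `image_id`, corner box columns
#'   and `label` (category id).
#' @param index Data frame with `image_id`, `image_path`; image sizes taken
#'   from `image_size`.
#' @param image_size `c(height, width)` applied to all images.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(annotations, index, image_size, path) {
  cats <- data.frame(id = 1:4, name = c("I", "II", "III", "IV"),
                     supercategory = "fracture")
  imgs <- data.frame(id = index$image_id, file_name = index$image_path,
                     height = image_size[1], width = image_size[2])
  bb <- box_to_coco(as.matrix(annotations[, c("x_min", "y_min",
                                              "x_max", "y_max")]))
  anns <- lapply(seq_len(nrow(annotations)), function(i) {
    list(id = i, image_id = annotations$image_id[i],
         category_id = annotations$label[i],
         bbox = as.numeric(bb[i, ]),
         area = as.numeric(bb[i, "width"] * bb[i, "height"]),
         iscrowd = 0L)
  })
  jsonlite::write_json(list(images = imgs, annotations = anns,
                            categories = cats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO-style annotation file back to corner-format boxes
#'
#' @param path JSON path written by [write_coco()] (or compatible).
#' @return List with `annotations` (data frame: image_id, x_min, y_min,
#'   x_max, y_max, label), `images`, `categories`.
#' @export
read_coco <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  a <- j$annotations
  bb <- do.call(rbind, a$bbox)
  corners <- box_from_coco(bb)
  ann <- data.frame(image_id = a$image_id,
                    x_min = corners[, 1], y_min = corners[, 2],
                    x_max = corners[, 3], y_max = corners[, 4],
                    label = a$category_id)
  list(annotations = ann, images = j$images, categories = j$categories)
}

#' Write a synthetic dataset to disk
#'
#' PNG images, `annotations.json` (COCO dialect) and `index.csv` with
#' columns image_path, class_label, site_label.
#'
#' @param ds A `synthetic_dataset` from [make_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(ds$images))
    write_gray_png(ds$images[[i]], file.path(dir, ds$index$image_path[i]))
  write_coco(ds$annotations, ds$index, ds$image_size,
             file.path(dir, "annotations.json"))
  utils::write.csv(ds$index[, c("image_path", "class_label", "site_label")],
                   file.path(dir, "index.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an index CSV mapping images to labels
#'
#' @param path CSV with columns `image_path`, `class_label`, `site_label`.
#' @return Data frame with an added integer `image_id`.
#' @export
read_index <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$image_id <- seq_len(nrow(df))
  df
}
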