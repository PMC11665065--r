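# COCO-dialect annotation I/O. Masks are stored with the uncompressed
# run-length encoding of the COCO dialect: the mask is flattened
# column-major and `counts` lists run lengths of alternating values
# starting with the number of zeros.

#' Run-length encode a binary mask (COCO dialect)
#'
#' @param mask binary matrix (H x W).
#' @return list with `size = c(H, W)` and integer `counts`.
#' @export
rle_encode <- function(mask) {
  v <- as.integer(as.vector(mask != 0))  # column-major flatten
  r <- rle(v)
  counts <- r$lengths
  if (length(v) && r$values[1] == 1L) counts <- c(0L, counts)
  list(size = c(nrow(mask), ncol(mask)), counts = as.integer(counts))
}

#' Decode a COCO run-length encoding back into a binary mask
#'
#' @param rle list with `size` and `counts` as from [rle_encode()].
#' @return binary integer matrix (H x W).
#' @export
rle_decode <- function(rle) {
  h <- rle$size[1]; w <- rle$size[2]
  counts <- rle$counts
  vals <- rep(c(0L, 1L), length.out = length(counts))
  v <- rep(vals, times = counts)
  if (length(v) != h * w)
    stop(sprintf("RLE counts sum to %d but size is %dx%d = %d",
                 length(v), h, w, h * w), call. = FALSE)
  matrix(v, nrow = h, ncol = w)
}

mask_bbox <- function(mask) {
  w <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(w)) return(c(0, 0, 0, 0))
  # COCO bbox: [x, y, width, height], 0-based top-left corner
  c(min(w[, 2]) - 1, min(w[, 1]) - 1,
    max(w[, 2]) - min(w[, 2]) + 1, max(w[, 1]) - min(w[, 1]) + 1)
}

#' Write patches and annotations in COCO-dialect JSON
#'
#' Writes one JSON file with `images`, `annotations` (RLE segmentations,
#' category "nucleus") and `categories`. If `image_dir` is given, patch
#' images are also written there as 8-bit RGB PNG.
#'
#' @param patches list of `synthetic_scene` patches.
#' @param path output JSON path.
#' @param file_names optional character vector of image file names
#'   (defaults to patch_0001.png, ...).
#' @param image_dir optional directory for PNG images.
#' @return invisibly, `path`.
#' @export
write_annotations <- function(patches, path, file_names = NULL,
                              image_dir = NULL) {
  if (is.null(file_names))
    file_names <- sprintf("patch_%04d.png", seq_along(patches))
  images <- lapply(seq_along(patches), function(i)
    list(id = i, file_name = file_names[i],
         width = patches[[i]]$width, height = patches[[i]]$height))
  annotations <- list()
  aid <- 0L
  for (i in seq_along(patches)) {
    p <- patches[[i]]
    n <- max(0L, max(p$label_map))
    for (j in seq_len(n)) {
      m <- (p$label_map == j) * 1L
      aid <- aid + 1L
      annotations[[aid]] <- list(
        id = aid, image_id = i, category_id = 1L,
        segmentation = rle_encode(m),
        area = sum(m), bbox = mask_bbox(m), iscrowd = 0L)
    }
  }
  obj <- list(
    images = images,
    annotations = annotations,
    categories = list(list(id = 1L, name = "nucleus"))
  )
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(image_dir)) {
    dir.create(image_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(patches))
      write_scene_png(patches[[i]], file.path(image_dir, file_names[i]))
  }
  invisible(path)
}

#' Read a COCO-dialect annotation file
#'
#' @param path JSON path written by [write_annotations()] (or any COCO file
#'   with uncompressed RLE segmentations).
#' @return named list (by image file name) of [instance_set()]s; images
#'   without annotations yield empty sets. The `images` data.frame is
#'   attached as an attribute.
#' @export
read_annotations <- function(path) {
  obj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("cannot parse annotation file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  for (field in c("images", "annotations", "categories"))
    if (is.null(obj[[field]]))
      stop(sprintf("annotation file '%s' lacks the '%s' record", path, field),
           call. = FALSE)
  img_ids <- vapply(obj$images, function(x) as.integer(x$id), integer(1))
  sets <- stats::setNames(vector("list", length(obj$images)),
                          vapply(obj$images, function(x) x$file_name, character(1)))
  buckets <- split(obj$annotations,
                   vapply(obj$annotations, function(a) as.integer(a$image_id),
                          integer(1)))
  for (i in seq_along(obj$images)) {
    anns <- buckets[[as.character(img_ids[i])]]
    if (is.null(anns)) {
      sets[[i]] <- instance_set(list())
      next
    }
    masks <- lapply(seq_along(anns), function(j) {
      seg <- anns[[j]]$segmentation
      if (is.null(seg$counts))
        stop(sprintf("annotation id %s of image %d in '%s' has no RLE counts",
                     anns[[j]]$id, img_ids[i], path), call. = FALSE)
      rle_decode(list(size = unlist(seg$size), counts = unlist(seg$counts)))
    })
    scores <- vapply(anns, function(a) as.numeric(a$score %||% 1), numeric(1))
    cats <- vapply(anns, function(a) as.integer(a$category_id), integer(1))
    sets[[i]] <- instance_set(masks, scores, cats)
  }
  attr(sets, "images") <- data.frame(
    id = img_ids,
    file_name = names(sets),
    width = vapply(obj$images, function(x) as.integer(x$width), integer(1)),
    height = vapply(obj$images, function(x) as.integer(x$height), integer(1)))
  sets
}

#' Write prediction results in COCO-dialect JSON
#'
#' @param results named list (by image file name) of [instance_set()]s.
#' @param path output JSON path.
#' @param image_ids optional integer ids parallel to `results` (default
#'   seq_along).
#' @return invisibly, `path`.
#' @export
write_results <- function(results, path, image_ids = seq_along(results)) {
  out <- list()
  for (i in seq_along(results)) {
    r <- results[[i]]
    for (j in seq_along(r$masks))
      out[[length(out) + 1L]] <- list(
        image_id = image_ids[i], category_id = r$categories[j],
        segmentation = rle_encode(r$masks[[j]]), score = r$scores[j],
        file_name = names(results)[i])
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read prediction results written by [write_results()]
#'
#' @param path JSON path.
#' @param file_names image file names defining the image order (results for
#'   absent images come back empty).
#' @return named list of [instance_set()]s parallel to `file_names`.
#' @export
read_results <- function(path, file_names) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  sets <- stats::setNames(
    replicate(length(file_names), instance_set(list()), simplify = FALSE),
    file_names)
  for (a in obj) {
    nm <- a$file_name
    if (is.null(sets[[nm]])) next
    m <- rle_decode(list(size = unlist(a$segmentation$size),
                         counts = unlist(a$segmentation$counts)))
    s <- sets[[nm]]
    sets[[nm]] <- instance_set(c(s$masks, list(m)), c(s$scores, a$score),
                               c(s$categories, a$category_id))
  }
  sets
}

#' Write a scene image as 8-bit RGB PNG
#'
#' @param scene a `synthetic_scene`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_scene_png <- function(scene, path) {
  png::writePNG(scene$image / 255, path)
  invisible(path)
}

#' Read an RGB PNG as a (1, 3, H, W) input tensor in `[0, 1]`
#'
#' @param path PNG path.
#' @return numeric array dim (1, 3, H, W).
#' @export
read_image_tensor <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  x <- array(0, dim = c(1, 3, dim(img)[1], dim(img)[2]))
  for (ch in 1:3) x[1, ch, , ] <- img[, , ch]
  x
}

# image array (H, W, 3) in 0..255 -> (1, 3, H, W) in [0, 1]
scene_tensor <- function(scene) {
  x <- array(0, dim = c(1, 3, scene$height, scene$width))
  for (ch in 1:3) x[1, ch, , ] <- scene$image[, , ch] / 255
  x
}
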