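# Reading and writing fundus image pairs and their ONH annotations.

#' Write a fundus pair as 16-bit TIFFs with a JSON annotation sidecar
#'
#' Writes `img_532.tif`, `img_633.tif` (16-bit grayscale, lossless) and
#' `annotations.json` holding the ONH center and radius (px), the pixel
#' scale, and any extra metadata.
#'
#' @param pair A `fundus_pair`.
#' @param dir Output directory (created if needed).
#' @param meta Named list of extra annotation fields (e.g. subject id).
#' @return `dir`, invisibly.
#' @export
write_fundus_pair <- function(pair, dir, meta = list()) {
  stopifnot(inherits(pair, "fundus_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tiff::writeTIFF(pair$image_532, file.path(dir, "img_532.tif"),
                  bits.per.sample = 16)
  tiff::writeTIFF(pair$image_633, file.path(dir, "img_633.tif"),
                  bits.per.sample = 16)
  ann <- c(list(onh_center = pair$onh_center, onh_radius = pair$onh_radius,
                um_per_px = pair$um_per_px), meta)
  jsonlite::write_json(ann, file.path(dir, "annotations.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a fundus pair written by [write_fundus_pair()]
#'
#' @param dir Directory containing `img_532.tif`, `img_633.tif` and
#'   `annotations.json`.
#' @return A `fundus_pair`; extra annotation fields are attached as the
#'   `meta` attribute.
#' @export
read_fundus_pair <- function(dir) {
  ann_path <- file.path(dir, "annotations.json")
  if (!file.exists(ann_path)) {
    abort(sprintf("No annotations.json in %s", dir), class = "oxy_input")
  }
  ann <- jsonlite::read_json(ann_path, simplifyVector = TRUE)
  img5 <- tiff::readTIFF(file.path(dir, "img_532.tif"))
  img6 <- tiff::readTIFF(file.path(dir, "img_633.tif"))
  pair <- structure(
    list(image_532 = img5, image_633 = img6,
         onh_center = as.numeric(ann$onh_center),
         onh_radius = as.numeric(ann$onh_radius),
         um_per_px = as.numeric(ann$um_per_px)),
    class = "fundus_pair"
  )
  attr(pair, "meta") <- ann[setdiff(names(ann),
                                    c("onh_center", "onh_radius",
                                      "um_per_px"))]
  pair
}
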