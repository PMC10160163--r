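#' Write a case directory
#'
#' Serializes a cine sequence and its optional companions to a case directory:
#' `frames.nii.gz`, `vx.nii.gz` / `vy.nii.gz`, `labels.nii.gz` (all stored
#' `[H, W, T]` in NIfTI axis order, float64), `meta.json` with the acquisition
#' metadata, and `contours.csv`.
#'
#' @param path directory to create/overwrite.
#' @param cine a [cine_sequence()].
#' @param flow optional [flow_field()] paired with `cine`.
#' @param mask optional [blood_pool_mask()].
#' @param contours optional [contour_set()].
#' @return `path`, invisibly.
#' @export
write_case <- function(path, cine, flow = NULL, mask = NULL, contours = NULL) {
  stopifnot(inherits(cine, "cine_sequence"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write_stack <- function(a, file)
    RNifti::writeNifti(aperm(a, c(2L, 3L, 1L)), file.path(path, file), datatype = "double")
  write_stack(cine$frames, "frames.nii.gz")
  meta <- cine$meta
  jsonlite::write_json(
    list(ps_x = meta$pixel_spacing[1], ps_y = meta$pixel_spacing[2],
         frame_interval = meta$frame_interval, heart_rate = meta$heart_rate,
         n_phases = meta$n_phases),
    file.path(path, "meta.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(flow)) {
    stopifnot(inherits(flow, "flow_field"))
    if (!identical(dim(flow$vx), dim(cine$frames)))
      stop("flow and cine shapes disagree", call. = FALSE)
    write_stack(flow$vx, "vx.nii.gz")
    write_stack(flow$vy, "vy.nii.gz")
  }
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "blood_pool_mask"))
    if (!identical(dim(mask$labels), dim(cine$frames)))
      stop("mask and cine shapes disagree", call. = FALSE)
    write_stack(mask$labels, "labels.nii.gz")
  }
  if (!is.null(contours)) {
    stopifnot(inherits(contours, "contour_set"))
    utils::write.csv(as.data.frame(unclass_tbl(contours)),
                     file.path(path, "contours.csv"), row.names = FALSE)
  }
  invisible(path)
}

unclass_tbl <- function(x) { class(x) <- "data.frame"; x }

#' Read a case directory
#'
#' Inverse of [write_case()]. The frames stack and metadata are mandatory;
#' flow, mask and contours are returned as `NULL` when absent. All components
#' are validated for mutual shape consistency.
#'
#' @param path case directory written by [write_case()].
#' @return A list with elements `cine`, `flow`, `mask`, `contours`.
#' @export
read_case <- function(path) {
  if (!dir.exists(path)) stop("case directory does not exist: ", path, call. = FALSE)
  fr_file <- file.path(path, "frames.nii.gz")
  meta_file <- file.path(path, "meta.json")
  if (!file.exists(fr_file)) stop("case container lacks frames.nii.gz", call. = FALSE)
  if (!file.exists(meta_file)) stop("case container lacks meta.json", call. = FALSE)
  read_stack <- function(file) {
    img <- RNifti::readNifti(file.path(path, file))
    aperm(array(as.numeric(img), dim(img)), c(3L, 1L, 2L))
  }
  mj <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  meta <- acquisition_meta(c(mj$ps_x, mj$ps_y), mj$frame_interval, mj$heart_rate, mj$n_phases)
  frames <- read_stack("frames.nii.gz")
  cine <- cine_sequence(frames, meta)
  flow <- NULL
  if (file.exists(file.path(path, "vx.nii.gz"))) {
    if (!file.exists(file.path(path, "vy.nii.gz")))
      stop("case has vx but not vy", call. = FALSE)
    flow <- flow_field(read_stack("vx.nii.gz"), read_stack("vy.nii.gz"))
    if (!identical(dim(flow$vx), dim(frames)))
      stop("flow and frames shapes disagree", call. = FALSE)
  }
  mask <- NULL
  if (file.exists(file.path(path, "labels.nii.gz"))) {
    mask <- blood_pool_mask(read_stack("labels.nii.gz"))
    if (!identical(dim(mask$labels), dim(frames)))
      stop("mask and frames shapes disagree", call. = FALSE)
  }
  contours <- NULL
  if (file.exists(file.path(path, "contours.csv")))
    contours <- contour_set(utils::read.csv(file.path(path, "contours.csv")))
  list(cine = cine, flow = flow, mask = mask, contours = contours)
}
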