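# NIfTI input/output and result bundles. Volumes and label maps are plain
# 3-d NIfTI images; vector fields are stored as 5-d images with dimensions
# (n1, n2, n3, 1, 3) and vector intent, the conventional displacement-field
# layout, in voxel units (a flag converts to physical mm via the header
# spacing on write).

#' Read a 3-d volume from NIfTI
#'
#' @param path NIfTI-1/2 file (.nii or .nii.gz).
#' @return 3-d numeric array with attributes `spacing` (voxel sizes, mm)
#'   and `pixdim` preserved from the header.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3L && all(d[-(1:3)] == 1L)) d <- d[1:3]
  if (length(d) != 3L)
    stop(sprintf("%s is not a 3-d volume", path), call. = FALSE)
  out <- array(as.numeric(img), dim = d)
  attr(out, "spacing") <- RNifti::pixdim(img)[1:3]
  out
}

#' Read an integer label map from NIfTI
#'
#' @param path NIfTI file.
#' @return integer 3-d array (0 = background), attribute `spacing`.
#' @export
read_labels <- function(path) {
  vol <- read_volume(path)
  if (any(abs(vol - round(vol)) > 1e-6) || any(vol < 0))
    stop(sprintf("%s does not contain non-negative integer labels", path),
         call. = FALSE)
  sp <- attr(vol, "spacing")
  out <- array(as.integer(round(vol)), dim = dim(vol))
  attr(out, "spacing") <- sp
  out
}

#' Read a 3-component vector field from NIfTI
#'
#' Accepts `(n1, n2, n3, 3)` or the conventional `(n1, n2, n3, 1, 3)`
#' displacement layout.
#'
#' @param path NIfTI file.
#' @return 4-d array `(n1, n2, n3, 3)`.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  a <- array(as.numeric(img), dim = d)
  if (length(d) == 5L && d[4] == 1L) {
    a <- array(a, dim = d[c(1:3, 5L)])
    d <- dim(a)
  }
  if (length(d) != 4L || d[4] != 3L)
    stop(sprintf("%s is not a 3-component vector field (got %s components)",
                 path, if (length(d) >= 4) d[length(d)] else 1),
         call. = FALSE)
  a
}

#' Write a volume or label map to NIfTI
#'
#' @param vol 3-d array.
#' @param path output path (.nii or .nii.gz).
#' @param spacing voxel sizes in mm (default: `spacing` attribute or 1).
#' @export
write_volume <- function(vol, path, spacing = NULL) {
  if (is.null(spacing)) spacing <- attr(vol, "spacing")
  if (is.null(spacing)) spacing <- c(1, 1, 1)
  img <- RNifti::asNifti(array(as.numeric(vol), dim = dim(vol)[1:3]))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a vector field to NIfTI
#'
#' Written as a 5-d `(n1, n2, n3, 1, 3)` image with vector intent, in voxel
#' units by default.
#'
#' @param u 4-d array `(n1, n2, n3, 3)`.
#' @param path output path.
#' @param spacing voxel sizes, mm.
#' @param units `"voxel"` (default) or `"mm"`: with `"mm"` each component
#'   is multiplied by its voxel size before writing.
#' @export
write_field <- function(u, path, spacing = c(1, 1, 1),
                        units = c("voxel", "mm")) {
  units <- match.arg(units)
  d <- dim(u)
  if (length(d) != 4L || d[4] != 3L)
    stop("u must be a 4-d array (n1, n2, n3, 3)", call. = FALSE)
  if (units == "mm")
    for (c_ in 1:3) u[, , , c_] <- u[, , , c_] * spacing[c_]
  arr <- array(u, dim = c(d[1:3], 1L, 3L))
  img <- RNifti::asNifti(arr)
  img <- RNifti::asNifti(img, reference = list(intent_code = 1007L))
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a registration result bundle to a directory
#'
#' Writes warped volumes, the forward and inverse displacement fields, the
#' loss trace (CSV), summary metrics (JSON), the configuration (YAML) and a
#' manifest with MD5 checksums of every artifact.
#'
#' @param result an [mdreg] object.
#' @param outdir output directory (created if needed).
#' @param spacing voxel sizes, mm.
#' @return the manifest, invisibly (list of file names and checksums).
#' @export
write_result <- function(result, outdir, spacing = c(1, 1, 1)) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  files <- character(0)
  wv <- function(obj, name, writer) {
    p <- file.path(outdir, name)
    writer(obj, p)
    files[[length(files) + 1L]] <<- p
  }
  wv(result$warped_moving, "warped_moving.nii.gz",
     function(o, p) write_volume(o, p, spacing))
  wv(result$warped_fixed, "warped_fixed.nii.gz",
     function(o, p) write_volume(o, p, spacing))
  wv(result$forward_field, "forward_field.nii.gz",
     function(o, p) write_field(o, p, spacing))
  wv(result$inverse_field, "inverse_field.nii.gz",
     function(o, p) write_field(o, p, spacing))
  if (!is.null(result$loss_trace)) {
    p <- file.path(outdir, "loss_trace.csv")
    write.csv(result$loss_trace, p, row.names = FALSE)
    files[[length(files) + 1L]] <- p
  }
  s <- summary(result)
  metrics <- list(mode = s$mode, grid = s$grid,
                  mean_displacement_vox = s$mean_disp,
                  max_displacement_vox = s$max_disp,
                  ncc_before = s$ncc_before, ncc_after = s$ncc_after,
                  jacobian_min = s$jac_range[1], jacobian_max = s$jac_range[2],
                  folding_forward_count = s$folding_forward$count,
                  folding_forward_percent = s$folding_forward$percent,
                  folding_inverse_count = s$folding_inverse$count,
                  folding_inverse_percent = s$folding_inverse$percent)
  p <- file.path(outdir, "metrics.json")
  jsonlite::write_json(metrics, p, auto_unbox = TRUE, digits = NA)
  files[[length(files) + 1L]] <- p
  # config copy with a provenance block (metrics.json stays deterministic
  # so identical runs produce identical metric files)
  p <- file.path(outdir, "config.yaml")
  yaml::write_yaml(c(unclass(result$config), list(provenance = list(
    package_version = as.character(utils::packageVersion("mdreg")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = result$config$seed))), p)
  files[[length(files) + 1L]] <- p
  manifest <- data.frame(file = basename(unlist(files)),
                         md5 = unname(tools::md5sum(unlist(files))),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       digits = NA)
  invisible(manifest)
}

#' Read a configuration from YAML
#'
#' A `provenance` block (written by [write_result()]) is ignored; any other
#' unknown field is an error.
#'
#' @param path YAML file with [mdreg_config()] fields.
#' @return an `mdreg_config` object.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals$provenance <- NULL
  known <- names(formals(mdreg_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0)
    stop(sprintf("unknown config fields: %s", paste(extra, collapse = ", ")),
         call. = FALSE)
  do.call(mdreg_config, vals)
}
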