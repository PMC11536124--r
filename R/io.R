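# File interchange: multi-page 16-bit TIFF stacks with a JSON sidecar for
# acquisition metadata, ASCII OBJ/PLY meshes, and CSV/JSON export of SPHARM
# coefficients and concavity spectra.

#' Write a frame stack as multi-page TIFF plus JSON sidecar
#'
#' Intensities are scaled to the full 16-bit range; the scale factor, frame
#' rate, pixel size and per-frame angles go into `<file>.json` so the stack
#' round-trips losslessly up to quantization.
#'
#' @param stack a [frame_stack()].
#' @param path output TIFF path.
#' @param extra named list merged into the sidecar (e.g. seed, shape spec).
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, extra = list()) {
  stopifnot(inherits(stack, "frame_stack"))
  mx <- max(stack$frames)
  scale <- if (mx > 0) 65535 / mx else 1
  d <- dim(stack$frames)
  pages <- lapply(seq_len(d[3]), function(k)
    round(stack$frames[, , k] * scale) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- c(list(fps = stack$fps, pixel_size_um = stack$pixel_size,
                 angles_deg = stack$angles, intensity_scale = scale,
                 axis = stack$axis), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a frame stack written by [write_stack_tiff()]
#'
#' @param path TIFF path; `<path>.json` sidecar is required unless `fps`
#'   and `pixel_size` are given.
#' @param fps,pixel_size,angles metadata overrides for foreign TIFFs.
#' @return a [frame_stack()].
#' @export
read_stack_tiff <- function(path, fps = NULL, pixel_size = NULL,
                            angles = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side, simplifyVector = TRUE)
  else list()
  fps <- fps %||% meta$fps
  pixel_size <- pixel_size %||% meta$pixel_size_um
  angles <- angles %||% meta$angles_deg
  if (is.null(fps) || is.null(pixel_size))
    .dt_stop("read_stack_tiff: no sidecar; supply fps and pixel_size")
  scale <- meta$intensity_scale %||% 1
  frames <- array(0, c(dim(pages[[1]])[1], dim(pages[[1]])[2], length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]] * 65535 / scale
  if (is.null(angles))
    angles <- (seq_along(pages) - 1) * 360 / length(pages)
  frame_stack(frames, fps = fps, pixel_size = pixel_size, angles = angles)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write and read triangle meshes as ASCII OBJ or PLY
#'
#' Format is chosen from the file extension (`.obj` / `.ply`).
#'
#' @param mesh a [surface_mesh()].
#' @param path file path.
#' @return `write_mesh`: `path` invisibly; `read_mesh`: a
#'   [surface_mesh()].
#' @name mesh-io
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  v <- mesh$vertices; f <- mesh$faces
  if (ext == "obj") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("v %.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else if (ext == "ply") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%.9g %.9g %.9g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else .dt_stop("write_mesh: unsupported extension '%s' (obj/ply)", ext)
  invisible(path)
}

#' @rdname mesh-io
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "obj") {
    ln <- readLines(path)
    vl <- ln[startsWith(ln, "v ")]
    fl <- ln[startsWith(ln, "f ")]
    v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                               function(z) as.numeric(z[1:3])))
    f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fl)), "\\s+"),
                               function(z) as.integer(sub("/.*", "", z[1:3]))))
    surface_mesh(v, f)
  } else if (ext == "ply") {
    ln <- readLines(path)
    he <- which(ln == "end_header")
    nv <- as.integer(sub("element vertex ", "", ln[grepl("^element vertex", ln)]))
    nf <- as.integer(sub("element face ", "", ln[grepl("^element face", ln)]))
    v <- do.call(rbind, lapply(strsplit(ln[(he + 1):(he + nv)], "\\s+"),
                               function(z) as.numeric(z[1:3])))
    f <- do.call(rbind, lapply(strsplit(ln[(he + nv + 1):(he + nv + nf)], "\\s+"),
                               function(z) as.integer(z[2:4]) + 1L))
    surface_mesh(v, f)
  } else .dt_stop("read_mesh: unsupported extension '%s' (obj/ply)", ext)
}

#' Export SPHARM coefficients as a tidy table
#'
#' @param model a [fit_spharm()] model.
#' @param path optional CSV path (columns coord, l, m, value); `NULL`
#'   returns the data.frame only.
#' @return the coefficient data.frame, invisibly if written.
#' @export
write_spharm_csv <- function(model, path = NULL) {
  stopifnot(inherits(model, "spharm_model"))
  lm <- do.call(rbind, lapply(0:model$lmax, function(l)
    cbind(l = l, m = -l:l)))
  df <- do.call(rbind, lapply(1:3, function(j)
    data.frame(coord = c("x", "y", "z")[j], l = lm[, 1], m = lm[, 2],
               value = model$coefficients[, j])))
  if (is.null(path)) return(df)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a reconstructed volume as multi-page TIFF (z pages)
#'
#' @param volume a `recon_volume` or `volume_phantom`.
#' @param path output TIFF path; voxel size goes into a JSON sidecar.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  vol <- volume$intensity
  vol <- pmax(vol, 0)
  mx <- max(vol)
  scale <- if (mx > 0) 65535 / mx else 1
  pages <- lapply(seq_len(dim(vol)[3]), function(k)
    round(vol[, , k] * scale) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  jsonlite::write_json(list(voxel_size_um = volume$voxel_size,
                            intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
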