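#' Read and write scalar maps as NIfTI-1
#'
#' Volumes are written with an RAS diagonal affine built from the voxel size
#' and origin.
#'
#' @param map a [scalar_map()] (or 3D/4D array with `geom`).
#' @param path output `.nii`/`.nii.gz` path.
#' @param geom grid geometry when `map` is a bare array.
#' @export
write_nifti_map <- function(map, path, geom = NULL) {
  if (inherits(map, "scalar_map")) {
    geom <- map$geom; data <- map$data
  } else data <- map
  stopifnot(!is.null(geom))
  img <- RNifti::asNifti(data, reference = NULL)
  RNifti::pixdim(img) <- geom$voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_map
#' @param semantics semantics tag for the returned map.
#' @export
read_nifti_map <- function(path, semantics = "value") {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  arr <- as.array(img)
  scalar_map(arr, grid_geometry(dim(arr)[1:3], vs), semantics)
}

#' FSL-style gradient tables
#'
#' `bvals`: one space-separated row of b-values; `bvecs`: three rows (x, y,
#' z components per volume).
#'
#' @param scheme a [gradient_scheme()].
#' @param prefix output path prefix (writes `<prefix>.bvals`,
#'   `<prefix>.bvecs`).
#' @export
write_scheme <- function(scheme, prefix) {
  writeLines(paste(scheme$bvals, collapse = " "), paste0(prefix, ".bvals"))
  writeLines(apply(t(scheme$bvecs), 1, paste, collapse = " "),
             paste0(prefix, ".bvecs"))
  invisible(prefix)
}

#' @rdname write_scheme
#' @param bvals_path,bvecs_path input paths.
#' @export
read_scheme <- function(bvals_path, bvecs_path) {
  bvals <- scan(bvals_path, quiet = TRUE)
  m <- do.call(rbind, lapply(readLines(bvecs_path), function(l)
    scan(text = l, quiet = TRUE)))
  gradient_scheme(bvals, t(m))
}

#' Write/read streamlines in TCK format (MRtrix dialect)
#'
#' Binary Float32 little-endian triplets, streamlines separated by NaN
#' triplets and the file terminated by an Inf triplet, preceded by a text
#' header ending in `END`. Coordinates are world mm.
#'
#' @param streamlines list of n x 3 point matrices.
#' @param path output `.tck` path.
#' @export
write_tck <- function(streamlines, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- c("mrtrix tracks", "datatype: Float32LE",
              sprintf("count: %d", length(streamlines)))
  # offset: header text + "file: . <offset>\nEND\n"
  base <- sum(nchar(header)) + length(header)          # + newlines
  guess <- base + 40
  file_line <- sprintf("file: . %d", guess)
  pad <- guess - (base + nchar(file_line) + nchar("END") + 2)
  if (pad < 0) stop("internal header sizing error")
  file_line <- paste0(file_line, strrep(" ", pad))
  writeChar(paste0(paste(c(header, file_line, "END"), collapse = "\n"), "\n"),
            con, eos = NULL)
  for (s in streamlines) {
    writeBin(as.vector(t(unclass(s))), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_tck
#' @export
read_tck <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  first_nul <- which(raw == as.raw(0))[1]
  txt_end <- if (is.na(first_nul)) min(4096, length(raw)) else first_nul - 1
  txt <- rawToChar(raw[seq_len(txt_end)])
  m <- regmatches(txt, regexpr("file: \\. ([0-9]+)", txt))
  offset <- as.integer(sub("file: \\. ", "", m))
  vals <- readBin(raw[(offset + 1):length(raw)], "numeric", size = 4,
                  n = (length(raw) - offset) / 4, endian = "little")
  pts <- matrix(vals, ncol = 3, byrow = TRUE)
  isnan <- rowSums(is.nan(pts)) == 3
  isinf <- rowSums(is.infinite(pts)) == 3
  stop_at <- which(isinf)[1]
  if (!is.na(stop_at)) pts <- pts[seq_len(stop_at - 1), , drop = FALSE]
  grp <- cumsum(c(TRUE, rowSums(is.nan(pts))[-nrow(pts)] == 3))
  keep <- rowSums(is.nan(pts)) < 3
  out <- split.data.frame(pts[keep, , drop = FALSE], grp[keep])
  lapply(unname(out), function(m) structure(as.matrix(m), class = "streamline",
                                            dimnames = NULL))
}

#' Write/read an average fiber as JSON lines
#'
#' One JSON object per node: signed node index, xyz coordinates,
#' contributor count, and per-node scalar means when present.
#'
#' @param fiber an `average_fiber`.
#' @param path output `.jsonl` path.
#' @export
write_average_fiber <- function(fiber, path) {
  lines <- vapply(seq_along(fiber$index), function(i) {
    obj <- list(n = fiber$index[i], xyz = fiber$nodes[i, ],
                count = fiber$count[i])
    if (!is.null(fiber$scalars)) obj$scalars <- as.list(fiber$scalars[i, , drop = FALSE])
    jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_average_fiber
#' @export
read_average_fiber <- function(path) {
  objs <- lapply(readLines(path), jsonlite::fromJSON)
  nodes <- do.call(rbind, lapply(objs, `[[`, "xyz"))
  scal <- if (!is.null(objs[[1]]$scalars))
    do.call(rbind, lapply(objs, function(o) as.data.frame(o$scalars)))
  new_average_fiber(nodes, vapply(objs, `[[`, 0, "n"),
                    vapply(objs, `[[`, 0, "count"), scal)
}
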