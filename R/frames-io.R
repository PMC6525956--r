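# Reading and writing binary frames and stimulus directories.

#' Write / read a binary frame as CSV of 0/1
#'
#' @param frame A `binary_frame`.
#' @param path File path.
#' @return `path` (writer) or the frame (reader).
#' @export
write_frame_csv <- function(frame, path) {
  validate_frame(frame)
  utils::write.table(frame, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_frame_csv
#' @export
read_frame_csv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  validate_frame(m)
  class(m) <- c("binary_frame", class(m))
  m
}

#' Write / read a binary frame as an ASCII portable graymap (PGM, P2)
#'
#' Pixels are written with maxval 1 (1 = bar/black, 0 = background/white).
#' Only the plain-text P2 variant is supported; it is the interchange format
#' for the camera-emulation fixtures.
#'
#' @param frame A `binary_frame`.
#' @param path File path.
#' @return `path` (writer) or the frame (reader).
#' @export
write_frame_pgm <- function(frame, path) {
  validate_frame(frame)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(frame), nrow(frame)), "1"), con)
  writeLines(apply(frame, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_frame_pgm
#' @export
read_frame_pgm <- function(path) {
  tok <- scan(path, what = character(), comment.char = "#", quiet = TRUE)
  if (tok[1] != "P2") stopf("only plain (P2) PGM files are supported")
  w <- as.integer(tok[2]); h <- as.integer(tok[3]); maxval <- as.numeric(tok[4])
  px <- as.numeric(tok[-(1:4)])
  if (length(px) != w * h) stopf("PGM pixel count does not match header")
  m <- matrix(as.integer(px / maxval >= 0.5), nrow = h, ncol = w, byrow = TRUE)
  validate_frame(m)
  class(m) <- c("binary_frame", class(m))
  m
}

#' Binarize a grayscale image matrix
#'
#' Converts a matrix of normalized intensities in \[0, 1\] (or 0..255) to a
#' 0/1 frame: a pixel is 1 if its normalized intensity is >= 0.5.
#'
#' @param img Numeric matrix of intensities.
#' @param max_intensity Intensity corresponding to full scale (default:
#'   guessed as 255 when any value exceeds 1, else 1).
#' @return An integer 0/1 matrix of the same shape.
#' @export
binarize_image <- function(img, max_intensity = NULL) {
  if (!is.matrix(img) || !is.numeric(img)) stopf("`img` must be a numeric matrix")
  if (is.null(max_intensity)) max_intensity <- if (max(img) > 1) 255 else 1
  out <- matrix(as.integer(img / max_intensity >= 0.5), nrow(img), ncol(img))
  class(out) <- c("binary_frame", class(out))
  out
}

#' Write a direction sequence to a directory of frames plus a JSON manifest
#'
#' Frames are written as `frame_0001.csv`, ... and the step metadata
#' (directions, release-probability pairs, bar positions, step duration) to
#' `manifest.json`. Re-running with the same sequence produces byte-identical
#' output.
#'
#' @param seq A `direction_sequence`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_direction_sequence <- function(seq, dir) {
  stopifnot(inherits(seq, "direction_sequence"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(seq$frames)
  files <- sprintf("frame_%04d.csv", seq_len(n))
  for (i in seq_len(n)) {
    write_frame_csv(seq$frames[[i]], file.path(dir, files[i]))
  }
  manifest <- list(
    n_steps = n,
    step_duration = seq$step_duration,
    directions = seq$directions,
    u_pairs = unname(seq$u_pairs),
    positions = seq$positions,
    frame_files = files
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a direction sequence from a fixtures directory
#'
#' @param dir Directory written by [write_direction_sequence()].
#' @return A `direction_sequence`.
#' @export
read_direction_sequence <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) stopf("no manifest.json in %s", dir)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  frames <- lapply(file.path(dir, man$frame_files), read_frame_csv)
  structure(
    list(frames = frames, directions = man$directions,
         u_pairs = matrix(man$u_pairs, ncol = 2,
                          dimnames = list(NULL, c("U1", "U2"))),
         positions = man$positions, step_duration = man$step_duration),
    class = "direction_sequence")
}
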