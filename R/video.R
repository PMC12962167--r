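#' Construct a frame sequence
#'
#' @param frames Numeric array of dimension `T x H x W x 3` with values in
#'   `[0, 1]` (values in `[0, 255]` are rescaled by 1/255).
#' @param fps Frames per second (> 0).
#'
#' @return An array of class `frame_seq` with attribute `fps`.
#' @export
frame_seq <- function(frames, fps) {
  d <- dim(frames)
  if (length(d) != 4 || d[4] != 3) stop_invalid("frames must be a T x H x W x 3 array")
  if (fps <= 0) stop_invalid("`fps` must be positive")
  if (max(frames) > 1) frames <- frames / 255
  if (min(frames) < 0 || max(frames) > 1) stop_invalid("frame values must lie in [0, 1]")
  structure(frames, fps = fps, class = "frame_seq")
}

#' @rdname frame_seq
#' @param x A `frame_seq`.
#' @export
frame_fps <- function(x) attr(x, "fps")

restore_frames <- function(frames, template) {
  structure(frames, fps = attr(template, "fps"), class = "frame_seq")
}

#' Crop all frames to a face region of interest
#'
#' The face box is computed once on the first frame (or supplied explicitly)
#' and held fixed across the whole sequence. Synthetic recordings bypass
#' detection by passing their known ROI box.
#'
#' @param frames A [frame_seq()].
#' @param box Optional integer box `c(x, y, w, h)` in 0-based pixel
#'   coordinates (`x` = column offset, `y` = row offset).
#' @param detector Optional function taking one `H x W x 3` frame and
#'   returning a box `c(x, y, w, h)` or `NULL` when no face is found. Any
#'   external face detector can be plugged in through this interface.
#'
#' @return A cropped `frame_seq` of size `T x h x w x 3`.
#' @export
crop_face_roi <- function(frames, box = NULL, detector = NULL) {
  d <- dim(frames)
  if (is.null(box)) {
    if (is.null(detector)) stop_invalid("supply either `box` or a `detector`")
    box <- detector(frames[1, , , , drop = TRUE])
    if (is.null(box)) {
      abort("no face found in frame 1 and no explicit box supplied",
            class = "hbpnet_no_face")
    }
  }
  box <- as.integer(round(box))
  x <- box[1]; y <- box[2]; w <- box[3]; h <- box[4]
  if (w < 1 || h < 1 || x < 0 || y < 0 || y + h > d[2] || x + w > d[3]) {
    stop_invalid("box (%d,%d,%d,%d) exceeds the %d x %d frame", x, y, w, h, d[2], d[3])
  }
  restore_frames(frames[, (y + 1):(y + h), (x + 1):(x + w), , drop = FALSE], frames)
}

#' Resize frames and normalise pixel values to [0, 1]
#'
#' Bilinear (pixel-centre aligned) spatial resizing to `height x width`.
#' Inputs on a 0--255 scale are rescaled by 1/255 on construction of the
#' frame sequence, so values here are already in `[0, 1]`; the output is
#' clamped to that range.
#'
#' @param frames A [frame_seq()].
#' @param height,width Target spatial size in pixels (>= 8).
#'
#' @return A `frame_seq` of size `T x height x width x 3`.
#' @export
resize_normalize <- function(frames, height, width) {
  if (height < 8 || width < 8) stop_invalid("target size must be at least 8 x 8")
  d <- dim(frames)
  if (d[2] == height && d[3] == width) return(frames)
  out <- cpp_resize_bilinear(as.numeric(frames), dim(frames), as.integer(height), as.integer(width))
  restore_frames(clamp01(out), frames)
}

#' Segment a frame sequence into fixed-length clips
#'
#' Training mode uses 50% overlap (stride `floor(T/2)`); test mode uses
#' non-overlapping clips (stride `T`). Trailing frames that do not fill a
#' whole clip are dropped.
#'
#' @param frames A [frame_seq()].
#' @param clip_len Clip length `T` in frames.
#' @param mode `"train"` (50% overlap) or `"test"` (no overlap).
#' @param labels Optional full-length [hbp_map()] (or numeric vector) for the
#'   recording; it is sliced per clip.
#'
#' @return A `clip_set`: list with `clips` (list of `3 x T x H x W` arrays),
#'   `start_frames` (0-based), optional `labels`, and `fps`.
#' @export
segment_clips <- function(frames, clip_len, mode = c("train", "test"), labels = NULL) {
  mode <- match.arg(mode)
  d <- dim(frames)
  n <- d[1]
  if (n < clip_len) {
    stop_invalid("recording of %d frames is shorter than one clip (T = %d)", n, clip_len)
  }
  stride <- if (mode == "train") max(1L, clip_len %/% 2L) else clip_len
  starts <- seq(0L, n - clip_len, by = stride)
  lab_values <- if (!is.null(labels)) hbp_values(labels) else NULL
  if (!is.null(lab_values) && length(lab_values) < n) {
    stop_invalid("labels (%d) shorter than the recording (%d frames)", length(lab_values), n)
  }
  clips <- lapply(starts, function(s) {
    aperm(unclass(frames)[(s + 1):(s + clip_len), , , , drop = FALSE], c(4, 1, 2, 3))
  })
  lab <- if (!is.null(lab_values)) {
    lapply(starts, function(s) lab_values[(s + 1):(s + clip_len)])
  }
  structure(
    list(clips = clips, start_frames = as.integer(starts), labels = lab,
         fps = attr(frames, "fps"), mode = mode),
    class = "clip_set"
  )
}

#' @export
length.clip_set <- function(x) length(x$clips)

#' Manifest of a clip set
#'
#' @param x A `clip_set`.
#' @param ... Unused.
#' @return A tibble with one row per clip.
#' @export
tidy.clip_set <- function(x, ...) {
  tibble(
    clip = seq_along(x$clips) - 1L,
    start_frame = x$start_frames,
    n_frames = vapply(x$clips, function(cl) dim(cl)[2], integer(1)),
    has_label = !is.null(x$labels)
  )
}

#' Overlay temporal attention differences onto frames
#'
#' Renders where the model's spatiotemporal attention changes between
#' consecutive frames: `Image_t = (Map_{t+1} - Map_t) * mu + Frame_t`,
#' clamped to `[0, 1]`. The first and last frames have no forward difference
#' and are passed through unchanged, so the output length equals the input
#' length. Single-channel maps are broadcast across RGB.
#'
#' @param maps Attention maps, `T x H x W` or `T x H x W x 3`, matching the
#'   frames spatially and temporally.
#' @param frames A [frame_seq()].
#' @param mu Visualisation intensity (default 1).
#'
#' @return A `frame_seq` of overlays.
#' @export
attention_overlay <- function(maps, frames, mu = 1) {
  d <- dim(frames)
  md <- dim(maps)
  if (length(md) == 3) {
    maps <- array(rep(as.numeric(maps), 3), dim = c(md, 3))
    md <- dim(maps)
  }
  if (!all(md == d)) {
    stop_invalid("maps (%s) do not match frames (%s)",
                 paste(md, collapse = "x"), paste(d, collapse = "x"))
  }
  out <- unclass(frames)
  n <- d[1]
  if (n > 2) {
    t_in <- 2:(n - 1)
    diffs <- maps[t_in + 1, , , , drop = FALSE] - maps[t_in, , , , drop = FALSE]
    out[t_in, , , ] <- clamp01(diffs * mu + out[t_in, , , , drop = FALSE])
  }
  restore_frames(out, frames)
}

#' Read / write frame sequences as PNG directories
#'
#' Frames are stored as individually numbered PNG files; lexicographic file
#' order defines frame order.
#'
#' @param path Directory of `.png` files (created when writing).
#' @param fps Frames per second to attach on read.
#' @return `read_frames_png()` returns a [frame_seq()]; `write_frames_png()`
#'   returns `path` invisibly.
#' @export
read_frames_png <- function(path, fps) {
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (!length(files)) stop_invalid("no PNG frames found under %s", path)
  imgs <- lapply(files, png::readPNG)
  d <- dim(imgs[[1]])
  arr <- array(0, dim = c(length(imgs), d[1], d[2], 3))
  for (i in seq_along(imgs)) {
    im <- imgs[[i]]
    if (length(dim(im)) == 2) im <- array(rep(im, 3), dim = c(dim(im), 3))
    arr[i, , , ] <- im[, , 1:3]
  }
  frame_seq(arr, fps)
}

#' @rdname read_frames_png
#' @param frames A [frame_seq()] to write.
#' @export
write_frames_png <- function(frames, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  n <- dim(frames)[1]
  fmt <- paste0("frame_%0", max(4, nchar(n)), "d.png")
  for (t in seq_len(n)) {
    png::writePNG(unclass(frames)[t, , , ], file.path(path, sprintf(fmt, t - 1)))
  }
  invisible(path)
}
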