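#' RGB image container
#'
#' An `rgb_image` wraps an `H x W x 3` numeric array with channel values in
#' `[0, 1]`. Stored 8-bit files are normalised by 255 on read. All analysis
#' functions in the package take either an `rgb_image` or a single-channel
#' `channel_image`.
#'
#' @param pixels numeric `H x W x 3` array with values in `[0, 1]`.
#' @return An object of class `rgb_image` with fields `pixels`, `height`
#'   and `width`.
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (dim(pixels)[1] < 2L || dim(pixels)[2] < 2L)
    stop("image must be at least 2 x 2")
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("image contains non-finite values")
  if (min(pixels) < -1e-9 || max(pixels) > 1 + 1e-9)
    stop("channel values must lie in [0, 1]")
  pixels[pixels < 0] <- 0
  pixels[pixels > 1] <- 1
  structure(
    list(pixels = pixels, height = dim(pixels)[1], width = dim(pixels)[2]),
    class = "rgb_image"
  )
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d>\n", x$height, x$width))
  invisible(x)
}

#' Single-channel image
#'
#' @param pixels numeric `H x W` matrix of finite values.
#' @param space_tag one of `"gray"`, `"L"`, `"a"`, `"b"`, `"RG"`, `"GR"`,
#'   `"BY"` identifying the colour channel the plane came from.
#' @return An object of class `channel_image`.
#' @export
channel_image <- function(pixels, space_tag = "gray") {
  if (!is.matrix(pixels)) pixels <- as.matrix(pixels)
  if (anyNA(pixels) || any(!is.finite(pixels)))
    stop("channel contains non-finite values")
  space_tag <- match.arg(space_tag, c("gray", "L", "a", "b", "RG", "GR", "BY"))
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         space_tag = space_tag),
    class = "channel_image"
  )
}

#' @export
print.channel_image <- function(x, ...) {
  cat(sprintf("<channel_image [%s] %d x %d>\n", x$space_tag, x$height, x$width))
  invisible(x)
}

as_pixel_matrix <- function(img) {
  if (inherits(img, "channel_image")) return(img$pixels)
  if (is.matrix(img)) return(img)
  stop("expected a channel_image or a matrix")
}

#' Read an image file
#'
#' Reads PNG (via the \pkg{png} package) or portable anymap (ASCII or binary
#' PGM/PPM) files into an [rgb_image]. Greyscale inputs are replicated onto
#' three channels. 8-bit and 16-bit samples are normalised to `[0, 1]`.
#'
#' @param path file path; format chosen by extension
#'   (`.png`, `.ppm`, `.pgm`, `.pnm`).
#' @return An [rgb_image].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    if (dim(a)[3] == 4L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
    if (dim(a)[3] == 2L) a <- array(rep(a[, , 1], 3L), c(dim(a)[1:2], 3L))
    return(rgb_image(a[, , 1:3, drop = FALSE]))
  }
  if (ext %in% c("ppm", "pgm", "pnm")) return(read_pnm(path))
  stop("unsupported image format: .", ext,
       " (supported: png, ppm, pgm, pnm)")
}

#' Write an image file
#'
#' @param img an [rgb_image] or [channel_image].
#' @param path output path ending in `.png`, `.ppm` or `.pgm`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  if (inherits(img, "channel_image")) {
    p <- img$pixels
    p <- pmin(pmax(p, 0), 1)
    img <- rgb_image(array(rep(p, 3L), c(dim(p), 3L)))
  }
  if (ext == "png") {
    png::writePNG(img$pixels, path)
  } else if (ext %in% c("ppm", "pgm", "pnm")) {
    write_pnm(img, path, gray = (ext == "pgm"))
  } else {
    stop("unsupported image format: .", ext)
  }
  invisible(path)
}

# Minimal PNM (P2/P3/P5/P6) reader: plain-text fixtures use P2/P3.
read_pnm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("not a supported PNM file: ", path)
  read_token <- function() {
    tok <- ""
    repeat {
      ch <- rawToChar(readBin(con, "raw", 1L))
      if (length(ch) == 0L || ch == "") stop("truncated PNM header")
      if (ch == "#") {                      # comment to end of line
        repeat {
          ch <- rawToChar(readBin(con, "raw", 1L))
          if (ch %in% c("\n", "")) break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) break else next
      }
      tok <- paste0(tok, ch)
    }
    tok
  }
  w <- as.integer(read_token()); h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  if (magic %in% c("P2", "P3")) {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  } else {
    if (maxval > 255L) stop("16-bit binary PNM not supported")
    vals <- as.integer(readBin(con, "raw", n))
  }
  if (length(vals) != n) stop("truncated PNM data")
  x <- vals / maxval
  if (nch == 1L) {
    m <- matrix(x, nrow = h, byrow = TRUE)
    a <- array(rep(m, 3L), c(h, w, 3L))
  } else {
    a <- array(0, c(h, w, 3L))
    for (k in 1:3)
      a[, , k] <- matrix(x[seq(k, n, by = 3L)], nrow = h, byrow = TRUE)
  }
  rgb_image(a)
}

write_pnm <- function(img, path, gray = FALSE) {
  px <- round(img$pixels * 255)
  h <- img$height; w <- img$width
  con <- file(path, "wb")
  on.exit(close(con))
  if (gray) {
    g <- round((px[, , 1] + px[, , 2] + px[, , 3]) / 3)
    writeLines(c("P2", paste(w, h), "255"), con)
    writeLines(apply(g, 1L, paste, collapse = " "), con)
  } else {
    writeLines(c("P3", paste(w, h), "255"), con)
    rows <- vapply(seq_len(h), function(r) {
      paste(as.vector(rbind(px[r, , 1], px[r, , 2], px[r, , 3])),
            collapse = " ")
    }, character(1))
    writeLines(rows, con)
  }
  invisible(path)
}
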