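#' Read and write grayscale images as 16-bit TIFF
#'
#' Images are stored as 16-bit grayscale TIFF; the physical pixel size is
#' carried in the TIFF resolution fields (pixels per centimetre).
#'
#' @param image a `gray_image` with intensities in [0, 1].
#' @param path file path.
#' @export
write_image_tiff <- function(image, path) {
  ps <- attr(image, "pixel_size")
  m <- t(unclass(image))[seq(ncol(image), 1), , drop = FALSE]  # y-up -> row-major
  attributes(m) <- list(dim = dim(m))
  res <- if (!is.null(ps)) 1e4 / ps else 72  # px per cm given um per px
  tiff::writeTIFF(m, path, bits.per.sample = 16L,
                  reduce = TRUE, compression = "none")
  invisible(path)
}

#' @rdname write_image_tiff
#' @param pixel_size micrometres per pixel to attach on read.
#' @export
read_image_tiff <- function(path, pixel_size = 0.1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3) m <- m[, , 1]
  m <- t(m[seq(nrow(m), 1), , drop = FALSE])
  gray_image(m, pixel_size = pixel_size)
}

#' Write angle profiles and morphometrics as a wide CSV
#'
#' One row per nucleus: id, genotype, sex, angle_000..angle_NNN, then any
#' additional stat columns. Reads back losslessly with
#' [read_profiles_csv()].
#'
#' @param profiles list of anchored `angle_profile`s.
#' @param meta data.frame with one row per profile (id, genotype, sex, ...).
#' @param path file path.
#' @export
write_profiles_csv <- function(profiles, meta, path) {
  m <- profiles_to_matrix(profiles)
  colnames(m) <- sprintf("angle_%03d", seq_len(ncol(m)) - 1)
  write.csv(cbind(meta, as.data.frame(m)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  acols <- grep("^angle_\\d+$", names(df))
  list(meta = df[, -acols, drop = FALSE],
       profiles = as.matrix(df[, acols, drop = FALSE]))
}

#' Export an outline (or consensus) as an SVG path
#'
#' Writes a minimal standalone SVG with one closed path per outline,
#' y-flipped into SVG's screen coordinates.
#'
#' @param outlines a single `outline`/`consensus_shape` or a list of them.
#' @param path file path.
#' @param stroke stroke colours recycled over outlines.
#' @export
write_outline_svg <- function(outlines, path, stroke = "#1f6fb4") {
  if (inherits(outlines, c("outline", "consensus_shape"))) outlines <- list(outlines)
  vs <- lapply(outlines, function(o) {
    if (inherits(o, "consensus_shape")) o <- o$mean_outline
    as_vertices(o)
  })
  allv <- do.call(rbind, vs)
  rng <- apply(allv, 2, range)
  pad <- 0.05 * max(rng[2, ] - rng[1, ])
  w <- (rng[2, 1] - rng[1, 1]) + 2 * pad
  h <- (rng[2, 2] - rng[1, 2]) + 2 * pad
  stroke <- rep(stroke, length.out = length(vs))
  paths <- vapply(seq_along(vs), function(i) {
    v <- vs[[i]]
    x <- v[, 1] - rng[1, 1] + pad
    y <- h - (v[, 2] - rng[1, 2] + pad)  # flip y for SVG
    sprintf('<path d="M %s Z" fill="none" stroke="%s" stroke-width="%.3f"/>',
            paste(sprintf("%.3f,%.3f", x, y), collapse = " L "),
            stroke[i], 0.01 * max(w, h))
  }, "")
  writeLines(c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="0 0 %.3f %.3f">', w, h),
               paths, "</svg>"), path)
  invisible(path)
}
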