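#' Write an image stack as a multi-page grayscale TIFF
#'
#' @param stack 3-d array `(rows, cols, frames)` with values in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_hs("the 'tiff' package is required for TIFF output")
  stopifnot(is.array(stack), length(dim(stack)) == 3L)
  frames <- lapply(seq_len(dim(stack)[3]), function(i) stack[, , i])
  tiff::writeTIFF(frames, path)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as an image stack
#'
#' @param path TIFF file path.
#' @return 3-d array `(rows, cols, frames)`.
#' @export
read_stack_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop_hs("the 'tiff' package is required for TIFF input")
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  shp <- unique(lapply(frames, dim))
  if (length(shp) != 1L) stop_hs("ragged TIFF: pages differ in shape")
  array(unlist(frames), dim = c(shp[[1]], length(frames)))
}
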