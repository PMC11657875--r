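# Plain-text image-stack format.
#
# No TIFF reader is available in this R environment, so stacks are carried
# in a simple whitespace-delimited text format instead: a header line
#   spinemorph-stack <planes> <rows> <cols> <pixel_nm> <pitch_nm>
# followed by one line per image row, planes concatenated in order.
# In memory a stack is a numeric array [row, col, plane] with attributes
# pixel_nm (lateral pitch) and pitch_nm (axial plane pitch).

#' Assemble an image stack array
#'
#' @param data numeric array `[row, col, plane]` (a matrix is promoted to a
#'   single-plane stack).
#' @param pixel_nm lateral pixel pitch, nm.
#' @param pitch_nm axial plane pitch, nm.
#' @return numeric array of class `spine_stack`.
#' @export
spine_stack <- function(data, pixel_nm = 20, pitch_nm = 300) {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1))
  stopifnot(is.array(data), length(dim(data)) == 3)
  attr(data, "pixel_nm") <- pixel_nm
  attr(data, "pitch_nm") <- pitch_nm
  class(data) <- c("spine_stack", class(data))
  data
}

#' Write a stack to the text format
#' @param stack a [spine_stack()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack_txt <- function(stack, path) {
  d <- dim(stack)
  con <- file(path, "w")
  on.exit(close(con))
  cat("spinemorph-stack", d[3], d[1], d[2],
      attr(stack, "pixel_nm"), attr(stack, "pitch_nm"), "\n", file = con)
  for (p in seq_len(d[3])) {
    utils::write.table(format(stack[, , p], digits = 17, trim = TRUE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Read a stack from the text format
#' @param path file written by [write_stack_txt()].
#' @return a [spine_stack()].
#' @export
read_stack_txt <- function(path) {
  hdr <- strsplit(trimws(readLines(path, n = 1)), "\\s+")[[1]]
  if (hdr[1] != "spinemorph-stack") stop(path, " is not a spinemorph stack")
  dims <- as.integer(hdr[2:4])
  vals <- scan(path, skip = 1, quiet = TRUE)
  arr <- array(0, c(dims[2], dims[3], dims[1]))
  per_plane <- dims[2] * dims[3]
  for (p in seq_len(dims[1])) {
    block <- vals[((p - 1) * per_plane + 1):(p * per_plane)]
    arr[, , p] <- matrix(block, nrow = dims[2], byrow = TRUE)
  }
  spine_stack(arr, pixel_nm = as.numeric(hdr[5]), pitch_nm = as.numeric(hdr[6]))
}
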