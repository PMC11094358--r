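#' Write a numeric matrix as an NPY file
#'
#' Minimal NPY (version 1.0) writer: little-endian float64, C order.  Used
#' for exporting density maps to numpy-compatible tooling.
#'
#' @param m numeric matrix.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_npy <- function(m, path) {
  stopifnot(is.matrix(m))
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(m), ncol(m))
  ## total header (magic 6 + version 2 + len 2 + dict) padded to 64 bytes
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1, 0))), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.numeric(t(m)), con, size = 8, endian = "little")
  invisible(path)
}

#' Read an NPY file written by [write_npy()]
#' @param path NPY file path.
#' @return numeric matrix.
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(magic[1:6], c(as.raw(0x93), charToRaw("NUMPY"))))
    stop("not an NPY file")
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  if (!grepl("'<f8'", header)) stop("only little-endian float64 NPY is supported")
  sh <- regmatches(header, regexpr("\\(([0-9]+), ([0-9]+)\\)", header))
  dims <- as.integer(strsplit(gsub("[()]", "", sh), ", ")[[1]])
  vals <- readBin(con, "numeric", prod(dims), size = 8, endian = "little")
  matrix(vals, dims[1], dims[2], byrow = TRUE)
}
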