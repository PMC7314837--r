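# Minimal MAT-file (level 5) reader/writer for numeric arrays, enough for
# interchange with the MATLAB-format deposits of this kind of dataset
# (cell_displacements.mat, tract_results.mat, stress_results.mat). Writes
# uncompressed double arrays; reads uncompressed elements and attempts
# zlib-decompression of compressed ones. Not a general MAT parser: cell
# arrays, structs and sparse matrices are skipped with a warning.

MI_INT8 <- 1L; MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_DOUBLE <- 9L
MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MX_DOUBLE_CLASS <- 6L

#' Write numeric arrays to a MAT v5 file
#'
#' @param path Output path.
#' @param vars Named list of numeric vectors/matrices/3D arrays; stored as
#'   double-precision MATLAB arrays.
#' @export
write_mat <- function(path, vars) {
  if (is.null(names(vars)) || any(names(vars) == ""))
    stop("all variables must be named")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("MATLAB 5.0 MAT-file, written by islandmech on %s",
                           format(Sys.time(), "%Y-%m-%d")))
  hdr <- c(hdr, raw(116 - length(hdr)))
  writeBin(hdr, con)
  writeBin(raw(8), con)                      # subsystem offset
  writeBin(as.raw(c(0x00, 0x01)), con)  # version 0x0100, little-endian
  writeBin(charToRaw("IM"), con)
  for (nm in names(vars)) writeBin(mat_element(nm, vars[[nm]]), con)
  invisible(path)
}

mat_element <- function(name, x) {
  dims <- dim(x) %||% c(length(x), 1L)
  pad8 <- function(r) c(r, raw((8 - length(r) %% 8) %% 8))
  sub <- function(type, payload) {
    c(writeBin(c(type, length(payload)), raw(), size = 4, endian = "little"),
      pad8(payload))
  }
  flags <- writeBin(c(MX_DOUBLE_CLASS, 0L), raw(), size = 4, endian = "little")
  body <- c(sub(MI_UINT32, flags),
            sub(MI_INT32, writeBin(as.integer(dims), raw(), size = 4,
                                   endian = "little")),
            sub(MI_INT8, charToRaw(name)),
            sub(MI_DOUBLE, writeBin(as.double(x), raw(), size = 8,
                                    endian = "little")))
  c(writeBin(c(MI_MATRIX, length(body)), raw(), size = 4, endian = "little"),
    body)
}

#' Read numeric arrays from a MAT v5 file
#'
#' @param path Input path.
#' @return Named list of numeric arrays (doubles); non-numeric elements are
#'   skipped with a warning.
#' @export
read_mat <- function(path) {
  raw_all <- readBin(path, raw(), n = file.info(path)$size)
  if (length(raw_all) < 128) stop("not a MAT v5 file (too short)")
  endian_tag <- rawToChar(raw_all[127:128])
  endian <- if (endian_tag == "IM") "little" else "big"
  out <- list()
  pos <- 129L
  while (pos + 8L <= length(raw_all) + 1L) {
    tag <- readBin(raw_all[pos:(pos + 7)], integer(), n = 2, size = 4,
                   endian = endian)
    type <- tag[1]; nb <- tag[2]
    if (nb < 0 || pos + 8 + nb - 1 > length(raw_all)) break
    payload <- if (nb > 0) raw_all[(pos + 8):(pos + 7 + nb)] else raw(0)
    if (type == MI_COMPRESSED) {
      dec <- tryCatch(memDecompress(payload, type = "gzip"),
                      error = function(e) NULL)
      if (is.null(dec))
        dec <- tryCatch(memDecompress(payload, type = "unknown"),
                        error = function(e) NULL)
      if (is.null(dec)) {
        warning("skipping compressed MAT element (cannot decompress)")
      } else {
        el <- parse_matrix(dec, endian)
        if (!is.null(el)) out[[el$name]] <- el$value
      }
    } else if (type == MI_MATRIX) {
      el <- parse_matrix(payload, endian)
      if (!is.null(el)) out[[el$name]] <- el$value
    }
    pos <- pos + 8L + nb + (8 - nb %% 8) %% 8
  }
  out
}

parse_matrix <- function(buf, endian) {
  pos <- 1L
  # a decompressed buffer starts with its own miMATRIX tag
  first <- readBin(buf[1:8], integer(), n = 2, size = 4, endian = endian)
  if (first[1] == MI_MATRIX) pos <- 9L
  nxt <- function() {
    tag <- readBin(buf[pos:(pos + 7)], integer(), n = 2, size = 4,
                   endian = endian)
    type <- tag[1]; nb <- tag[2]
    small <- FALSE
    if (bitwAnd(type, -65536L) != 0L) {  # small data element format
      nb <- bitwShiftR(bitwAnd(type, -65536L), 16)
      type <- bitwAnd(type, 65535L)
      payload <- buf[(pos + 4):(pos + 3 + nb)]
      pos <<- pos + 8L
      small <- TRUE
    } else {
      payload <- if (nb > 0) buf[(pos + 8):(pos + 7 + nb)] else raw(0)
      pos <<- pos + 8L + nb + (8 - nb %% 8) %% 8
    }
    list(type = type, payload = payload)
  }
  flags <- nxt()
  cls <- as.integer(flags$payload[1])
  dims_el <- nxt()
  dims <- readBin(dims_el$payload, integer(), n = length(dims_el$payload) / 4,
                  size = 4, endian = endian)
  name_el <- nxt()
  name <- rawToChar(name_el$payload)
  if (cls != MX_DOUBLE_CLASS && !(cls %in% c(7L, 8L, 9L, 10L, 11L, 12L, 13L))) {
    warning(sprintf("skipping non-numeric MAT variable '%s' (class %d)",
                    name, cls))
    return(NULL)
  }
  data_el <- nxt()
  vals <- switch(as.character(data_el$type),
    "9" = readBin(data_el$payload, double(), n = length(data_el$payload) / 8,
                  size = 8, endian = endian),
    "7" = readBin(data_el$payload, double(), n = length(data_el$payload) / 4,
                  size = 4, endian = endian),
    "5" = , "6" = as.double(
      readBin(data_el$payload, integer(), n = length(data_el$payload) / 4,
              size = 4, endian = endian)),
    "3" = , "4" = as.double(
      readBin(data_el$payload, integer(), n = length(data_el$payload) / 2,
              size = 2, endian = endian)),
    "1" = , "2" = as.double(as.integer(data_el$payload)),
    {
      warning(sprintf("skipping MAT variable '%s' (data type %d)",
                      name, data_el$type))
      return(NULL)
    })
  list(name = name, value = array(vals, dim = dims))
}
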