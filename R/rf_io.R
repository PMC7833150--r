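## Binary persistence of response-function lattices: IEEE-754 64-bit
## little-endian values in an unformatted stream, n slowest / m middle /
## l fastest, preceded by a fixed-size header.

.RF_MAGIC <- charToRaw("SHRF")
.RF_VERSION <- 1L
.QUANTITY_CODE <- c(hstar10 = 1L, kerma = 2L)

#' Save a response function to a binary stream file
#'
#' Values are written as 8-byte IEEE-754 little-endian floats in C row-major
#' order (layer index slowest, then m, then l), after a fixed header (magic,
#' version, nuclide, quantity, resolution, half extents, altitude nodes).
#' Round trips are bit-exact.
#'
#' @param rf A \code{dose_response_function}.
#' @param path Output file path.
#' @export
save_rf <- function(rf, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(.RF_MAGIC, con)
  writeBin(.RF_VERSION, con, size = 4L, endian = "little")
  nuc <- charToRaw(rf$nuclide)
  stopifnot(length(nuc) <= 16L)
  writeBin(c(nuc, raw(16L - length(nuc))), con)
  writeBin(.QUANTITY_CODE[[rf$quantity]], con, size = 4L, endian = "little")
  writeBin(as.numeric(rf$resolution), con, size = 8L, endian = "little")
  writeBin(as.integer(c(rf$half_l, rf$half_m)), con, size = 4L, endian = "little")
  writeBin(as.integer(!is.null(rf$ground)), con, size = 4L, endian = "little")
  writeBin(length(rf$altitudes), con, size = 4L, endian = "little")
  if (length(rf$altitudes))
    writeBin(as.numeric(rf$altitudes), con, size = 8L, endian = "little")
  if (!is.null(rf$ground))
    writeBin(as.vector(rf$ground), con, size = 8L, endian = "little")
  if (!is.null(rf$cloud))
    writeBin(as.vector(rf$cloud), con, size = 8L, endian = "little")
  invisible(path)
}

.read_chk <- function(con, what, n, size) {
  out <- readBin(con, what, n = n, size = size, endian = "little")
  if (length(out) != n)
    .stop_cls("shinemap_format_error", "truncated response-function stream")
  out
}

#' Load a response function saved by \code{\link{save_rf}}
#'
#' @param path File path.
#' @return A \code{dose_response_function}; bad magic, unknown version or
#'   quantity code, or a truncated stream raise a format error.
#' @export
load_rf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (length(magic) != 4L || !identical(magic, .RF_MAGIC))
    .stop_cls("shinemap_format_error", "bad magic in response-function file")
  version <- .read_chk(con, integer(), 1L, 4L)
  if (version != .RF_VERSION)
    .stop_cls("shinemap_format_error", "unsupported version: ", version)
  nuc_raw <- readBin(con, "raw", n = 16L)
  nuclide <- rawToChar(nuc_raw[nuc_raw != as.raw(0)])
  qcode <- .read_chk(con, integer(), 1L, 4L)
  qi <- match(qcode, .QUANTITY_CODE)
  if (is.na(qi))
    .stop_cls("shinemap_format_error", "unknown quantity code: ", qcode)
  quantity <- names(.QUANTITY_CODE)[qi]
  resolution <- .read_chk(con, numeric(), 1L, 8L)
  hl <- .read_chk(con, integer(), 2L, 4L)
  has_ground <- .read_chk(con, integer(), 1L, 4L)
  n_alt <- .read_chk(con, integer(), 1L, 4L)
  altitudes <- if (n_alt > 0L) .read_chk(con, numeric(), n_alt, 8L) else numeric(0)
  nl <- 2L * hl[1L] + 1L
  nm <- 2L * hl[2L] + 1L
  ground <- NULL
  if (has_ground == 1L)
    ground <- matrix(.read_chk(con, numeric(), nl * nm, 8L), nl, nm)
  cloud <- NULL
  if (n_alt > 0L)
    cloud <- array(.read_chk(con, numeric(), nl * nm * n_alt, 8L),
                   c(nl, nm, n_alt))
  .rf_new(nuclide, quantity, resolution, hl[1L], hl[2L],
          ground = ground, cloud = cloud, altitudes = altitudes)
}

#' Write a YAML manifest of response-function archives in a directory
#'
#' @param dir Directory containing \code{.rf} files written by
#'   \code{\link{save_rf}}.
#' @param path Manifest path (default \code{manifest.yaml} inside
#'   \code{dir}).
#' @export
save_rf_manifest <- function(dir, path = file.path(dir, "manifest.yaml")) {
  files <- list.files(dir, pattern = "\\.rf$", full.names = TRUE)
  entries <- lapply(files, function(f) {
    rf <- load_rf(f)
    list(file = basename(f), nuclide = rf$nuclide, quantity = rf$quantity,
         resolution_m = rf$resolution,
         half_extent = rf$half_l,
         has_ground = !is.null(rf$ground),
         altitudes_m = as.numeric(rf$altitudes),
         md5 = unname(md5sum(f)))
  })
  write_yaml(list(version = 1L, archives = entries), path)
  invisible(path)
}
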