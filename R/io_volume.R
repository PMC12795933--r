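# NRRD volume I/O: 3D scalar volumes with axis-aligned space directions.
# Raw little-endian and ascii encodings (ascii keeps fixtures text-only).

#' Read and write NRRD volumes
#'
#' Supports detached-free NRRD with `dimension: 3`, scalar types
#' (`double`, `float`, `short`, `uchar`, `int`), `raw` or `ascii`
#' encodings, and axis-aligned `space directions` (or `spacings`).
#' The voxel-to-world affine is reconstructed from the space directions
#' and origin; anisotropic spacings round trip exactly.
#'
#' @param path file path.
#' @return `read_volume`: a [volume()].
#' @export
read_volume <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, 1)
    if (length(ln) == 0) stop("truncated NRRD header")
    if (ln == "") break
    if (grepl("^#", ln)) next
    kv <- regmatches(ln, regexec("^([^:]+):=?\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) fields[[trimws(tolower(kv[2]))]] <- trimws(kv[3])
  }
  need <- function(k) {
    if (is.null(fields[[k]])) stop("NRRD header missing required field: ", k)
    fields[[k]]
  }
  if (as.integer(need("dimension")) != 3L)
    stop("only 3-dimensional NRRD volumes are supported")
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  type <- need("type")
  enc <- need("encoding")
  spacing <- if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    m <- t(vapply(vecs, function(v)
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3)))
    if (max(abs(m - diag(diag(m), 3, 3))) > 1e-9)
      stop("only axis-aligned space directions are supported")
    diag(m)
  } else if (!is.null(fields[["spacings"]])) {
    as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1]])
  } else stop("NRRD header missing spacing information")
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("invalid NRRD spacing")
  origin <- if (!is.null(fields[["space origin"]]))
    as.numeric(strsplit(gsub("[()]", "", fields[["space origin"]]), ",")[[1]])
  else c(0, 0, 0)
  n <- prod(sizes)
  data <- if (enc == "raw") {
    switch(type,
           double = , float64 = readBin(con, "double", n, size = 8, endian = "little"),
           float = , float32 = readBin(con, "double", n, size = 4, endian = "little"),
           short = , int16 = readBin(con, "integer", n, size = 2, endian = "little"),
           uchar = , uint8 = as.numeric(readBin(con, "integer", n, size = 1,
                                                signed = FALSE)),
           int = , int32 = readBin(con, "integer", n, size = 4, endian = "little"),
           stop("unsupported NRRD type: ", type))
  } else if (enc %in% c("ascii", "text", "txt")) {
    as.numeric(scan(con, what = numeric(), n = n, quiet = TRUE))
  } else stop("unsupported NRRD encoding: ", enc)
  if (length(data) != n) stop("NRRD data shorter than the declared sizes")
  volume(array(as.numeric(data), dim = sizes), spacing = spacing, origin = origin)
}

#' @rdname read_volume
#' @param vol a [volume()].
#' @param encoding `"raw"` (binary little-endian doubles) or `"ascii"`.
#' @export
write_volume <- function(vol, path, encoding = c("raw", "ascii")) {
  stopifnot(is_volume(vol))
  encoding <- match.arg(encoding)
  d <- dim(vol$data)
  hdr <- c("NRRD0004",
           "# generated by surgnav",
           "type: double",
           "dimension: 3",
           "space: right-anterior-superior",
           paste("sizes:", paste(d, collapse = " ")),
           paste0("space directions: ",
                  sprintf("(%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
                          vol$spacing[1], vol$spacing[2], vol$spacing[3])),
           "kinds: domain domain domain",
           if (encoding == "raw") "endian: little",
           paste("encoding:", encoding),
           paste0("space origin: ",
                  sprintf("(%.17g,%.17g,%.17g)",
                          vol$origin[1], vol$origin[2], vol$origin[3])),
           "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (encoding == "raw")
    writeBin(as.numeric(vol$data), con, size = 8, endian = "little")
  else
    writeLines(paste(format(as.numeric(vol$data), digits = 17), collapse = " "), con)
  invisible(path)
}
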