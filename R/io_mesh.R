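# Mesh and point-cloud interchange: PLY (ascii + binary little-endian),
# STL (ascii + binary), OBJ, XYZ, and the trajectory/transform JSON
# schemas. PLY binary little-endian is the canonical write format.

mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("ply", "stl", "obj"))
    stop("unsupported mesh extension: ", ext)
  ext
}

#' Read and write triangle meshes
#'
#' Supported formats by extension: PLY (ascii and binary little-endian),
#' STL (ascii and binary) and OBJ. PLY binary round trips are lossless for
#' vertices (double precision) and faces.
#'
#' @param path file path; format from the extension.
#' @return `read_mesh`: a `triangle_mesh`. Files with no faces are an error.
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  res <- switch(mesh_format(path),
                ply = read_ply(path),
                stl = read_stl(path),
                obj = read_obj(path))
  if (is.null(res$faces) || nrow(res$faces) == 0)
    stop("mesh file contains no faces: ", path)
  triangle_mesh(res$vertices, res$faces)
}

#' @rdname read_mesh
#' @param mesh a `triangle_mesh`.
#' @param binary write binary PLY/STL (default) or ascii.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  stopifnot(is_triangle_mesh(mesh))
  switch(mesh_format(path),
         ply = write_ply(mesh$vertices, mesh$faces, path, binary = binary),
         stl = write_stl(mesh, path, binary = binary),
         obj = write_obj(mesh, path))
  invisible(path)
}

#' Read and write point clouds
#'
#' PLY (vertex element, optional normals) or whitespace-separated XYZ text.
#'
#' @param path file path (`.ply` or `.xyz`).
#' @return `read_pointcloud`: a `point_cloud`.
#' @export
read_pointcloud <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    r <- read_ply(path)
    point_cloud(r$vertices, r$normals)
  } else if (ext == "xyz") {
    m <- as.matrix(utils::read.table(path))
    if (ncol(m) >= 6) point_cloud(m[, 1:3], m[, 4:6]) else point_cloud(m[, 1:3])
  } else stop("unsupported point-cloud extension: ", ext)
}

#' @rdname read_pointcloud
#' @param cloud a `point_cloud`.
#' @param binary write binary PLY (default).
#' @export
write_pointcloud <- function(cloud, path, binary = TRUE) {
  stopifnot(is_point_cloud(cloud))
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    write_ply(cloud$points, NULL, path, normals = cloud$normals, binary = binary)
  } else if (ext == "xyz") {
    m <- if (is.null(cloud$normals)) cloud$points else cbind(cloud$points, cloud$normals)
    utils::write.table(m, path, row.names = FALSE, col.names = FALSE)
  } else stop("unsupported point-cloud extension: ", ext)
  invisible(path)
}

# ---- PLY ----

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", 1L, size = sz, endian = "little")
  else
    readBin(con, "integer", 1L, size = sz, endian = "little",
            signed = !(type %in% c("uchar", "uint8", "ushort", "uint16")))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, 1)
  if (!identical(magic, "ply")) stop("not a PLY file: ", path)
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    ln <- readLines(con, 1)
    if (length(ln) == 0) stop("truncated PLY header")
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tok[1] == "comment") next
    if (tok[1] == "format") { fmt <- tok[2]; next }
    if (tok[1] == "element") {
      cur <- tok[2]
      elements[[cur]] <- list(count = as.integer(tok[3]), props = list())
      next
    }
    if (tok[1] == "property") {
      if (tok[2] == "list")
        elements[[cur]]$props[[tok[5]]] <- list(list = TRUE, count_type = tok[3],
                                                item_type = tok[4])
      else
        elements[[cur]]$props[[tok[3]]] <- list(list = FALSE, type = tok[2])
      next
    }
    if (tok[1] == "end_header") break
  }
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  verts <- NULL; norms <- NULL; faces <- NULL
  if (fmt == "ascii") {
    rest <- readLines(con)
    pos <- 1L
    for (en in names(elements)) {
      el <- elements[[en]]
      n <- el$count
      if (n == 0) next
      lines <- rest[pos:(pos + n - 1)]
      pos <- pos + n
      if (en == "vertex") {
        m <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), as.numeric))
        cn <- names(el$props)
        verts <- m[, match(c("x", "y", "z"), cn), drop = FALSE]
        if (all(c("nx", "ny", "nz") %in% cn))
          norms <- m[, match(c("nx", "ny", "nz"), cn), drop = FALSE]
      } else if (en == "face") {
        faces <- do.call(rbind, lapply(strsplit(trimws(lines), "\\s+"), function(v) {
          v <- as.integer(v)
          if (v[1] != 3L) stop("only triangle faces supported")
          v[2:4] + 1L
        }))
      }
    }
  } else {
    for (en in names(elements)) {
      el <- elements[[en]]
      if (en == "vertex") {
        cn <- names(el$props)
        m <- matrix(0, el$count, length(cn))
        for (i in seq_len(el$count))
          for (j in seq_along(cn))
            m[i, j] <- ply_read_scalar(con, el$props[[j]]$type)
        verts <- m[, match(c("x", "y", "z"), cn), drop = FALSE]
        if (all(c("nx", "ny", "nz") %in% cn))
          norms <- m[, match(c("nx", "ny", "nz"), cn), drop = FALSE]
      } else if (en == "face") {
        fl <- matrix(0L, el$count, 3)
        pr <- el$props[[1]]
        for (i in seq_len(el$count)) {
          cnt <- ply_read_scalar(con, pr$count_type)
          if (cnt != 3L) stop("only triangle faces supported")
          fl[i, ] <- vapply(1:3, function(j)
            as.integer(ply_read_scalar(con, pr$item_type)), 0L)
        }
        faces <- fl + 1L
      } else {
        # skip unknown fixed-size element
        for (i in seq_len(el$count))
          for (p in el$props) ply_read_scalar(con, p$type)
      }
    }
  }
  if (is.null(verts)) stop("PLY file has no vertex element")
  list(vertices = verts, faces = faces, normals = norms)
}

write_ply <- function(vertices, faces, path, normals = NULL, binary = TRUE) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           paste("element vertex", nrow(vertices)),
           "property double x", "property double y", "property double z")
  if (!is.null(normals))
    hdr <- c(hdr, "property double nx", "property double ny", "property double nz")
  if (!is.null(faces))
    hdr <- c(hdr, paste("element face", nrow(faces)),
             "property list uchar int vertex_indices")
  hdr <- c(hdr, "end_header")
  writeLines(hdr, con)
  vm <- if (is.null(normals)) vertices else cbind(vertices, normals)
  if (binary) {
    writeBin(as.numeric(t(vm)), con, size = 8, endian = "little")
    if (!is.null(faces))
      for (i in seq_len(nrow(faces))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(faces[i, ] - 1L), con, size = 4, endian = "little")
      }
  } else {
    writeLines(apply(vm, 1, function(r) paste(format(r, digits = 17), collapse = " ")), con)
    if (!is.null(faces))
      writeLines(apply(faces, 1, function(r)
        paste(c(3L, r - 1L), collapse = " ")), con)
  }
  invisible(path)
}

# ---- STL ----

read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", 80)
  ntri <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (length(ntri) == 1 && !is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)) {
    v <- matrix(0, ntri * 3L, 3)
    for (i in seq_len(ntri)) {
      readBin(con, "double", 3, size = 4, endian = "little")  # normal
      tri <- readBin(con, "double", 9, size = 4, endian = "little")
      v[(3 * i - 2):(3 * i), ] <- matrix(tri, 3, 3, byrow = TRUE)
      readBin(con, "raw", 2)
    }
  } else {
    close(con); on.exit(NULL)
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                               function(t) as.numeric(t[2:4])))
  }
  # weld duplicate vertices
  key <- apply(round(v, 9), 1, paste, collapse = " ")
  uid <- match(key, unique(key))
  verts <- v[!duplicated(uid), , drop = FALSE]
  faces <- matrix(uid, ncol = 3, byrow = TRUE)
  list(vertices = verts, faces = faces, normals = NULL)
}

write_stl <- function(mesh, path, binary = TRUE) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(n[i, ]), con, size = 4, endian = "little")
      writeBin(as.numeric(t(v[f[i, ], ])), con, size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %g %g %g", n[i, 1], n[i, 2], n[i, 3]), con)
      writeLines("    outer loop", con)
      for (j in 1:3)
        writeLines(sprintf("      vertex %g %g %g", v[f[i, j], 1],
                           v[f[i, j], 2], v[f[i, j], 3]), con)
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

# ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(t) as.numeric(t[2:4])))
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(t) {
    idx <- as.integer(sub("/.*", "", t[-1]))
    if (length(idx) != 3) stop("only triangle faces supported")
    idx
  }))
  list(vertices = verts, faces = faces, normals = NULL)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1, function(r)
    paste("v", paste(format(r, digits = 17), collapse = " "))), con)
  writeLines(apply(mesh$faces, 1, function(r)
    paste("f", paste(r, collapse = " "))), con)
  invisible(path)
}

# ---- trajectories & transforms ----

#' Trajectory and transform JSON I/O
#'
#' Trajectories use the schema
#' `{"label": str, "entry_mm": [x,y,z], "target_mm": [x,y,z]}` (a JSON
#' array of such objects); transforms are 4x4 row-major matrices.
#'
#' @param path file path.
#' @return `read_trajectories`: list of [trajectory()] objects.
#' @export
read_trajectories <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(x, function(t)
    trajectory(as.numeric(t$entry_mm), as.numeric(t$target_mm), t$label))
}

#' @rdname read_trajectories
#' @param trajectories list of [trajectory()] objects.
#' @export
write_trajectories <- function(trajectories, path) {
  payload <- lapply(trajectories, function(t)
    list(label = t$label, entry_mm = t$entry, target_mm = t$target))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname read_trajectories
#' @export
read_transform <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.list(m) && !is.null(m$matrix)) m <- m$matrix
  m <- if (is.list(m)) do.call(rbind, m) else as.matrix(m)
  rt_from_matrix(m)
}

#' @rdname read_trajectories
#' @param transform a [rigid_transform()].
#' @export
write_transform <- function(transform, path) {
  m <- rt_to_matrix(transform)
  jsonlite::write_json(lapply(seq_len(4), function(i) m[i, ]), path,
                       digits = NA)
  invisible(path)
}
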