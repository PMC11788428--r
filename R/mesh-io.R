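# Mesh file I/O: OBJ (v/f records) and PLY (ascii + binary_little_endian).
# Texture/normal fields in OBJ are ignored; faces are converted to 0-based
# indices internally. Units are millimetres; if a file's bounding-box
# diagonal is < 10 the coordinates are assumed to be metres and scaled
# by 1000 with a warning.

units_heuristic <- function(mesh, path) {
  if (nrow(mesh$vertices) > 0L && bbox_diagonal(mesh) < 10) {
    warning(sprintf("'%s': bounding-box diagonal < 10; assuming metres, scaling x1000",
                    path), call. = FALSE)
    mesh$vertices <- mesh$vertices * 1000
  }
  mesh
}

#' Read a triangle mesh from OBJ or PLY
#'
#' @param path file path.
#' @param format `"obj"`, `"ply"`, or `"auto"` (from the file extension).
#' @return a [triangle_mesh].
#' @export
read_mesh <- function(path, format = c("auto", "obj", "ply")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("obj", "ply")) stop(sprintf("cannot infer mesh format from '%s'", path))
    format <- ext
  }
  mesh <- switch(format, obj = read_obj(path), ply = read_ply(path))
  units_heuristic(mesh, path)
}

#' Write a triangle mesh to OBJ or PLY
#'
#' @param mesh a [triangle_mesh].
#' @param path output path.
#' @param format `"obj"`, `"ply"`, or `"auto"`; PLY is written as ascii
#'   unless `binary = TRUE`.
#' @param binary write binary_little_endian PLY.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "obj", "ply"), binary = FALSE) {
  stopifnot_mesh(mesh)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("obj", "ply")) stop(sprintf("cannot infer mesh format from '%s'", path))
    format <- ext
  }
  switch(format,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path, binary = binary))
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v ", lines, value = FALSE)
  flines <- grep("^f ", lines, value = FALSE)
  parse_v <- function(idx) {
    parts <- strsplit(trimws(sub("^v", "", lines[idx])), "\\s+")[[1L]]
    xyz <- suppressWarnings(as.numeric(parts[1:3]))
    if (any(is.na(xyz))) stop(sprintf("OBJ parse error at line %d: '%s'", idx, lines[idx]))
    xyz
  }
  parse_f <- function(idx) {
    parts <- strsplit(trimws(sub("^f", "", lines[idx])), "\\s+")[[1L]]
    if (length(parts) != 3L) {
      stop(sprintf("OBJ parse error at line %d: only triangles supported ('%s')", idx, lines[idx]))
    }
    # drop texture/normal refs: keep the part before the first '/'
    ids <- suppressWarnings(as.integer(vapply(strsplit(parts, "/"), `[[`, "", 1L)))
    if (any(is.na(ids))) stop(sprintf("OBJ parse error at line %d: '%s'", idx, lines[idx]))
    ids
  }
  verts <- if (length(vlines)) do.call(rbind, lapply(vlines, parse_v)) else matrix(0, 0, 3)
  faces1 <- if (length(flines)) do.call(rbind, lapply(flines, parse_f)) else matrix(0L, 0, 3)
  if (nrow(faces1) > 0L && (any(faces1 < 1L) || any(faces1 > nrow(verts)))) {
    bad <- which(faces1 < 1L | faces1 > nrow(verts))[1L]
    stop(sprintf("OBJ face references vertex %d of %d", faces1[bad], nrow(verts)))
  }
  triangle_mesh(verts, faces1 - 1L, name = basename(path))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
  if (nrow(mesh$faces) > 0L) {
    f1 <- mesh$faces + 1L
    writeLines(sprintf("f %d %d %d", f1[, 1L], f1[, 2L], f1[, 3L]), con)
  }
  invisible(path)
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ascii lines terminated by "end_header"
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop(sprintf("PLY parse error: unterminated header in %s", path))
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (!grepl("^ply", header[1L])) stop(sprintf("PLY parse error: missing 'ply' magic in %s", path))
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L) stop("PLY parse error: missing format line")
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian")) {
    stop(sprintf("unsupported PLY format '%s' (ascii and binary_little_endian only)", fmt))
  }
  el_lines <- grep("^element ", header)
  get_count <- function(what) {
    ln <- grep(sprintf("^element %s ", what), header, value = TRUE)
    if (length(ln) != 1L) stop(sprintf("PLY parse error: no 'element %s'", what))
    as.integer(strsplit(trimws(ln), "\\s+")[[1L]][3L])
  }
  nv <- get_count("vertex")
  nf <- get_count("face")
  # vertex properties must start with x, y, z as float/double
  vert_el <- grep("^element vertex ", header)
  next_el <- el_lines[el_lines > vert_el]
  vprops <- header[(vert_el + 1L):(if (length(next_el)) next_el[1L] - 1L else length(header) - 1L)]
  vprops <- grep("^property ", vprops, value = TRUE)
  vtypes <- vapply(strsplit(trimws(vprops), "\\s+"), `[[`, "", 2L)
  if (length(vprops) < 3L) stop("PLY parse error: vertex element needs >= 3 properties")
  if (fmt == "ascii") {
    body <- readLines(con)
    if (length(body) < nv + nf) stop("PLY parse error: truncated ascii body")
    vparts <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
    verts <- t(vapply(vparts, function(p) as.numeric(p[1:3]), numeric(3)))
    fparts <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    faces <- t(vapply(fparts, function(p) {
      cnt <- as.integer(p[1L])
      if (cnt != 3L) stop("PLY parse error: only triangular faces supported")
      as.integer(p[2:4])
    }, integer(3)))
  } else {
    sizeof <- c(float = 4L, float32 = 4L, double = 8L, float64 = 8L,
                char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                int = 4L, uint = 4L, int32 = 4L, uint32 = 4L)
    vsz <- sizeof[vtypes]
    if (any(is.na(vsz))) stop("PLY parse error: unknown vertex property type")
    verts <- matrix(0, nv, 3L)
    for (i in seq_len(nv)) {
      for (p in seq_along(vtypes)) {
        val <- read_ply_scalar(con, vtypes[p])
        if (p <= 3L) verts[i, p] <- val
      }
    }
    faces <- matrix(0L, nf, 3L)
    flist_line <- grep("^property list", header, value = TRUE)[1L]
    ftoks <- strsplit(trimws(flist_line), "\\s+")[[1L]]
    cnt_type <- ftoks[3L]; idx_type <- ftoks[4L]
    for (i in seq_len(nf)) {
      cnt <- read_ply_scalar(con, cnt_type)
      if (cnt != 3) stop("PLY parse error: only triangular faces supported")
      faces[i, ] <- c(read_ply_scalar(con, idx_type),
                      read_ply_scalar(con, idx_type),
                      read_ply_scalar(con, idx_type))
    }
  }
  if (nrow(faces) > 0L && (any(faces < 0L) || any(faces >= nv))) {
    stop(sprintf("PLY face index out of range [0, %d)", nv))
  }
  triangle_mesh(verts, faces, name = basename(path))
}

read_ply_scalar <- function(con, type) {
  switch(type,
         float = , float32 = readBin(con, "numeric", 1L, size = 4L, endian = "little"),
         double = , float64 = readBin(con, "numeric", 1L, size = 8L, endian = "little"),
         char = , int8 = readBin(con, "integer", 1L, size = 1L, signed = TRUE, endian = "little"),
         uchar = , uint8 = readBin(con, "integer", 1L, size = 1L, signed = FALSE, endian = "little"),
         short = , int16 = readBin(con, "integer", 1L, size = 2L, signed = TRUE, endian = "little"),
         ushort = , uint16 = readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = "little"),
         int = , int32 = readBin(con, "integer", 1L, size = 4L, endian = "little"),
         uint = , uint32 = readBin(con, "integer", 1L, size = 4L, endian = "little"),
         stop(sprintf("unknown PLY scalar type '%s'", type)))
}

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c("ply",
              sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
              sprintf("element vertex %d", nv),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con, sep = "\n")
    for (i in seq_len(nv)) {
      writeBin(as.numeric(mesh$vertices[i, ]), con, size = 8L, endian = "little")
    }
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.9g %.9g %.9g",
                       mesh$vertices[, 1L], mesh$vertices[, 2L], mesh$vertices[, 3L]), con)
    if (nf > 0L) {
      writeLines(sprintf("3 %d %d %d",
                         mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L]), con)
    }
  }
  invisible(path)
}

#' Read a dataset manifest
#'
#' A manifest is a CSV with columns `id`, `mesh_path`, `split`
#' (one of pretrain, finetune, eval, test) describing a fixed-topology
#' mesh dataset on disk.
#'
#' @param path CSV path.
#' @return a tibble with the manifest columns.
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "mesh_path", "split")
  if (!all(need %in% names(df))) {
    stop(sprintf("manifest must have columns %s", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(df$split), c("pretrain", "finetune", "eval", "test"))
  if (length(bad)) stop(sprintf("unknown split label(s): %s", paste(bad, collapse = ", ")))
  tibble::as_tibble(df)
}
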