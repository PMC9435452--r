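# PLY / OBJ mesh input-output.
#
# PLY is written with double-precision coordinates so that a binary
# round-trip is bit-exact; readers accept float or double coordinates and
# optional uchar RGB. OBJ stores 1-based indices on disk; the in-memory
# faces are 1-based as well, so conversion happens only for PLY (0-based on
# disk).

.ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                    short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                    int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                    float = 4L, float32 = 4L, double = 8L, float64 = 8L)

.ply_read_column <- function(raw_mat, offset, type, n) {
  size <- .ply_type_size[[type]]
  bytes <- as.vector(raw_mat[offset + seq_len(size), , drop = FALSE])
  what <- if (type %in% c("float", "float32", "double", "float64")) "double"
          else "integer"
  signed <- !(type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32"))
  out <- readBin(bytes, what = what, n = n, size = size,
                 signed = if (size < 4L) signed else TRUE, endian = "little")
  out
}

#' Read a triangle mesh from PLY or OBJ
#'
#' Supports ASCII and binary-little-endian PLY (with optional uchar RGB
#' vertex colour) and Wavefront OBJ (`v`/`f` records; `f` entries may carry
#' `/vt/vn` suffixes, which are ignored). Vertex order is preserved from
#' the file.
#'
#' @param path path to the mesh file.
#' @param format `"ply"`, `"obj"` or `"auto"` (from the file extension).
#' @return a `triangle_mesh`.
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("cannot read mesh file '%s': no such file", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", obj = "obj",
                     stop(sprintf("cannot infer mesh format of '%s'", path)))
  }
  switch(format, ply = .read_ply(path), obj = .read_obj(path))
}

.read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) stop(sprintf("malformed PLY '%s': no end_header", path))
    header <- c(header, line)
    if (identical(trimws(line), "end_header")) break
  }
  if (!identical(trimws(header[1L]), "ply"))
    stop(sprintf("'%s' is not a PLY file", path))
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1L) stop(sprintf("malformed PLY '%s': missing format line", path))
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1L]][2L]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("unsupported PLY format '%s' in '%s'", fmt, path))

  # parse elements and their properties in order
  elements <- list()
  current <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1L]]
    if (tok[1L] == "element") {
      if (!is.null(current)) elements[[current$name]] <- current
      current <- list(name = tok[2L], count = as.integer(tok[3L]), props = list())
    } else if (tok[1L] == "property" && !is.null(current)) {
      if (tok[2L] == "list") {
        current$props[[length(current$props) + 1L]] <-
          list(name = tok[5L], list = TRUE, count_type = tok[3L], item_type = tok[4L])
      } else {
        current$props[[length(current$props) + 1L]] <-
          list(name = tok[3L], list = FALSE, type = tok[2L])
      }
    }
  }
  if (!is.null(current)) elements[[current$name]] <- current
  if (is.null(elements$vertex)) stop(sprintf("malformed PLY '%s': no vertex element", path))

  if (fmt == "ascii") .read_ply_ascii(con, elements, path)
  else .read_ply_binary(con, elements, path)
}

.read_ply_ascii <- function(con, elements, path) {
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pos <- 0L
  vertices <- NULL; colors <- NULL; faces <- matrix(integer(0), 0L, 3L)
  for (el in elements) {
    block <- lines[pos + seq_len(el$count)]
    pos <- pos + el$count
    toks <- strsplit(trimws(block), "\\s+")
    if (el$name == "vertex") {
      pnames <- vapply(el$props, `[[`, "", "name")
      vals <- matrix(as.numeric(unlist(toks)), nrow = el$count, byrow = TRUE)
      xyz <- match(c("x", "y", "z"), pnames)
      if (anyNA(xyz)) stop(sprintf("malformed PLY '%s': vertex lacks x/y/z", path))
      vertices <- vals[, xyz, drop = FALSE]
      rgb <- match(c("red", "green", "blue"), pnames)
      if (!anyNA(rgb)) colors <- matrix(as.integer(vals[, rgb]), ncol = 3L)
    } else if (el$name == "face") {
      faces <- t(vapply(seq_along(toks), function(i) {
        tk <- as.integer(toks[[i]])
        if (tk[1L] != 3L)
          stop(sprintf("malformed PLY '%s': face %d is not a triangle", path, i))
        tk[2:4] + 1L
      }, integer(3L)))
    }
  }
  triangle_mesh(vertices, faces, colors)
}

.read_ply_binary <- function(con, elements, path) {
  payload <- readBin(con, "raw", n = file.size(path))
  offset <- 0L
  vertices <- NULL; colors <- NULL; faces <- matrix(integer(0), 0L, 3L)
  for (el in elements) {
    if (any(vapply(el$props, `[[`, TRUE, "list"))) {
      # list element (faces): fixed triangle records assumed, verified below
      p <- el$props[[1L]]
      csz <- .ply_type_size[[p$count_type]]
      isz <- .ply_type_size[[p$item_type]]
      rec <- csz + 3L * isz
      need <- el$count * rec
      if (offset + need > length(payload))
        stop(sprintf("malformed PLY '%s': truncated %s data", path, el$name))
      raw_mat <- matrix(payload[offset + seq_len(need)], nrow = rec)
      counts <- .ply_read_column(raw_mat, 0L, p$count_type, el$count)
      if (any(counts != 3L))
        stop(sprintf("malformed PLY '%s': face %d is not a triangle",
                     path, which(counts != 3L)[1L]))
      idx <- vapply(0:2, function(k)
        .ply_read_column(raw_mat, csz + k * isz, p$item_type, el$count),
        numeric(el$count))
      if (el$name == "face") faces <- matrix(as.integer(idx), ncol = 3L) + 1L
      offset <- offset + need
    } else {
      sizes <- vapply(el$props, function(p) .ply_type_size[[p$type]], 1L)
      rec <- sum(sizes)
      need <- el$count * rec
      if (offset + need > length(payload))
        stop(sprintf("malformed PLY '%s': truncated %s data", path, el$name))
      raw_mat <- matrix(payload[offset + seq_len(need)], nrow = rec)
      offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
      pnames <- vapply(el$props, `[[`, "", "name")
      if (el$name == "vertex") {
        get_col <- function(nm) {
          i <- match(nm, pnames)
          if (is.na(i)) return(NULL)
          .ply_read_column(raw_mat, offs[i], el$props[[i]]$type, el$count)
        }
        vertices <- cbind(get_col("x"), get_col("y"), get_col("z"))
        if (is.null(vertices) || ncol(vertices) != 3L)
          stop(sprintf("malformed PLY '%s': vertex lacks x/y/z", path))
        r <- get_col("red"); g <- get_col("green"); b <- get_col("blue")
        if (!is.null(r) && !is.null(g) && !is.null(b))
          colors <- cbind(as.integer(r), as.integer(g), as.integer(b))
      }
      offset <- offset + need
    }
  }
  triangle_mesh(vertices, faces, colors)
}

.read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^v\\s", lines)
  flines <- grep("^f\\s", lines)
  if (length(vlines) == 0L) stop(sprintf("malformed OBJ '%s': no vertices", path))
  vt <- strsplit(trimws(sub("^v\\s+", "", lines[vlines])), "\\s+")
  vertices <- t(vapply(vt, function(x) as.numeric(x[1:3]), numeric(3L)))
  faces <- matrix(integer(0), 0L, 3L)
  if (length(flines) > 0L) {
    out <- vector("list", length(flines))
    for (i in seq_along(flines)) {
      tok <- strsplit(trimws(sub("^f\\s+", "", lines[flines[i]])), "\\s+")[[1L]]
      idx <- suppressWarnings(as.integer(vapply(strsplit(tok, "/"), `[[`, "", 1L)))
      if (anyNA(idx) || length(idx) < 3L)
        stop(sprintf("malformed OBJ '%s': bad face at line %d", path, flines[i]))
      # fan-triangulate polygons; triangles pass through unchanged
      out[[i]] <- cbind(idx[1L], idx[seq(2L, length(idx) - 1L)],
                        idx[seq(3L, length(idx))])
    }
    faces <- do.call(rbind, out)
  }
  triangle_mesh(vertices, faces)
}

#' Write a triangle mesh to PLY or OBJ
#'
#' Binary PLY stores coordinates as doubles, so a write/read round-trip is
#' bit-exact; vertex colours, when present, are written as uchar RGB. OBJ is
#' written with 12 significant digits.
#'
#' @param mesh a `triangle_mesh`.
#' @param path output path.
#' @param format `"ply"`, `"obj"` or `"auto"` (from the extension).
#' @param binary write binary-little-endian PLY (default) or ASCII.
#' @return the path, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "obj"),
                       binary = TRUE) {
  validate_mesh(mesh)
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", obj = "obj",
                     stop(sprintf("cannot infer mesh format of '%s'", path)))
  }
  ok <- tryCatch({
    if (format == "ply") .write_ply(mesh, path, binary) else .write_obj(mesh, path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop(sprintf("cannot write mesh to '%s': %s", path, conditionMessage(ok)))
  invisible(path)
}

.write_ply <- function(mesh, path, binary) {
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  has_col <- !is.null(mesh$colors)
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (binary) "binary_little_endian" else "ascii"),
              sprintf("element vertex %d", nv),
              "property double x", "property double y", "property double z",
              if (has_col) c("property uchar red", "property uchar green",
                             "property uchar blue"),
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  faces0 <- mesh$faces - 1L
  if (binary) {
    for (i in seq_len(nv)) {
      writeBin(as.numeric(mesh$vertices[i, ]), con, size = 8L, endian = "little")
      if (has_col)
        writeBin(as.raw(mesh$colors[i, ]), con)
    }
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(faces0[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    vtxt <- apply(mesh$vertices, 1L, function(r)
      paste(sprintf("%.17g", r), collapse = " "))
    if (has_col)
      vtxt <- paste(vtxt, apply(mesh$colors, 1L, paste, collapse = " "))
    writeLines(vtxt, con, sep = "\n")
    if (nf > 0L)
      writeLines(paste("3", faces0[, 1L], faces0[, 2L], faces0[, 3L]), con,
                 sep = "\n")
  }
  invisible(NULL)
}

.write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(mesh$vertices, 1L, function(r)
    paste("v", paste(sprintf("%.12g", r), collapse = " "))), con)
  if (nrow(mesh$faces) > 0L)
    writeLines(paste("f", mesh$faces[, 1L], mesh$faces[, 2L], mesh$faces[, 3L]),
               con)
  invisible(NULL)
}

#' Read a landmark file
#'
#' Plain-text format, one landmark per line: `name x y z` (mm).
#'
#' @param path path to the landmark file.
#' @return a named n x 3 matrix of landmark coordinates.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read landmark file '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  tok <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(tok, length, 1L) < 4L)
  if (length(bad) > 0L)
    stop(sprintf("malformed landmark line %d in '%s'", bad[1L], path))
  coords <- t(vapply(tok, function(x) as.numeric(x[2:4]), numeric(3L)))
  rownames(coords) <- vapply(tok, `[[`, "", 1L)
  coords
}
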