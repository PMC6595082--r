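#' Mesh file I/O (PLY and STL)
#'
#' Meshes are written with vertex coordinates in world millimetres.  PLY can
#' be written in ascii (default) or binary little-endian form and read back;
#' STL (ascii) is write-only, as the format does not preserve shared
#' vertices.
#'
#' @param mesh a [triangle_mesh()].
#' @param path output file path.
#' @param binary write binary little-endian PLY (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_ply <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  fmt <- if (binary) "binary_little_endian" else "ascii"
  header <- c(
    "ply",
    sprintf("format %s 1.0", fmt),
    "comment longivol mesh, coordinates in world mm",
    sprintf("element vertex %d", nv),
    "property double x", "property double y", "property double z",
    sprintf("element face %d", nf),
    "property list uchar int vertex_indices",
    "end_header")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (binary) {
    writeBin(as.numeric(t(mesh$vertices)), con, size = 8, endian = "little")
    fm <- mesh$faces - 1L
    for (q in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(fm[q, ]), con, size = 4, endian = "little")
    }
  } else {
    vtxt <- apply(mesh$vertices, 1, function(r)
      paste(sprintf("%.17g", r), collapse = " "))
    ftxt <- apply(mesh$faces - 1L, 1, function(r)
      paste(c(3L, r), collapse = " "))
    writeLines(c(vtxt, ftxt), con)
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("unreadable input: truncated PLY header")
    header <- c(header, line)
    if (line == "end_header") break
  }
  fmt_line <- grep("^format ", header, value = TRUE)
  if (length(fmt_line) != 1) stop("unreadable input: missing PLY format line")
  binary <- grepl("binary_little_endian", fmt_line)
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", header, value = TRUE)))
  if (length(nv) != 1 || length(nf) != 1 || is.na(nv) || is.na(nf))
    stop("unreadable input: missing PLY element counts")
  vprops <- grep("^property (double|float)", header, value = TRUE)
  dbl <- grepl("double", vprops[1])
  if (binary) {
    verts <- matrix(readBin(con, "double", n = nv * length(vprops),
                            size = if (dbl) 8 else 4, endian = "little"),
                    ncol = length(vprops), byrow = TRUE)[, 1:3, drop = FALSE]
    faces <- matrix(0L, nf, 3)
    for (q in seq_len(nf)) {
      k <- as.integer(readBin(con, "raw", n = 1))
      idx <- readBin(con, "integer", n = k, size = 4, endian = "little")
      if (k != 3L) stop("unreadable input: non-triangular PLY face")
      faces[q, ] <- idx + 1L
    }
  } else {
    body <- readLines(con)
    body <- body[nzchar(body)]
    if (length(body) < nv + nf) stop("unreadable input: truncated PLY body")
    verts <- do.call(rbind, lapply(strsplit(body[seq_len(nv)], "\\s+"),
                                   function(x) as.numeric(x[1:3])))
    fl <- strsplit(body[nv + seq_len(nf)], "\\s+")
    faces <- do.call(rbind, lapply(fl, function(x) {
      x <- as.integer(x)
      if (x[1] != 3L) stop("unreadable input: non-triangular PLY face")
      x[2:4] + 1L
    }))
  }
  triangle_mesh(verts, faces)
}

#' @rdname write_ply
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  v <- mesh$vertices; f <- mesh$faces
  lines <- character(2 + 7 * nrow(f))
  lines[1] <- "solid longivol"
  pos <- 2
  for (q in seq_len(nrow(f))) {
    a <- v[f[q, 1], ]; b <- v[f[q, 2], ]; cc <- v[f[q, 3], ]
    n <- c((b[2]-a[2])*(cc[3]-a[3]) - (b[3]-a[3])*(cc[2]-a[2]),
           (b[3]-a[3])*(cc[1]-a[1]) - (b[1]-a[1])*(cc[3]-a[3]),
           (b[1]-a[1])*(cc[2]-a[2]) - (b[2]-a[2])*(cc[1]-a[1]))
    nn <- sqrt(sum(n^2)); if (nn > 0) n <- n / nn
    lines[pos:(pos + 6)] <- c(
      sprintf("  facet normal %g %g %g", n[1], n[2], n[3]),
      "    outer loop",
      sprintf("      vertex %g %g %g", a[1], a[2], a[3]),
      sprintf("      vertex %g %g %g", b[1], b[2], b[3]),
      sprintf("      vertex %g %g %g", cc[1], cc[2], cc[3]),
      "    endloop",
      "  endfacet")
    pos <- pos + 7
  }
  lines[pos] <- "endsolid longivol"
  writeLines(lines, path)
  invisible(path)
}
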