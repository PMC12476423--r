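#' Read a triangulated surface mesh
#'
#' Supports Wavefront OBJ (`v`/`vn`/`f` records, faces triangulated on
#' read by fanning), PLY (ascii and binary little-endian) and STL (binary
#' and ascii; duplicate corner positions are welded into shared vertices).
#' Normals absent from the file are recomputed from the geometry with
#' [compute_vertex_normals()]. OBJ's 1-based face indices are kept 1-based
#' internally; PLY/STL 0-based indices are shifted at the boundary.
#'
#' @param path file to read.
#' @param format `"obj"`, `"ply"` or `"stl"`; default guessed from the
#'   file extension.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  format <- match.arg(tolower(format %||% tools::file_ext(path)),
                      c("obj", "ply", "stl"))
  switch(format,
         obj = read_obj(path),
         ply = read_ply(path),
         stl = read_stl(path))
}

#' Write a triangulated surface mesh
#'
#' Vertex order is preserved exactly; [read_mesh()] on the result returns
#' the same connectivity. OBJ and ascii PLY are plain text; STL is the
#' 80-byte-header binary layout (`ascii = TRUE` writes ascii STL). PLY is
#' written ascii by default, binary little-endian with `ascii = FALSE`.
#'
#' @param mesh a [surface_mesh()].
#' @param path output file.
#' @param format `"obj"`, `"ply"` or `"stl"`; default from the extension.
#' @param ascii logical; for PLY/STL choose the text encoding.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL, ascii = TRUE) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (nrow(mesh$vertices) == 0L) stop("refusing to write an empty mesh")
  format <- match.arg(tolower(format %||% tools::file_ext(path)),
                      c("obj", "ply", "stl"))
  switch(format,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path, ascii),
         stl = write_stl(mesh, path, ascii))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || identical(a, "")) b else a

## ---- OBJ ----------------------------------------------------------------

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  vs <- lines[startsWith(lines, "v ")]
  vns <- lines[startsWith(lines, "vn ")]
  fs <- lines[startsWith(lines, "f ")]
  if (length(vs) == 0L) stop(sprintf("OBJ '%s': no vertex records", path))
  parse_nums <- function(x, tag) {
    toks <- strsplit(sub(paste0("^", tag, "\\s+"), "", x), "\\s+")
    m <- t(vapply(toks, function(tk) as.numeric(tk[1:3]), numeric(3)))
    if (anyNA(m)) stop(sprintf("OBJ '%s': malformed '%s' record", path, tag))
    m
  }
  v <- parse_nums(vs, "v")
  tris <- vnidx <- NULL
  if (length(fs)) {
    out_t <- vector("list", length(fs)); out_n <- vector("list", length(fs))
    for (i in seq_along(fs)) {
      toks <- strsplit(sub("^f\\s+", "", fs[i]), "\\s+")[[1]]
      parts <- strsplit(toks, "/", fixed = TRUE)
      vi <- vapply(parts, function(p) as.integer(p[1]), integer(1))
      ni <- vapply(parts, function(p)
        if (length(p) >= 3 && nzchar(p[3])) as.integer(p[3]) else NA_integer_,
        integer(1))
      if (anyNA(vi) || length(vi) < 3)
        stop(sprintf("OBJ '%s': malformed face record '%s'", path, fs[i]))
      # fan-triangulate polygons
      k <- length(vi)
      out_t[[i]] <- cbind(vi[1], vi[2:(k - 1)], vi[3:k])
      out_n[[i]] <- cbind(ni[1], ni[2:(k - 1)], ni[3:k])
    }
    tris <- do.call(rbind, out_t)
    vnidx <- do.call(rbind, out_n)
    if (min(tris) < 1L || max(tris) > nrow(v))
      stop(sprintf("OBJ '%s': face references vertex %d of %d",
                   path, max(tris), nrow(v)))
  } else tris <- matrix(integer(), 0L, 3L)
  normals <- NULL
  if (length(vns) && !is.null(vnidx) && !anyNA(vnidx)) {
    vn <- parse_nums(vns, "vn")
    # accept only the common case where normal index == vertex index
    if (nrow(vn) == nrow(v) && all(vnidx == tris)) normals <- vn
  }
  surface_mesh(v, tris, normals)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# exported by octodeform", con)
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("vn %.9g %.9g %.9g", mesh$normals[, 1],
                     mesh$normals[, 2], mesh$normals[, 3]), con)
  tr <- mesh$triangles
  writeLines(sprintf("f %d//%d %d//%d %d//%d",
                     tr[, 1], tr[, 1], tr[, 2], tr[, 2], tr[, 3], tr[, 3]), con)
}

## ---- PLY ----------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop(sprintf("PLY '%s': truncated header", path))
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
    if (length(header) > 500L) stop(sprintf("PLY '%s': header not terminated", path))
  }
  if (trimws(header[1]) != "ply") stop(sprintf("PLY '%s': missing magic", path))
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_line), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop(sprintf("PLY '%s': unsupported format '%s'", path, fmt))
  # parse element/property structure
  elems <- list(); cur <- NULL
  for (ln in header) {
    tk <- strsplit(trimws(ln), "\\s+")[[1]]
    if (tk[1] == "element") {
      cur <- tk[2]
      elems[[cur]] <- list(count = as.integer(tk[3]), props = list())
    } else if (tk[1] == "property" && !is.null(cur)) {
      if (tk[2] == "list") {
        elems[[cur]]$props[[tk[5]]] <- list(list = TRUE, ctype = tk[3], vtype = tk[4])
      } else {
        elems[[cur]]$props[[tk[3]]] <- list(list = FALSE, vtype = tk[2])
      }
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stop(sprintf("PLY '%s': needs vertex and face elements", path))
  if (fmt == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    nv <- elems$vertex$count; nf <- elems$face$count
    if (length(body) < nv + nf) stop(sprintf("PLY '%s': truncated body", path))
    vprops <- names(elems$vertex$props)
    vm <- t(vapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"),
                   function(tk) as.numeric(tk[seq_along(vprops)]),
                   numeric(length(vprops))))
    colnames(vm) <- vprops
    fl <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
    tris <- lapply(fl, function(tk) {
      k <- as.integer(tk[1])
      idx <- as.integer(tk[1 + seq_len(k)])
      if (k < 3) stop(sprintf("PLY '%s': face with %d vertices", path, k))
      cbind(idx[1], idx[2:(k - 1)], idx[3:k])
    })
    tris <- do.call(rbind, tris) + 1L
  } else {
    read_t <- function(type, n) {
      switch(type,
             char = , int8 = readBin(con, integer(), n, size = 1, signed = TRUE),
             uchar = , uint8 = readBin(con, integer(), n, size = 1, signed = FALSE),
             short = , int16 = readBin(con, integer(), n, size = 2, endian = "little"),
             ushort = , uint16 = readBin(con, integer(), n, size = 2, signed = FALSE, endian = "little"),
             int = , int32 = , uint = , uint32 = readBin(con, integer(), n, size = 4, endian = "little"),
             float = , float32 = readBin(con, numeric(), n, size = 4, endian = "little"),
             double = , float64 = readBin(con, numeric(), n, size = 8, endian = "little"),
             stop(sprintf("PLY '%s': unsupported type '%s'", path, type)))
    }
    vprops <- elems$vertex$props
    nv <- elems$vertex$count
    vm <- matrix(NA_real_, nv, length(vprops),
                 dimnames = list(NULL, names(vprops)))
    # read row-wise (properties may interleave)
    for (i in seq_len(nv))
      for (j in seq_along(vprops))
        vm[i, j] <- read_t(vprops[[j]]$vtype, 1L)
    fp <- elems$face$props[[1]]
    tris <- vector("list", elems$face$count)
    for (i in seq_len(elems$face$count)) {
      k <- read_t(fp$ctype, 1L)
      idx <- read_t(fp$vtype, k)
      tris[[i]] <- cbind(idx[1], idx[2:(k - 1)], idx[3:k])
    }
    tris <- do.call(rbind, tris) + 1L
  }
  v <- vm[, c("x", "y", "z"), drop = FALSE]
  normals <- if (all(c("nx", "ny", "nz") %in% colnames(vm)))
    vm[, c("nx", "ny", "nz"), drop = FALSE] else NULL
  if (min(tris) < 1L || max(tris) > nrow(v))
    stop(sprintf("PLY '%s': face references vertex %d of %d",
                 path, max(tris) - 1L, nrow(v)))
  surface_mesh(v, tris, normals)
}

write_ply <- function(mesh, path, ascii = TRUE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$triangles)
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (ascii) "ascii" else "binary_little_endian"),
              "comment exported by octodeform",
              sprintf("element vertex %d", nv),
              "property double x", "property double y", "property double z",
              "property double nx", "property double ny", "property double nz",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  vm <- cbind(mesh$vertices, mesh$normals)
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(apply(vm, 1, function(r) paste(sprintf("%.12g", r), collapse = " ")), con)
    tr <- mesh$triangles - 1L
    writeLines(sprintf("3 %d %d %d", tr[, 1], tr[, 2], tr[, 3]), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeBin(as.numeric(t(vm)), con, size = 8, endian = "little")
    tr <- mesh$triangles - 1L
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(tr[i, ]), con, size = 4, endian = "little")
    }
  }
}

## ---- STL ----------------------------------------------------------------

read_stl <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head_raw <- readBin(con, raw(), min(512, sz))
  close(con)
  # ascii STL starts with "solid" and contains only printable text;
  # binary STL has an arbitrary 80-byte header
  starts_solid <- length(head_raw) >= 5 &&
    identical(rawToChar(head_raw[1:5]), "solid")
  printable <- all(head_raw %in% as.raw(c(9L, 10L, 13L, 32:126)))
  if (starts_solid && printable) read_stl_ascii(path) else read_stl_binary(path)
}

stl_weld <- function(tri_pts) {
  # tri_pts: (3*n_t) x 3 matrix of corner positions in triangle order
  key <- paste(tri_pts[, 1], tri_pts[, 2], tri_pts[, 3], sep = "_")
  ids <- match(key, unique(key))
  v <- tri_pts[!duplicated(key), , drop = FALSE]
  tris <- matrix(ids, ncol = 3L, byrow = TRUE)
  surface_mesh(v, tris)
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, raw(), 80L)
  nt <- readBin(con, integer(), 1L, size = 4, endian = "little")
  if (nt <= 0 || sz < 84 + 50 * nt)
    stop(sprintf("STL '%s': inconsistent triangle count %d", path, nt))
  pts <- matrix(NA_real_, 3L * nt, 3L)
  for (i in seq_len(nt)) {
    vals <- readBin(con, numeric(), 12L, size = 4, endian = "little")
    readBin(con, raw(), 2L)  # attribute byte count
    pts[3L * i - 2:0, ] <- matrix(vals[4:12], 3L, 3L, byrow = TRUE)
  }
  stl_weld(pts)
}

read_stl_ascii <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  vl <- grep("^vertex\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(vl) %% 3L != 0L)
    stop(sprintf("STL '%s': vertex records not a multiple of 3", path))
  pts <- t(vapply(strsplit(vl, "\\s+"),
                  function(tk) as.numeric(tk[2:4]), numeric(3)))
  if (anyNA(pts)) stop(sprintf("STL '%s': malformed vertex record", path))
  stl_weld(pts)
}

write_stl <- function(mesh, path, ascii = FALSE) {
  tr <- mesh$triangles
  a <- mesh$vertices[tr[, 1], , drop = FALSE]
  b <- mesh$vertices[tr[, 2], , drop = FALSE]
  c_ <- mesh$vertices[tr[, 3], , drop = FALSE]
  e1 <- b - a; e2 <- c_ - a
  fn <- normalize_rows(cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
                             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
                             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]))
  if (ascii) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid octodeform", con)
    for (i in seq_len(nrow(tr))) {
      writeLines(c(sprintf("facet normal %.9g %.9g %.9g", fn[i, 1], fn[i, 2], fn[i, 3]),
                   "outer loop",
                   sprintf("vertex %.9g %.9g %.9g", a[i, 1], a[i, 2], a[i, 3]),
                   sprintf("vertex %.9g %.9g %.9g", b[i, 1], b[i, 2], b[i, 3]),
                   sprintf("vertex %.9g %.9g %.9g", c_[i, 1], c_[i, 2], c_[i, 3]),
                   "endloop", "endfacet"), con)
    }
    writeLines("endsolid octodeform", con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(c(charToRaw("octodeform binary STL"), raw(80 - 21)), con)
    writeBin(as.integer(nrow(tr)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(tr))) {
      writeBin(as.numeric(c(fn[i, ], a[i, ], b[i, ], c_[i, ])), con,
               size = 4, endian = "little")
      writeBin(raw(2), con)
    }
  }
}
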