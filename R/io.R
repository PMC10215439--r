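#' Read a triangulated surface file
#'
#' Supported formats (by extension): Wavefront `obj`, ASCII `ply`, ASCII
#' `stl` and VTK XML PolyData `vtp`. VTP point-data arrays (and `ply` extra
#' vertex properties) are loaded into `point_data`; a `Normals` array is
#' used as the vertex normals. STL stores no shared vertices or point data:
#' duplicated corner vertices are merged and normals recomputed, with a
#' warning.
#'
#' @param path file path; format inferred from the extension.
#' @return a [surface_mesh()].
#' @export
read_surface <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path),
         ply = read_ply(path),
         stl = read_stl_ascii(path),
         vtp = read_vtp(path),
         stop("unsupported surface format '.", ext, "' (use obj/ply/stl/vtp)"))
}

#' Write a triangulated surface file
#'
#' Format chosen from the extension as in [read_surface()]. Only `vtp` and
#' `ply` carry point-data arrays; writing a mesh with point data to
#' `obj`/`stl` drops the arrays with a warning.
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_surface <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  ext <- tolower(tools::file_ext(path))
  if (length(mesh$point_data) && ext %in% c("obj", "stl")) {
    warning("point-data arrays are not representable in .", ext, "; dropped")
  }
  switch(ext,
         obj = write_obj(mesh, path),
         ply = write_ply(mesh, path),
         stl = write_stl_ascii(mesh, path),
         vtp = write_vtp(mesh, path),
         stop("unsupported surface format '.", ext, "' (use obj/ply/stl/vtp)"))
  invisible(path)
}

num_fmt <- function(x) formatC(x, format = "g", digits = 17)

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v ", lines, value = TRUE)
  nl <- grep("^vn ", lines, value = TRUE)
  fl <- grep("^f ", lines, value = TRUE)
  if (!length(vl) || !length(fl)) stop("malformed OBJ: no vertices or faces in ", path)
  parse3 <- function(x) {
    do.call(rbind, lapply(strsplit(trimws(x), "\\s+"), function(t) as.numeric(t[2:4])))
  }
  verts <- parse3(vl)
  faces <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(t) {
    as.integer(vapply(t[2:4], function(s) strsplit(s, "/")[[1L]][1L], character(1)))
  }))
  normals <- if (length(nl) == length(vl)) {
    n <- parse3(nl)
    n / sqrt(rowSums(n^2))
  } else NULL
  surface_mesh(verts, faces, normals = normals)
}

write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  v <- mesh$vertices; n <- mesh$normals
  writeLines(sprintf("v %s %s %s", num_fmt(v[, 1]), num_fmt(v[, 2]), num_fmt(v[, 3])), con)
  writeLines(sprintf("vn %s %s %s", num_fmt(n[, 1]), num_fmt(n[, 2]), num_fmt(n[, 3])), con)
  f <- mesh$faces
  writeLines(sprintf("f %d//%d %d//%d %d//%d",
                     f[, 1], f[, 1], f[, 2], f[, 2], f[, 3], f[, 3]), con)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  end_h <- match("end_header", trimws(lines))
  if (is.na(end_h)) stop("malformed PLY: no end_header in ", path)
  header <- trimws(lines[seq_len(end_h)])
  if (any(grepl("^format binary", header))) stop("binary PLY not supported; use ascii")
  nv <- as.integer(sub("element vertex ", "", grep("^element vertex ", header, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("^element face ", header, value = TRUE)))
  # vertex property names, in declaration order between the two elements
  vi <- grep("^element vertex ", header)
  fi <- grep("^element face ", header)
  props <- sub("^property \\S+ ", "", grep("^property ", header[(vi + 1L):(fi - 1L)], value = TRUE))
  body <- lines[(end_h + 1L):length(lines)]
  vrows <- do.call(rbind, lapply(strsplit(trimws(body[seq_len(nv)]), "\\s+"), as.numeric))
  colnames(vrows) <- props
  frows <- do.call(rbind, lapply(strsplit(trimws(body[nv + seq_len(nf)]), "\\s+"), as.integer))
  if (any(frows[, 1L] != 3L)) stop("PLY contains non-triangular faces")
  normals <- if (all(c("nx", "ny", "nz") %in% props)) {
    n <- vrows[, c("nx", "ny", "nz"), drop = FALSE]
    n / sqrt(rowSums(n^2))
  } else NULL
  extra <- setdiff(props, c("x", "y", "z", "nx", "ny", "nz"))
  pd <- stats::setNames(lapply(extra, function(p) as.numeric(vrows[, p])), extra)
  surface_mesh(vrows[, c("x", "y", "z"), drop = FALSE], frows[, 2:4] + 1L,
               normals = normals, point_data = pd)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  pd <- mesh$point_data
  writeLines(c("ply", "format ascii 1.0", sprintf("element vertex %d", nv),
               "property double x", "property double y", "property double z",
               "property double nx", "property double ny", "property double nz",
               sprintf("property double %s", names(pd)),
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  vm <- cbind(mesh$vertices, mesh$normals)
  for (nm in names(pd)) vm <- cbind(vm, pd[[nm]])
  writeLines(apply(vm, 1L, function(r) paste(num_fmt(r), collapse = " ")), con)
  f0 <- mesh$faces - 1L
  writeLines(sprintf("3 %d %d %d", f0[, 1], f0[, 2], f0[, 3]), con)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^\\s*solid", lines[1L]))) stop("not an ASCII STL: ", path)
  vlines <- grep("^\\s*vertex ", lines, value = TRUE)
  if (length(vlines) %% 3L != 0L) stop("malformed STL: vertex count not a multiple of 3")
  vm <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"),
                              function(t) as.numeric(t[2:4])))
  key <- apply(vm, 1L, function(r) paste(num_fmt(r), collapse = "_"))
  uid <- !duplicated(key)
  map <- match(key, key[uid])
  faces <- matrix(map, ncol = 3L, byrow = TRUE)
  warning("STL carries no shared vertex set or point data; vertices merged, normals recomputed")
  surface_mesh(vm[uid, , drop = FALSE], faces)
}

write_stl_ascii <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid surface", con)
  f <- mesh$faces
  cr <- face_cross(mesh$vertices, f)
  cr <- cr / sqrt(rowSums(cr^2))
  v <- mesh$vertices
  blocks <- vapply(seq_len(nrow(f)), function(i) {
    paste(sprintf("facet normal %s %s %s", num_fmt(cr[i, 1]), num_fmt(cr[i, 2]), num_fmt(cr[i, 3])),
          "  outer loop",
          sprintf("    vertex %s %s %s", num_fmt(v[f[i, 1], 1]), num_fmt(v[f[i, 1], 2]), num_fmt(v[f[i, 1], 3])),
          sprintf("    vertex %s %s %s", num_fmt(v[f[i, 2], 1]), num_fmt(v[f[i, 2], 2]), num_fmt(v[f[i, 2], 3])),
          sprintf("    vertex %s %s %s", num_fmt(v[f[i, 3], 1]), num_fmt(v[f[i, 3], 2]), num_fmt(v[f[i, 3], 3])),
          "  endloop", "endfacet", sep = "\n")
  }, character(1))
  writeLines(blocks, con)
  writeLines("endsolid surface", con)
}

read_vtp <- function(path) {
  doc <- xml2::read_xml(path)
  piece <- xml2::xml_find_first(doc, ".//Piece")
  if (inherits(piece, "xml_missing")) stop("malformed VTP: no Piece element in ", path)
  get_num <- function(node) as.numeric(strsplit(trimws(xml2::xml_text(node)), "\\s+")[[1L]])
  pts <- get_num(xml2::xml_find_first(piece, ".//Points/DataArray"))
  verts <- matrix(pts, ncol = 3L, byrow = TRUE)
  conn <- as.integer(get_num(xml2::xml_find_first(piece, ".//Polys/DataArray[@Name='connectivity']")))
  offs <- as.integer(get_num(xml2::xml_find_first(piece, ".//Polys/DataArray[@Name='offsets']")))
  if (any(diff(c(0L, offs)) != 3L)) stop("VTP contains non-triangular polys")
  faces <- matrix(conn, ncol = 3L, byrow = TRUE) + 1L
  pd_nodes <- xml2::xml_find_all(piece, ".//PointData/DataArray")
  pd <- list(); normals <- NULL
  for (nd in pd_nodes) {
    nm <- xml2::xml_attr(nd, "Name")
    ncomp <- xml2::xml_attr(nd, "NumberOfComponents")
    vals <- get_num(nd)
    if (!is.na(ncomp) && as.integer(ncomp) == 3L) {
      m <- matrix(vals, ncol = 3L, byrow = TRUE)
      if (identical(nm, "Normals")) normals <- m / sqrt(rowSums(m^2)) else {
        pd[[paste0(nm, "_x")]] <- m[, 1]; pd[[paste0(nm, "_y")]] <- m[, 2]
        pd[[paste0(nm, "_z")]] <- m[, 3]
      }
    } else {
      pd[[nm]] <- vals
    }
  }
  surface_mesh(verts, faces, normals = normals, point_data = pd)
}

write_vtp <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  da <- function(name, values, ncomp = NULL) {
    comp <- if (is.null(ncomp)) "" else sprintf(' NumberOfComponents="%d"', ncomp)
    sprintf('    <DataArray type="Float64" Name="%s"%s format="ascii">\n%s\n    </DataArray>',
            name, comp, paste(num_fmt(values), collapse = " "))
  }
  pd_entries <- c(da("Normals", as.vector(t(mesh$normals)), 3L),
                  vapply(names(mesh$point_data),
                         function(nm) da(nm, mesh$point_data[[nm]]), character(1)))
  xml <- c('<VTKFile type="PolyData" version="1.0" byte_order="LittleEndian">',
           ' <PolyData>',
           sprintf('  <Piece NumberOfPoints="%d" NumberOfVerts="0" NumberOfLines="0" NumberOfStrips="0" NumberOfPolys="%d">', nv, nf),
           '   <PointData>', pd_entries, '   </PointData>',
           '   <Points>',
           da("Points", as.vector(t(mesh$vertices)), 3L),
           '   </Points>',
           '   <Polys>',
           sprintf('    <DataArray type="Int64" Name="connectivity" format="ascii">\n%s\n    </DataArray>',
                   paste(as.vector(t(mesh$faces - 1L)), collapse = " ")),
           sprintf('    <DataArray type="Int64" Name="offsets" format="ascii">\n%s\n    </DataArray>',
                   paste(seq_len(nf) * 3L, collapse = " ")),
           '   </Polys>',
           '  </Piece>',
           ' </PolyData>',
           '</VTKFile>')
  writeLines(xml, path)
}

#' Write / read a WSS vector time series as long-format CSV
#'
#' Columns `vertex_id,t,tx,ty,tz` (vertex id 1-based, t in seconds,
#' components in Pa), sorted by time then vertex; the cycle period is kept
#' in a `# period_s=` comment on the first line.
#'
#' @param field a [wss_field()].
#' @param path file path.
#' @param mesh the [surface_mesh()] the series lives on (for `read`).
#' @param period optional period override when the file has no header.
#' @return `read_wss_series` returns a validated [wss_field()].
#' @export
write_wss_series <- function(field, path) {
  stopifnot(inherits(field, "wss_field"))
  K <- length(field$times); n <- nrow(field$mesh$vertices)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# period_s=%.17g", field$period), con)
  writeLines("vertex_id,t,tx,ty,tz", con)
  for (k in seq_len(K)) {
    writeLines(sprintf("%d,%.17g,%.17g,%.17g,%.17g", seq_len(n), field$times[k],
                       field$vectors[k, , 1L], field$vectors[k, , 2L],
                       field$vectors[k, , 3L]), con)
  }
  invisible(path)
}

#' @rdname write_wss_series
#' @export
read_wss_series <- function(path, mesh, period = NULL) {
  stopifnot(inherits(mesh, "surface_mesh"))
  header <- readLines(path, n = 1L)
  if (grepl("^#", header)) {
    m <- regmatches(header, regexec("period_s=([0-9.eE+-]+)", header))[[1L]]
    if (length(m) == 2L && is.null(period)) period <- as.numeric(m[2L])
  }
  if (is.null(period)) stop("no period_s header in ", path, "; pass period explicitly")
  df <- utils::read.csv(path, comment.char = "#")
  n <- nrow(mesh$vertices)
  times <- sort(unique(df$t))
  K <- length(times)
  if (nrow(df) != K * n) {
    stop(sprintf("series has %d rows; expected K x N = %d x %d for this mesh",
                 nrow(df), K, n))
  }
  df <- df[order(df$t, df$vertex_id), ]
  if (!all(df$vertex_id == rep(seq_len(n), K))) {
    stop("vertex ids do not cover 1..N at every time sample")
  }
  vectors <- array(0, dim = c(K, n, 3L))
  vectors[, , 1L] <- matrix(df$tx, nrow = K, byrow = TRUE)
  vectors[, , 2L] <- matrix(df$ty, nrow = K, byrow = TRUE)
  vectors[, , 3L] <- matrix(df$tz, nrow = K, byrow = TRUE)
  wss_field(mesh, times, period, vectors)
}

#' Write the hemodynamic index bundle as CSV
#'
#' One row per vertex: `vertex_id`, the six indices and the degeneracy
#' flags.
#'
#' @param indices a `hemodynamic_indices` bundle.
#' @param path file path.
#' @export
write_indices_csv <- function(indices, path) {
  utils::write.csv(as.data.frame(indices), path, row.names = FALSE)
  invisible(path)
}
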