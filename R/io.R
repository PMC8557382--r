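#' Read a point cloud from PLY or XYZ
#'
#' Supports ASCII and binary little-endian PLY (vertex properties `x`,
#' `y`, `z` stored as any scalar numeric type) and plain whitespace
#' delimited XYZ text.  In the XYZ dialect the first three columns are
#' x, y, z in metres, extra columns are ignored, and lines starting with
#' `#` are skipped.  Rows with non-finite coordinates are dropped.
#'
#' @param path file path.
#' @param format `"ply"`, `"xyz"` or `"auto"` (by file extension;
#'   anything other than `.ply` is treated as XYZ).
#' @param tree_id identifier for the cloud; defaults to the file stem.
#' @return A [point_cloud()].
#' @export
read_point_cloud <- function(path, format = c("auto", "ply", "xyz"),
                             tree_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  if (is.null(tree_id))
    tree_id <- sub("\\.[^.]*$", "", basename(path))
  pts <- if (format == "ply") read_ply_vertices(path) else read_xyz(path)
  ok <- is.finite(pts[, 1]) & is.finite(pts[, 2]) & is.finite(pts[, 3])
  if (!any(ok)) stop("no finite points in ", path)
  point_cloud(pts[ok, , drop = FALSE], tree_id = tree_id)
}

read_xyz <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop("no data rows in XYZ file ", path)
  tok <- strsplit(lines, "\\s+")
  if (any(lengths(tok) < 3))
    stop("unparseable XYZ file ", path, ": a row has fewer than 3 columns")
  raw <- vapply(tok, function(t) t[1:3], character(3))
  first3 <- suppressWarnings(array(as.numeric(raw), dim(raw)))
  bad <- is.na(first3) & !(toupper(raw) %in% c("NAN", "NA", "INF", "-INF"))
  if (any(bad))
    stop("unparseable XYZ file ", path, ": non-numeric coordinate")
  t(first3)
}

# -- PLY ---------------------------------------------------------------------

ply_type_size <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_what <- function(type) {
  if (type %in% c("float", "float32", "double", "float64")) "double"
  else "integer"
}

parse_ply_header <- function(con) {
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file")
  fmt <- NULL
  elements <- list()
  cur <- NULL
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0) stop("truncated PLY header")
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(tok) == 0 || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      fmt <- tok[2]
    } else if (tok[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property") {
      if (tok[2] == "list") {
        cur$props[[tok[5]]] <- list(name = tok[5], list = TRUE,
                                    count_type = tok[3], value_type = tok[4])
      } else {
        cur$props[[tok[3]]] <- list(name = tok[3], list = FALSE, type = tok[2])
      }
    } else if (tok[1] == "end_header") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      break
    }
  }
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop("unsupported PLY format: ", fmt)
  list(format = fmt, elements = elements)
}

read_ply_vertices <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- parse_ply_header(con)
  vtx <- hdr$elements[["vertex"]]
  if (is.null(vtx)) stop("PLY file has no vertex element: ", path)
  pnames <- names(vtx$props)
  if (!all(c("x", "y", "z") %in% pnames))
    stop("PLY vertex element lacks x/y/z properties: ", path)
  if (hdr$format == "ascii") {
    vals <- scan(con, what = double(), quiet = TRUE)
    # ascii: only scalar vertex properties supported when vertex is first
    if (names(hdr$elements)[1] != "vertex")
      stop("PLY: vertex must be the first element")
    if (any(vapply(vtx$props, `[[`, TRUE, "list")))
      stop("PLY: list-typed vertex properties are not supported")
    np <- length(vtx$props)
    if (length(vals) < np * vtx$count) stop("truncated PLY vertex data")
    block <- matrix(vals[seq_len(np * vtx$count)], ncol = np, byrow = TRUE)
    return(block[, match(c("x", "y", "z"), pnames), drop = FALSE])
  }
  # binary little-endian
  if (names(hdr$elements)[1] != "vertex")
    stop("PLY: vertex must be the first element")
  if (any(vapply(vtx$props, `[[`, TRUE, "list")))
    stop("PLY: list-typed vertex properties are not supported")
  sizes <- vapply(vtx$props, function(p) ply_type_size[[p$type]], 1L)
  rec <- sum(sizes)
  raw <- readBin(con, "raw", n = rec * vtx$count)
  if (length(raw) < rec * vtx$count) stop("truncated PLY vertex data")
  offs <- cumsum(c(0L, sizes))[seq_along(sizes)]
  out <- matrix(0, vtx$count, 3)
  for (k in 1:3) {
    i <- which(pnames == c("x", "y", "z")[k])
    sz <- sizes[i]
    idx <- rep((0:(vtx$count - 1L)) * rec, each = sz) + offs[i] +
      seq_len(sz)
    out[, k] <- readBin(raw[idx], ply_read_what(vtx$props[[i]]$type),
                        n = vtx$count, size = sz, endian = "little",
                        signed = !(sz <= 2 &&
                                   grepl("^u", vtx$props[[i]]$type)))
  }
  out
}

#' Write a point cloud to PLY (ASCII) or XYZ
#'
#' Coordinates are written with 17 significant digits so that an ASCII
#' round trip reproduces the binary double values exactly.
#'
#' @param cloud a [point_cloud()] or n x 3 matrix.
#' @param path output path.
#' @param format `"ply"`, `"xyz"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "ply", "xyz")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.ply$", path, ignore.case = TRUE)) "ply" else "xyz"
  pts <- as_xyz(cloud)
  body <- sprintf("%.17g %.17g %.17g", pts[, 1], pts[, 2], pts[, 3])
  if (format == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(pts)),
             "property double x", "property double y", "property double z",
             "end_header")
    writeLines(c(hdr, body), path)
  } else {
    writeLines(body, path)
  }
  invisible(path)
}

#' Read tree metrics (DBH, height) from CSV
#'
#' The CSV must have columns `tree_id`, `dbh_cm` and `height_m`.
#' Slenderness is always recomputed as `height_m / dbh_cm` (height in
#' metres over diameter in centimetres, giving the conventional
#' 0.4--0.9 range for mature trees); any slenderness column in the file
#' is ignored, since printed values can carry rounding or transcription
#' errors.
#'
#' @param path CSV path.
#' @return A data frame of class `tree_metrics` with columns `tree_id`,
#'   `dbh_cm`, `height_m`, `slenderness`.
#' @export
read_tree_metrics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "dbh_cm", "height_m")
  if (!all(need %in% names(df)))
    stop("tree metrics CSV must have columns ", paste(need, collapse = ", "))
  tree_metrics(df$tree_id, df$dbh_cm, df$height_m)
}

#' Construct tree metrics
#'
#' @param tree_id character vector of identifiers (must be unique).
#' @param dbh_cm diameter at breast height in centimetres.
#' @param height_m total tree height in metres.
#' @return A data frame of class `tree_metrics`.
#' @export
tree_metrics <- function(tree_id, dbh_cm, height_m) {
  tree_id <- as.character(tree_id)
  dbh_cm <- as.numeric(dbh_cm)
  height_m <- as.numeric(height_m)
  if (anyDuplicated(tree_id)) stop("duplicate tree_id")
  if (any(!is.finite(dbh_cm)) || any(dbh_cm <= 0))
    stop("dbh_cm must be positive")
  if (any(!is.finite(height_m)) || any(height_m <= 0))
    stop("height_m must be positive")
  structure(data.frame(tree_id = tree_id, dbh_cm = dbh_cm,
                       height_m = height_m,
                       slenderness = height_m / dbh_cm,
                       stringsAsFactors = FALSE),
            class = c("tree_metrics", "data.frame"))
}

#' Write a triangle mesh to PLY (ASCII) or OBJ
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format `"ply"`, `"obj"` or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj" else "ply"
  if (!inherits(mesh, "triangle_mesh")) stop("'mesh' must be a triangle_mesh")
  if (nrow(mesh$faces) < 1) stop("mesh has no faces")
  v <- mesh$vertices
  f <- mesh$faces
  if (format == "ply") {
    hdr <- c("ply", "format ascii 1.0",
             sprintf("element vertex %d", nrow(v)),
             "property double x", "property double y", "property double z",
             sprintf("element face %d", nrow(f)),
             "property list uchar int vertex_indices",
             "end_header")
    writeLines(c(hdr,
                 sprintf("%.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
                 sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L)),
               path)
  } else {
    writeLines(c(sprintf("v %.17g %.17g %.17g", v[, 1], v[, 2], v[, 3]),
                 sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3])),
               path)
  }
  invisible(path)
}

#' Read a triangle mesh from ASCII PLY or OBJ
#'
#' @param path file path.
#' @param format `"ply"`, `"obj"` or `"auto"` (by extension).
#' @return A [triangle_mesh()].
#' @export
read_mesh <- function(path, format = c("auto", "ply", "obj")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.obj$", path, ignore.case = TRUE)) "obj" else "ply"
  if (format == "obj") {
    lines <- readLines(path)
    vl <- grep("^v ", lines, value = TRUE)
    fl <- grep("^f ", lines, value = TRUE)
    v <- do.call(rbind, lapply(strsplit(vl, "\\s+"), function(t)
      as.numeric(t[2:4])))
    f <- do.call(rbind, lapply(strsplit(fl, "\\s+"), function(t)
      as.integer(sub("/.*$", "", t[2:4]))))
    return(triangle_mesh(v, f))
  }
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- parse_ply_header(con)
  if (hdr$format != "ascii") stop("only ASCII PLY meshes are supported")
  vtx <- hdr$elements[["vertex"]]
  fce <- hdr$elements[["face"]]
  if (is.null(vtx) || is.null(fce)) stop("PLY mesh needs vertex and face elements")
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  vlines <- lines[seq_len(vtx$count)]
  flines <- lines[vtx$count + seq_len(fce$count)]
  v <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), function(t)
    as.numeric(t[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(flines), "\\s+"), function(t) {
    k <- as.integer(t[1])
    if (k != 3) stop("only triangular faces are supported")
    as.integer(t[2:4]) + 1L
  }))
  triangle_mesh(v, f)
}
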