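# Readers and writers for the standard point-cloud/mesh formats: OFF
# (triangle meshes, both header dialects), PLY (ASCII and binary little
# endian, with an optional per-vertex integer part property), plain-text XYZ,
# one-integer-per-line .seg part labels, and JSON dataset manifests.
# Readers validate and reject malformed inputs rather than repairing them.

#' Triangle mesh container
#' @param vertices numeric V x 3 matrix.
#' @param faces integer F x 3 matrix of 0-based vertex indices.
#' @return A `mesh` object.
#' @export
mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  stop_if_not_matrix3(vertices, "vertices")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("faces must have 3 columns", call. = FALSE)
  if (nrow(faces) && (min(faces) < 0L || max(faces) >= nrow(vertices))) {
    stop("face indices out of range [0, V)", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "mesh")
}

#' Read / write OFF meshes
#'
#' Accepts both common OFF header dialects: counts on the line after the
#' `OFF` sentinel, and counts on the sentinel line itself (`OFF 4 4 0`).
#' Degenerate (zero-area) faces are dropped at load time. Parse errors name
#' the offending line.
#'
#' @param path file path.
#' @return `read_off` returns a `mesh`.
#' @export
read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines_trim <- trimws(lines)
  keep <- which(nzchar(lines_trim) & !startsWith(lines_trim, "#"))
  if (!length(keep)) stop("empty OFF file: ", path, call. = FALSE)
  first <- lines_trim[keep[1]]
  if (!startsWith(first, "OFF")) {
    stop(sprintf("%s: line %d: missing OFF sentinel", path, keep[1]),
         call. = FALSE)
  }
  rest <- trimws(sub("^OFF", "", first))
  if (nzchar(rest)) {
    counts <- suppressWarnings(as.integer(strsplit(rest, "\\s+")[[1]]))
    body_at <- 2L
  } else {
    if (length(keep) < 2L) {
      stop(sprintf("%s: missing counts line", path), call. = FALSE)
    }
    counts <- suppressWarnings(
      as.integer(strsplit(lines_trim[keep[2]], "\\s+")[[1]]))
    body_at <- 3L
  }
  if (length(counts) < 2L || anyNA(counts[1:2])) {
    stop(sprintf("%s: line %d: malformed counts line", path,
                 keep[min(body_at - 1L, length(keep))]), call. = FALSE)
  }
  nv <- counts[1]; nf <- counts[2]
  body <- keep[body_at:length(keep)]
  if (length(body) < nv + nf) {
    stop(sprintf("%s: expected %d vertex + %d face lines, found %d", path,
                 nv, nf, length(body)), call. = FALSE)
  }
  vl <- lines_trim[body[seq_len(nv)]]
  verts <- matrix(suppressWarnings(
    as.numeric(unlist(strsplit(vl, "\\s+")))), ncol = 3, byrow = TRUE)
  if (anyNA(verts)) {
    bad <- which(is.na(rowSums(verts)))[1]
    stop(sprintf("%s: line %d: malformed vertex", path, body[bad]),
         call. = FALSE)
  }
  faces <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    ln <- body[nv + i]
    toks <- suppressWarnings(as.integer(strsplit(lines_trim[ln], "\\s+")[[1]]))
    if (anyNA(toks) || length(toks) < 1L || toks[1] != 3L ||
        length(toks) < 4L) {
      stop(sprintf("%s: line %d: only triangular faces are supported", path,
                   ln), call. = FALSE)
    }
    idx <- toks[2:4]
    if (any(idx < 0L) || any(idx >= nv)) {
      stop(sprintf("%s: line %d: face index out of range [0, %d)", path, ln,
                   nv), call. = FALSE)
    }
    faces[i, ] <- idx
  }
  m <- mesh(verts, faces)
  areas <- triangle_areas(m)
  if (any(areas <= 1e-14)) {
    m$faces <- m$faces[areas > 1e-14, , drop = FALSE]
  }
  m
}

#' @rdname read_off
#' @param m a `mesh`.
#' @export
write_off <- function(m, path) {
  stopifnot(inherits(m, "mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(m$vertices), nrow(m$faces)), con)
  writeLines(apply(m$vertices, 1, function(v)
    paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
          collapse = " ")), con)
  if (nrow(m$faces)) {
    writeLines(paste("3", m$faces[, 1], m$faces[, 2], m$faces[, 3]), con)
  }
  invisible(path)
}

#' Triangle areas of a mesh
#' @param m a `mesh`.
#' @return numeric vector of face areas.
#' @export
triangle_areas <- function(m) {
  if (!nrow(m$faces)) return(numeric(0))
  a <- m$vertices[m$faces[, 1] + 1L, , drop = FALSE]
  b <- m$vertices[m$faces[, 2] + 1L, , drop = FALSE]
  cc <- m$vertices[m$faces[, 3] + 1L, , drop = FALSE]
  u <- b - a; v <- cc - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

#' Sample points uniformly from a mesh surface
#'
#' Triangles are selected with probability proportional to their area, then
#' points are placed by uniform barycentric sampling. Deterministic given
#' `seed`.
#'
#' @param m a `mesh` with at least one non-degenerate triangle.
#' @param n_points number of points.
#' @param seed RNG seed.
#' @param category,instance_id metadata for the resulting cloud.
#' @return A `point_cloud` (not normalized).
#' @export
sample_mesh_surface <- function(m, n_points, seed, category = NA_character_,
                                instance_id = NA_character_) {
  stopifnot(inherits(m, "mesh"), n_points >= 1)
  areas <- triangle_areas(m)
  if (!length(areas) || sum(areas) <= 0) {
    stop("mesh has zero total surface area", call. = FALSE)
  }
  with_seed(seed, {
    tri <- sample.int(length(areas), n_points, replace = TRUE, prob = areas)
    r1 <- sqrt(runif(n_points)); r2 <- runif(n_points)
    a <- m$vertices[m$faces[tri, 1] + 1L, , drop = FALSE]
    b <- m$vertices[m$faces[tri, 2] + 1L, , drop = FALSE]
    cc <- m$vertices[m$faces[tri, 3] + 1L, , drop = FALSE]
    pts <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * cc
    point_cloud(pts, category = category, instance_id = instance_id)
  })
}

#' Read / write point clouds as PLY
#'
#' ASCII (default) or binary little-endian PLY with float vertex properties
#' x, y, z and, when part labels are present, an integer `part` property.
#' Round trips are lossless for ASCII (full precision) and within float32
#' precision for binary.
#'
#' @param pc a `point_cloud`.
#' @param path file path.
#' @param format "ascii" or "binary" (binary little-endian).
#' @export
write_ply <- function(pc, path, format = c("ascii", "binary")) {
  stopifnot(inherits(pc, "point_cloud"))
  format <- match.arg(format)
  n <- n_points(pc)
  has_part <- !is.null(pc$part_labels)
  hdr <- c("ply",
           if (format == "ascii") "format ascii 1.0"
           else "format binary_little_endian 1.0",
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z",
           if (has_part) "property int part",
           "end_header")
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    co <- format(pc$coords, digits = 17, scientific = FALSE, trim = TRUE)
    lines <- paste(co[, 1], co[, 2], co[, 3])
    if (has_part) lines <- paste(lines, pc$part_labels)
    writeLines(lines, con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con)
    for (i in seq_len(n)) {
      writeBin(as.numeric(pc$coords[i, ]), con, size = 8, endian = "little")
      if (has_part) {
        writeBin(as.integer(pc$part_labels[i]), con, size = 4,
                 endian = "little")
      }
    }
  }
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln)) stop(path, ": truncated PLY header", call. = FALSE)
    hdr <- c(hdr, ln)
    if (trimws(ln) == "end_header") break
    if (length(hdr) > 100) stop(path, ": header too long", call. = FALSE)
  }
  if (hdr[1] != "ply") stop(path, ": missing ply sentinel", call. = FALSE)
  fmt <- grep("^format", hdr, value = TRUE)
  binary <- grepl("binary_little_endian", fmt)
  n <- as.integer(sub("element vertex ", "",
                      grep("^element vertex", hdr, value = TRUE)))
  if (is.na(n)) stop(path, ": missing vertex element", call. = FALSE)
  props <- sub("^property\\s+\\S+\\s+", "", grep("^property", hdr, value = TRUE))
  ptypes <- sub("^property\\s+(\\S+).*$", "\\1", grep("^property", hdr, value = TRUE))
  if (!identical(props[1:3], c("x", "y", "z"))) {
    stop(path, ": expected x y z as the first vertex properties",
         call. = FALSE)
  }
  has_part <- length(props) >= 4 && props[4] == "part"
  if (binary) {
    coords <- matrix(0, n, 3)
    part <- if (has_part) integer(n) else NULL
    sz <- function(tp) if (tp %in% c("double", "float64")) 8 else 4
    for (i in seq_len(n)) {
      coords[i, ] <- readBin(con, "double", 3, size = sz(ptypes[1]),
                             endian = "little")
      if (has_part) {
        part[i] <- readBin(con, "integer", 1, size = 4, endian = "little")
      }
    }
  } else {
    txt <- readLines(con)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < n) stop(path, ": fewer vertex lines than declared",
                              call. = FALSE)
    toks <- strsplit(trimws(txt[seq_len(n)]), "\\s+")
    ncols <- 3L + has_part
    if (any(lengths(toks) < ncols)) {
      stop(path, ": malformed vertex line", call. = FALSE)
    }
    vals <- matrix(as.numeric(unlist(lapply(toks, `[`, seq_len(ncols)))),
                   ncol = ncols, byrow = TRUE)
    if (anyNA(vals)) stop(path, ": non-numeric vertex data", call. = FALSE)
    coords <- vals[, 1:3, drop = FALSE]
    part <- if (has_part) as.integer(vals[, 4]) else NULL
  }
  point_cloud(coords, part_labels = part)
}

#' Read / write plain-text XYZ point clouds
#' @param pc a `point_cloud`.
#' @param path file path.
#' @export
write_xyz <- function(pc, path) {
  stopifnot(inherits(pc, "point_cloud"))
  co <- format(pc$coords, digits = 17, scientific = FALSE, trim = TRUE)
  writeLines(paste(co[, 1], co[, 2], co[, 3]), path)
  invisible(path)
}

#' @rdname write_xyz
#' @export
read_xyz <- function(path) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  toks <- strsplit(trimws(txt), "\\s+")
  if (any(lengths(toks) != 3L)) {
    stop(path, ": every line must have exactly 3 coordinates", call. = FALSE)
  }
  vals <- matrix(as.numeric(unlist(toks)), ncol = 3, byrow = TRUE)
  if (anyNA(vals)) stop(path, ": non-numeric coordinates", call. = FALSE)
  point_cloud(vals)
}

#' Read / write per-point part labels (.seg convention)
#'
#' One integer per line, one line per point. `read_seg_labels` can check the
#' expected length against a cloud.
#'
#' @param labels integer vector.
#' @param path file path.
#' @param expected_n optional expected number of labels; a mismatch is an
#'   error.
#' @export
write_seg_labels <- function(labels, path) {
  writeLines(as.character(as.integer(labels)), path)
  invisible(path)
}

#' @rdname write_seg_labels
#' @export
read_seg_labels <- function(path, expected_n = NULL) {
  txt <- readLines(path, warn = FALSE)
  txt <- txt[nzchar(trimws(txt))]
  labels <- suppressWarnings(as.integer(txt))
  if (anyNA(labels)) stop(path, ": non-integer label line", call. = FALSE)
  if (!is.null(expected_n) && length(labels) != expected_n) {
    stop(sprintf("%s: %d labels but cloud has %d points", path,
                 length(labels), expected_n), call. = FALSE)
  }
  labels
}

#' Read / write dataset manifests as JSON
#'
#' The manifest records every instance (id, category, split, seed, file
#' paths) together with the generator configuration. `read_manifest` checks
#' that instance ids are unique and that referenced files exist.
#'
#' @param dataset a `shape_dataset` (or a list with `manifest` and `config`).
#' @param path file path.
#' @export
write_manifest <- function(dataset, path) {
  obj <- list(records = dataset$manifest, metadata = dataset$config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @param check_files whether to require referenced files to exist.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  records <- as.data.frame(obj$records, stringsAsFactors = FALSE)
  if (anyDuplicated(records$instance_id)) {
    stop(path, ": duplicate instance ids in manifest", call. = FALSE)
  }
  if (check_files && !is.null(records$cloud_path) &&
      !all(is.na(records$cloud_path))) {
    missing <- records$cloud_path[!is.na(records$cloud_path) &
                                    !file.exists(records$cloud_path)]
    if (length(missing)) {
      stop(path, ": missing referenced files: ",
           paste(utils::head(missing, 3), collapse = ", "), call. = FALSE)
    }
  }
  list(manifest = records, config = obj$metadata)
}
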