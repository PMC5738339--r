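# FreeSurfer surface / curv / label I/O with plain-text fallbacks.
#
# Binary formats are big-endian. Surfaces carry magic 0xFFFFFE, per-vertex
# morph ("curv") files magic 0xFFFFFF, each packed in 3 bytes. Faces and
# label indices are 0-based on disk and converted to R's 1-based indexing
# on read. All readers accept gzip-compressed files transparently.

SURF_MAGIC <- 16777214L  # 0xFFFFFE
CURV_MAGIC <- 16777215L  # 0xFFFFFF

read_int3 <- function(con) {
  b <- readBin(con, "integer", n = 3L, size = 1L, signed = FALSE)
  if (length(b) < 3L) lsctp_abort("truncated file: no 3-byte magic", "lsctp_length_error")
  b[1L] * 65536L + b[2L] * 256L + b[3L]
}

write_int3 <- function(con, x) {
  writeBin(as.integer(c(x %/% 65536L, (x %/% 256L) %% 256L, x %% 256L)),
           con, size = 1L)
}

# Read bytes until the "\n\n" terminator of a FreeSurfer creation comment.
read_fs_comment <- function(con) {
  bytes <- raw(0)
  prev_nl <- FALSE
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (length(b) == 0L) lsctp_abort("truncated file in header comment", "lsctp_length_error")
    if (b == as.raw(10L)) {
      if (prev_nl) break
      prev_nl <- TRUE
    } else {
      prev_nl <- FALSE
      bytes <- c(bytes, b)
    }
  }
  rawToChar(bytes)
}

is_ascii_file <- function(path, marker) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  head <- readBin(con, "raw", n = nchar(marker))
  length(head) == nchar(marker) && rawToChar(head) == marker
}

#' Read a surface mesh
#'
#' Reads a FreeSurfer binary triangle surface (magic `0xFFFFFE`) or, as a
#' plain-text fallback, a FreeSurfer ASCII surface (first line `#!ascii`,
#' then a vertex/face count line, vertex rows `x y z 0` and face rows with
#' 0-based indices). Gzipped files are accepted.
#'
#' @param path file path.
#' @param name mesh name; defaults to the file stem.
#' @return an [triangle_mesh()] object.
#' @export
read_surface <- function(path, name = NULL) {
  if (!file.exists(path)) lsctp_abort(sprintf("no such file: %s", path), "lsctp_io_error")
  name <- name %||% sub("\\.gz$", "", basename(path))
  if (is_ascii_file(path, "#!ascii")) {
    return(read_surface_ascii(path, name))
  }
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- read_int3(con)
  if (magic != SURF_MAGIC) {
    lsctp_abort(sprintf(
      "not a triangle surface: magic 0x%06X (expected 0x%06X)", magic, SURF_MAGIC
    ), "lsctp_format_error")
  }
  read_fs_comment(con)
  counts <- readBin(con, "integer", n = 2L, size = 4L, endian = "big")
  if (length(counts) < 2L) lsctp_abort("truncated surface header", "lsctp_length_error")
  nv <- counts[1L]; nf <- counts[2L]
  coords <- readBin(con, "double", n = 3L * nv, size = 4L, endian = "big")
  if (length(coords) < 3L * nv) {
    lsctp_abort(sprintf("truncated surface: %d of %d coordinates", length(coords), 3L * nv),
                "lsctp_length_error")
  }
  faces <- readBin(con, "integer", n = 3L * nf, size = 4L, endian = "big")
  if (length(faces) < 3L * nf) {
    lsctp_abort(sprintf("truncated surface: %d of %d face indices", length(faces), 3L * nf),
                "lsctp_length_error")
  }
  triangle_mesh(
    matrix(coords, ncol = 3L, byrow = TRUE),
    matrix(faces, ncol = 3L, byrow = TRUE) + 1L,
    name = name
  )
}

read_surface_ascii <- function(path, name) {
  lines <- readLines(gzfile(path))
  lines <- lines[nzchar(trimws(lines))]
  counts <- scan(text = lines[2L], quiet = TRUE)
  nv <- counts[1L]; nf <- counts[2L]
  if (length(lines) < 2L + nv + nf) lsctp_abort("truncated ASCII surface", "lsctp_length_error")
  vdat <- scan(text = lines[2L + seq_len(nv)], quiet = TRUE)
  fdat <- scan(text = lines[2L + nv + seq_len(nf)], quiet = TRUE)
  v <- matrix(vdat, ncol = 4L, byrow = TRUE)[, 1:3, drop = FALSE]
  f <- matrix(fdat, ncol = 4L, byrow = TRUE)[, 1:3, drop = FALSE] + 1L
  triangle_mesh(v, f, name = name)
}

#' Write a surface mesh in FreeSurfer binary triangle format
#'
#' @param mesh an `lsctp_mesh`.
#' @param path output path (gzip applied when it ends in `.gz`).
#' @export
write_surface <- function(mesh, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  write_int3(con, SURF_MAGIC)
  writeChar("created by lsctp\n\n", con, eos = NULL)
  writeBin(c(nrow(mesh$vertices), nrow(mesh$faces)), con, size = 4L, endian = "big")
  writeBin(as.double(t(mesh$vertices)), con, size = 4L, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read a per-vertex scalar map
#'
#' Reads a FreeSurfer new-format curv/morph file (magic `0xFFFFFF`,
#' float32 values) or a plain-text fallback of one value per line with
#' optional `#` comment lines. Gzipped files are accepted.
#'
#' @param path file path.
#' @return numeric vector of per-vertex values, with attribute `subject_id`
#'   (the file stem).
#' @export
read_morph <- function(path) {
  if (!file.exists(path)) lsctp_abort(sprintf("no such file: %s", path), "lsctp_io_error")
  sid <- sub("\\.[^.]*$", "", sub("\\.gz$", "", basename(path)))
  con <- gzfile(path, "rb")
  head <- readBin(con, "raw", n = 3L)
  close(con)
  binary <- length(head) == 3L && all(head == as.raw(255L))
  if (binary) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    read_int3(con)
    hdr <- readBin(con, "integer", n = 3L, size = 4L, endian = "big")
    if (length(hdr) < 3L) lsctp_abort("truncated curv header", "lsctp_length_error")
    nv <- hdr[1L]
    vals <- readBin(con, "double", n = nv, size = 4L, endian = "big")
    if (length(vals) < nv) {
      lsctp_abort(sprintf("truncated curv: %d of %d values", length(vals), nv),
                  "lsctp_length_error")
    }
  } else {
    lines <- readLines(gzfile(path))
    lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    vals <- as.double(lines)
    if (anyNA(vals)) lsctp_abort("non-numeric line in plain morph file", "lsctp_format_error")
  }
  if (any(!is.finite(vals))) lsctp_abort("non-finite vertex value", "lsctp_invariant_error")
  structure(vals, subject_id = sid)
}

#' Write a per-vertex scalar map in FreeSurfer curv format
#'
#' @param values numeric vector, one value per vertex.
#' @param path output path (gzip applied when it ends in `.gz`).
#' @param n_faces face count recorded in the header (informational).
#' @export
write_morph <- function(values, path, n_faces = 0L) {
  if (any(!is.finite(values))) lsctp_abort("non-finite vertex value", "lsctp_invariant_error")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  write_int3(con, CURV_MAGIC)
  writeBin(c(length(values), as.integer(n_faces), 1L), con, size = 4L, endian = "big")
  writeBin(as.double(values), con, size = 4L, endian = "big")
  invisible(path)
}

#' Read a vertex mask from a label file
#'
#' Accepts a FreeSurfer ASCII label (header line starting `#!ascii`, count
#' line, then `vertex x y z stat` rows with 0-based vertex numbers) or a
#' plain index list: one 0-based vertex index per line, `#` comment lines
#' ignored. Both dialects are 0-based on disk.
#'
#' @param path file path.
#' @param n_vertices vertex count of the target mesh.
#' @param label mask name; defaults to the file stem.
#' @return logical vector of length `n_vertices` with attribute `label`.
#' @export
read_label <- function(path, n_vertices, label = NULL) {
  if (!file.exists(path)) lsctp_abort(sprintf("no such file: %s", path), "lsctp_io_error")
  label <- label %||% sub("\\.[^.]*$", "", sub("\\.gz$", "", basename(path)))
  lines <- readLines(gzfile(path))
  if (length(lines) > 0L && grepl("^#!ascii", lines[1L])) {
    n <- as.integer(trimws(lines[2L]))
    idx0 <- if (n > 0L) {
      vapply(strsplit(trimws(lines[2L + seq_len(n)]), "\\s+"),
             function(x) as.double(x[1L]), numeric(1))
    } else numeric(0)
  } else {
    keep <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
    idx0 <- as.double(keep)
    if (anyNA(idx0)) lsctp_abort("non-numeric line in plain label file", "lsctp_format_error")
  }
  if (any(idx0 < 0) || any(idx0 >= n_vertices)) {
    lsctp_abort(sprintf(
      "label index out of range for %d-vertex mesh (max listed: %g)",
      n_vertices, if (length(idx0)) max(idx0) else NA_real_
    ), "lsctp_bounds_error")
  }
  mask <- rep(FALSE, n_vertices)
  mask[as.integer(idx0) + 1L] <- TRUE
  structure(mask, label = label)
}

#' Write a vertex mask as a FreeSurfer ASCII label
#'
#' @param mask logical vector over vertices.
#' @param path output path.
#' @param mesh optional mesh supplying coordinates for the label rows;
#'   zeros are written when absent.
#' @export
write_label <- function(mask, path, mesh = NULL) {
  idx <- which(mask)
  coords <- if (!is.null(mesh)) mesh$vertices[idx, , drop = FALSE] else
    matrix(0, nrow = length(idx), ncol = 3L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#!ascii label, written by lsctp (0-based vertex indices)", con)
  writeLines(as.character(length(idx)), con)
  if (length(idx)) {
    writeLines(sprintf("%d  %.6f  %.6f  %.6f  0.000000",
                       idx - 1L, coords[, 1L], coords[, 2L], coords[, 3L]), con)
  }
  invisible(path)
}

#' Assemble a cohort thickness matrix
#'
#' @param matrix subjects x vertices numeric matrix, thickness in mm.
#'   Zero encodes "no cortex here" (medial wall); negative values and NaN
#'   are invariant violations, not missingness.
#' @param subject_ids character vector, one id per row.
#' @return the validated matrix with class `cohort_thickness` and row names
#'   set to the subject ids.
#' @export
cohort_thickness <- function(matrix, subject_ids = NULL) {
  m <- as.matrix(matrix)
  storage.mode(m) <- "double"
  subject_ids <- subject_ids %||% rownames(m) %||% sprintf("subject%02d", seq_len(nrow(m)))
  if (nrow(m) < 2L) lsctp_abort("a cohort needs at least 2 subjects", "lsctp_invariant_error")
  if (length(subject_ids) != nrow(m)) {
    lsctp_abort("one subject id per row required", "lsctp_dimension_error")
  }
  if (any(!is.finite(m))) lsctp_abort("non-finite thickness value", "lsctp_invariant_error")
  bad <- which(m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    lsctp_abort(sprintf(
      "negative thickness for subject '%s' at vertex %d",
      subject_ids[bad[1L, 1L]], bad[1L, 2L]
    ), "lsctp_invariant_error")
  }
  colnames(m) <- NULL
  rownames(m) <- unname(subject_ids)
  class(m) <- c("cohort_thickness", class(m))
  m
}

#' Load a cohort from per-subject morph files
#'
#' @param paths character vector of at least two morph files, each holding
#'   one thickness value per mesh vertex. Row order follows `paths`.
#' @param mesh the shared reference mesh.
#' @param subject_ids optional ids; defaults to the file stems.
#' @return a [cohort_thickness()] matrix.
#' @export
load_cohort <- function(paths, mesh, subject_ids = NULL) {
  if (length(paths) < 2L) lsctp_abort("a cohort needs at least 2 subjects", "lsctp_invariant_error")
  nv <- n_vertices(mesh)
  maps <- lapply(paths, read_morph)
  lens <- lengths(maps)
  if (any(lens != nv)) {
    i <- which(lens != nv)[1L]
    lsctp_abort(sprintf(
      "'%s' has %d values but mesh '%s' has %d vertices",
      basename(paths[i]), lens[i], mesh$name, nv
    ), "lsctp_dimension_error")
  }
  ids <- subject_ids %||% vapply(maps, attr, character(1), "subject_id")
  cohort_thickness(do.call(rbind, maps), subject_ids = ids)
}

#' Write / read a cohort as a plain TSV matrix
#'
#' Tab-separated subjects x vertices matrix: one header line naming the
#' columns (`subject`, then `v0`, `v1`, ... in 0-based vertex order), one
#' row per subject.
#'
#' @param cohort a [cohort_thickness()] matrix.
#' @param path file path.
#' @export
write_cohort_tsv <- function(cohort, path) {
  df <- data.frame(subject = rownames(cohort), unclass(cohort), check.names = FALSE)
  colnames(df) <- c("subject", sprintf("v%d", seq_len(ncol(cohort)) - 1L))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  cohort_thickness(as.matrix(df[, -1L, drop = FALSE]), subject_ids = df[[1L]])
}
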