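#' Read and write fiducial point sets
#'
#' Two dialects are supported: plain CSV with columns `label,x,y,z`, and
#' the 3D Slicer markups fiducial format (FCSV; first line
#' `# Markups fiducial file version = ...`). FCSV files declaring an LPS
#' coordinate system have `x` and `y` negated on read so the returned set
#' is always RAS. Malformed rows are reported with their line number;
#' duplicate labels and empty files are errors.
#'
#' @param path File path.
#' @param dialect `"auto"` (from the header/extension), `"csv"` or
#'   `"fcsv"`.
#' @param frame,units,role Tags for the returned [fiducial_set()].
#' @return `read_fiducials()` returns a [fiducial_set()] (RAS);
#'   `write_fiducials()` the path, invisibly.
#' @examples
#' fcsv <- system.file("extdata", "example_markers_lps.fcsv",
#'                     package = "phantomreg")
#' read_fiducials(fcsv)  # LPS input, returned in RAS
#' @export
read_fiducials <- function(path, dialect = c("auto", "csv", "fcsv"),
                           frame = "RICS", units = "mm", role = "C") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(paste0("empty fiducial file: ", path))
  if (dialect == "auto") {
    dialect <- if (grepl("^# Markups fiducial file version", lines[1]) ||
                   tolower(tools::file_ext(path)) == "fcsv") "fcsv"
               else "csv"
  }
  if (dialect == "fcsv") {
    lps <- any(grepl("coordinatesystem\\s*[:=]\\s*(lps|1)\\s*$",
                     tolower(lines[startsWith(lines, "#")])))
    data_lines <- which(!startsWith(lines, "#"))
    if (length(data_lines) == 0) abort("FCSV file contains no points")
    rows <- purrr::map_dfr(data_lines, function(i) {
      f <- strsplit(lines[i], ",")[[1]]
      xyz <- suppressWarnings(as.numeric(f[2:4]))
      if (length(f) < 4 || anyNA(xyz)) {
        abort(sprintf("malformed FCSV row at line %d of %s", i, path))
      }
      label <- if (length(f) >= 12 && nzchar(f[12])) f[12] else f[1]
      tibble(label = label, x = xyz[1], y = xyz[2], z = xyz[3])
    })
    if (lps) {
      rows$x <- -rows$x
      rows$y <- -rows$y
    }
  } else {
    header <- strsplit(lines[1], ",")[[1]]
    cols <- match(c("label", "x", "y", "z"), trimws(tolower(header)))
    if (anyNA(cols)) abort(paste0("CSV header must name label,x,y,z: ", path))
    if (length(lines) < 2) abort(paste0("CSV has a header but no rows: ", path))
    rows <- purrr::map_dfr(2:length(lines), function(i) {
      f <- trimws(strsplit(lines[i], ",")[[1]])
      xyz <- suppressWarnings(as.numeric(f[cols[2:4]]))
      if (length(f) < max(cols) || anyNA(xyz)) {
        abort(sprintf("malformed CSV row at line %d of %s", i, path))
      }
      tibble(label = f[cols[1]], x = xyz[1], y = xyz[2], z = xyz[3])
    })
  }
  if (anyDuplicated(rows$label)) {
    abort(paste0("duplicate fiducial labels in ", path))
  }
  fiducial_set(rows, frame = frame, units = units, role = role)
}

#' @rdname read_fiducials
#' @param fs A [fiducial_set()] to write.
#' @export
write_fiducials <- function(fs, path, dialect = c("auto", "csv", "fcsv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(fs, "fiducial_set"))
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) == "fcsv") "fcsv" else "csv"
  }
  if (dialect == "fcsv") {
    lines <- c(
      "# Markups fiducial file version = 4.11",
      "# CoordinateSystem = RAS",
      "# columns = id,x,y,z,ow,ox,oy,oz,vis,sel,lock,label,desc,associatedNodeID",
      sprintf("vtkMRMLMarkupsFiducialNode_%d,%.9g,%.9g,%.9g,0,0,0,1,1,1,0,%s,,",
              seq_len(nrow(fs)), fs$x, fs$y, fs$z, fs$label))
    writeLines(lines, path)
  } else {
    readr::write_csv(tibble(label = fs$label, x = fs$x, y = fs$y, z = fs$z),
                     path)
  }
  invisible(path)
}

#' Read and write frame transforms
#'
#' A transform is stored as a plain-text 4x4 row-major matrix with a JSON
#' sidecar (`<path>.json`) recording source/target frames, units and the
#' position label.
#'
#' @param transform A [frame_transform()].
#' @param path Path of the matrix text file.
#' @return `read_transform()` returns a [frame_transform()];
#'   `write_transform()` the path, invisibly.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "frame_transform"))
  writeLines(apply(transform$matrix, 1, function(r)
    paste(sprintf("%.17g", r), collapse = " ")), path)
  meta <- list(source_frame = transform$source_frame,
               target_frame = transform$target_frame,
               unit_in = transform$unit_in, unit_out = transform$unit_out,
               position = transform$position)
  jsonlite::write_json(meta[!vapply(meta, is.null, TRUE)],
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  rows <- strsplit(trimws(readLines(path, warn = FALSE)), "\\s+")
  rows <- rows[lengths(rows) > 0]
  if (length(rows) != 4 || any(lengths(rows) != 4)) {
    abort(paste0("transform file is not a 4x4 matrix: ", path))
  }
  m <- do.call(rbind, lapply(rows, as.numeric))
  sidecar <- paste0(path, ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  frame_transform(m,
                  source_frame = meta$source_frame %||% "RICS",
                  target_frame = meta$target_frame %||% "RICS",
                  unit_in = meta$unit_in %||% "mm",
                  unit_out = meta$unit_out %||% "mm",
                  position = meta$position)
}

#' Read and write lesion masks (NIfTI, ASCII NRRD)
#'
#' NIfTI files are handled through RNifti; the grid geometry (spacing,
#' origin, direction) is taken from/encoded in the qform, with NIfTI's
#' native RAS convention kept as-is. NRRD support is a minimal
#' text-encoding subset written for mask interchange: 3-D, `encoding:
#' ascii`, RAS space; raw or gzip encodings are rejected with a clear
#' error.
#'
#' @param lesion A [lesion_model()].
#' @param path File path (`.nii`, `.nii.gz` or `.nrrd`).
#' @return `read_lesion()` returns a [lesion_model()]; `write_lesion()`
#'   the path, invisibly.
#' @export
write_lesion <- function(lesion, path) {
  stopifnot(inherits(lesion, "lesion_model"))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    d <- dim(lesion$mask)
    dirs <- lesion$direction %*% diag(lesion$spacing)
    header <- c(
      "NRRD0004",
      "# binary lesion mask",
      "type: unsigned char",
      "dimension: 3",
      "space: right-anterior-superior",
      paste0("sizes: ", paste(d, collapse = " ")),
      paste0("space directions: ",
             paste(apply(dirs, 2, function(v)
               sprintf("(%.9g,%.9g,%.9g)", v[1], v[2], v[3])),
               collapse = " ")),
      "kinds: domain domain domain",
      "endian: little",
      "encoding: ascii",
      sprintf("space origin: (%.9g,%.9g,%.9g)", lesion$origin[1],
              lesion$origin[2], lesion$origin[3]),
      "")
    values <- as.integer(lesion$mask)  # column-major = fastest-first axis
    writeLines(c(header,
                 vapply(split(values, ceiling(seq_along(values) / 400)),
                        paste, "", collapse = " ")),
               path)
  } else {
    img <- RNifti::asNifti(array(as.integer(lesion$mask),
                                 dim = dim(lesion$mask)))
    affine <- rbind(cbind(lesion$direction %*% diag(lesion$spacing),
                          lesion$origin),
                    c(0, 0, 0, 1))
    # the sform stores the affine verbatim (the qform would re-derive
    # spacing from pixdim and lose anisotropy)
    img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

#' @rdname write_lesion
#' @export
read_lesion <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    blank <- which(!nzchar(trimws(lines)))[1]
    if (is.na(blank)) abort("NRRD header not terminated by a blank line")
    header <- lines[seq_len(blank - 1)]
    field <- function(name) {
      ln <- grep(paste0("^", name, ":"), header, value = TRUE)
      if (length(ln) == 0) return(NULL)
      trimws(sub(paste0("^", name, ":"), "", ln[1]))
    }
    enc <- field("encoding")
    if (is.null(enc) || !enc %in% c("ascii", "text", "txt")) {
      abort(paste0("only ASCII-encoded NRRD is supported, got encoding: ",
                   enc %||% "<missing>"))
    }
    sizes <- as.integer(strsplit(field("sizes"), "\\s+")[[1]])
    if (length(sizes) != 3) abort("only 3-D NRRD masks are supported")
    parse_vec <- function(s) as.numeric(strsplit(gsub("[()]", "", s),
                                                 ",")[[1]])
    dir_str <- regmatches(field("space directions"),
                          gregexpr("\\([^)]*\\)",
                                   field("space directions")))[[1]]
    dirs <- vapply(dir_str, parse_vec, numeric(3))
    spacing <- sqrt(colSums(dirs^2))
    direction <- sweep(dirs, 2, spacing, `/`)
    dimnames(direction) <- NULL
    origin <- parse_vec(field("space origin") %||% "(0,0,0)")
    values <- as.integer(scan(text = paste(lines[-seq_len(blank)],
                                           collapse = " "),
                              quiet = TRUE))
    if (length(values) != prod(sizes)) {
      abort("NRRD data length does not match sizes")
    }
    lesion_model(array(values, dim = sizes), spacing = spacing,
                 origin = origin, direction = direction)
  } else {
    img <- RNifti::readNifti(path)
    affine <- RNifti::xform(img)
    lin <- affine[1:3, 1:3]
    spacing <- sqrt(colSums(lin^2))
    lesion_model(array(as.logical(img), dim = dim(img)),
                 spacing = spacing,
                 origin = affine[1:3, 4],
                 direction = sweep(lin, 2, spacing, `/`))
  }
}
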