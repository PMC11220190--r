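# Hyperspectral cube, label mask, and manifest I/O.
#
# Canonical in-memory layout is an H x W x C array (rows = image lines,
# columns = samples, slices = spectral bands), 0-based pixel coordinates,
# origin top-left. Two on-disk dialects are supported: ENVI header + raw
# (interleaves bsq/bil/bip, float32 or uint16) and an RDS array container
# holding `data` and `wavelengths_nm`.

#' Construct a hyperspectral cube
#'
#' Bundles a reflectance array with its band wavelengths and a scene
#' identifier, validating the invariants every downstream step relies on.
#'
#' @param data Numeric H x W x C array of reflectance values.
#' @param wavelengths_nm Strictly increasing numeric vector of length C,
#'   band-center wavelengths in nanometres.
#' @param scene_id Character scalar naming the scene.
#' @return An object of class `hyper_cube`: a list with elements `data`,
#'   `wavelengths_nm`, `scene_id`.
#' @examples
#' cube <- hyper_cube(array(runif(4 * 4 * 3), c(4, 4, 3)),
#'                    wavelengths_nm = c(550, 775, 1000))
#' dim(cube$data)
#' @export
hyper_cube <- function(data, wavelengths_nm, scene_id = "scene") {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("cube data must be a 3-axis H x W x C array", call. = FALSE)
  }
  if (dim(data)[3] != length(wavelengths_nm)) {
    stop("number of bands (", dim(data)[3], ") does not match ",
         "length(wavelengths_nm) (", length(wavelengths_nm), ")",
         call. = FALSE)
  }
  if (any(diff(wavelengths_nm) <= 0)) {
    stop("wavelengths_nm must be strictly increasing", call. = FALSE)
  }
  bad <- which(apply(data, 3, function(b) any(!is.finite(b))))
  if (length(bad)) {
    stop("non-finite values in band(s) ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  structure(list(data = data,
                 wavelengths_nm = as.numeric(wavelengths_nm),
                 scene_id = as.character(scene_id)),
            class = "hyper_cube")
}

#' @export
print.hyper_cube <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<hyper_cube '%s'> %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              x$scene_id, d[1], d[2], d[3],
              min(x$wavelengths_nm), max(x$wavelengths_nm)))
  invisible(x)
}

#' Construct a binary label mask
#'
#' @param data Integer H x W matrix with values in \{0, 1\};
#'   0 = normal tissue, 1 = tumor.
#' @return An object of class `label_mask` (an integer matrix).
#' @export
label_mask <- function(data) {
  if (!is.matrix(data)) stop("mask must be an H x W matrix", call. = FALSE)
  v <- unique(as.vector(data))
  if (!all(v %in% c(0L, 1L))) {
    stop("mask values outside {0, 1}: ",
         paste(utils::head(setdiff(v, 0:1), 10), collapse = ", "),
         call. = FALSE)
  }
  structure(matrix(as.integer(data), nrow(data), ncol(data)),
            class = c("label_mask", "matrix"))
}

# ---- ENVI dialect ----------------------------------------------------------

# ENVI data type codes used here: 4 = float32, 12 = uint16.
envi_header_path <- function(path) paste0(path, ".hdr")

write_envi <- function(cube, path, interleave = "bsq", data_type = 4L) {
  d <- dim(cube$data)
  a <- cube$data  # H x W x C
  perm <- switch(interleave,
                 bsq = c(2, 1, 3),   # sample fastest, then line, then band
                 bil = c(2, 3, 1),   # sample, band, line
                 bip = c(3, 2, 1),   # band, sample, line
                 stop("unknown interleave: ", interleave, call. = FALSE))
  v <- as.vector(aperm(a, perm))
  con <- file(path, "wb")
  on.exit(close(con))
  if (data_type == 4L) {
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
  } else if (data_type == 12L) {
    if (any(v < 0 | v > 65535 | v != round(v))) {
      stop("values not representable as uint16", call. = FALSE)
    }
    writeBin(as.integer(v), con, size = 2L, endian = "little")
  } else {
    stop("unsupported ENVI data type: ", data_type, call. = FALSE)
  }
  hdr <- c("ENVI",
           paste0("description = {", cube$scene_id, "}"),
           paste0("samples = ", d[2]),
           paste0("lines = ", d[1]),
           paste0("bands = ", d[3]),
           "header offset = 0",
           "file type = ENVI Standard",
           paste0("data type = ", data_type),
           paste0("interleave = ", interleave),
           "byte order = 0",
           paste0("wavelength = {",
                  paste(format(cube$wavelengths_nm, trim = TRUE),
                        collapse = ", "), "}"))
  writeLines(hdr, envi_header_path(path))
  invisible(NULL)
}

parse_envi_header <- function(hdr_path) {
  txt <- paste(readLines(hdr_path, warn = FALSE), collapse = "\n")
  get_num <- function(key) {
    m <- regmatches(txt, regexpr(paste0(key, "\\s*=\\s*[0-9]+"), txt))
    if (!length(m)) stop("ENVI header missing '", key, "'", call. = FALSE)
    as.integer(sub(".*=\\s*", "", m))
  }
  get_str <- function(key) {
    m <- regmatches(txt, regexpr(paste0(key, "\\s*=\\s*[a-zA-Z]+"), txt))
    if (!length(m)) stop("ENVI header missing '", key, "'", call. = FALSE)
    tolower(sub(".*=\\s*", "", m))
  }
  wl <- regmatches(txt, regexpr("wavelength\\s*=\\s*\\{[^}]*\\}", txt))
  wavelengths <- if (length(wl)) {
    as.numeric(strsplit(gsub(".*\\{|\\}", "", wl), ",")[[1]])
  } else NULL
  desc <- regmatches(txt, regexpr("description\\s*=\\s*\\{[^}]*\\}", txt))
  scene_id <- if (length(desc)) gsub(".*\\{|\\}", "", desc) else NA_character_
  list(samples = get_num("samples"), lines = get_num("lines"),
       bands = get_num("bands"), data_type = get_num("data type"),
       interleave = get_str("interleave"), byte_order = get_num("byte order"),
       wavelengths = wavelengths, scene_id = scene_id)
}

read_envi <- function(path) {
  hdr_path <- envi_header_path(path)
  if (!file.exists(hdr_path)) {
    stop("ENVI header not found: ", hdr_path, call. = FALSE)
  }
  h <- parse_envi_header(hdr_path)
  n <- h$samples * h$lines * h$bands
  size <- if (h$data_type == 4L) 4L else if (h$data_type == 12L) 2L else
    stop("unsupported ENVI data type: ", h$data_type, call. = FALSE)
  expected_bytes <- as.numeric(n) * size
  actual_bytes <- file.info(path)$size
  if (is.na(actual_bytes) || actual_bytes != expected_bytes) {
    stop("ENVI raw size mismatch for ", path, ": header implies ",
         expected_bytes, " bytes (", h$bands, " bands), file has ",
         actual_bytes, call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  endian <- if (h$byte_order == 0L) "little" else "big"
  v <- if (h$data_type == 4L) {
    readBin(con, "numeric", n = n, size = 4L, endian = endian)
  } else {
    readBin(con, "integer", n = n, size = 2L, signed = FALSE, endian = endian)
  }
  a <- switch(h$interleave,
              bsq = aperm(array(v, c(h$samples, h$lines, h$bands)), c(2, 1, 3)),
              bil = aperm(array(v, c(h$samples, h$bands, h$lines)), c(3, 1, 2)),
              bip = aperm(array(v, c(h$bands, h$samples, h$lines)), c(3, 2, 1)),
              stop("unknown interleave: ", h$interleave, call. = FALSE))
  bad <- which(apply(a, 3, function(b) any(!is.finite(b))))
  if (length(bad)) {
    stop("non-finite values in band(s) ", paste(bad, collapse = ", "),
         " of ", path, call. = FALSE)
  }
  wl <- if (is.null(h$wavelengths)) seq_len(h$bands) else h$wavelengths
  sid <- if (is.na(h$scene_id)) {
    tools::file_path_sans_ext(basename(path))
  } else h$scene_id
  hyper_cube(a, wl, sid)
}

# ---- public cube I/O -------------------------------------------------------

guess_dialect <- function(path) {
  if (grepl("\\.rds$", path, ignore.case = TRUE)) "rds" else "envi"
}

#' Read a hyperspectral cube
#'
#' @param path Path to the cube file. For the ENVI dialect this is the raw
#'   binary file; a text header `<path>.hdr` must sit next to it.
#' @param dialect `"envi"` or `"rds"`; by default inferred from the file
#'   extension (`.rds` selects the RDS container).
#' @return A [hyper_cube]. Axis order is normalized to H x W x C regardless
#'   of the on-disk interleave.
#' @export
read_cube <- function(path, dialect = guess_dialect(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  dialect <- match.arg(dialect, c("envi", "rds"))
  if (dialect == "envi") return(read_envi(path))
  obj <- readRDS(path)
  if (!all(c("data", "wavelengths_nm") %in% names(obj))) {
    stop("RDS container must hold `data` and `wavelengths_nm`", call. = FALSE)
  }
  bad <- which(apply(obj$data, 3, function(b) any(!is.finite(b))))
  if (length(bad)) {
    stop("non-finite values in band(s) ", paste(bad, collapse = ", "),
         " of ", path, call. = FALSE)
  }
  sid <- if (!is.null(obj$scene_id)) obj$scene_id else
    tools::file_path_sans_ext(basename(path))
  hyper_cube(obj$data, obj$wavelengths_nm, sid)
}

#' Write a hyperspectral cube
#'
#' @param cube A [hyper_cube].
#' @param path Output path (raw file for ENVI; `.rds` for the container).
#' @param dialect `"envi"` or `"rds"`; inferred from the extension by default.
#' @param interleave ENVI interleave, one of `"bsq"`, `"bil"`, `"bip"`.
#' @param data_type ENVI data type code: 4 (float32) or 12 (uint16).
#' @return The path, invisibly. Roundtrips losslessly through the RDS
#'   container; float32 ENVI quantizes to single precision.
#' @export
write_cube <- function(cube, path, dialect = guess_dialect(path),
                       interleave = "bsq", data_type = 4L) {
  stopifnot(inherits(cube, "hyper_cube"))
  cube <- hyper_cube(cube$data, cube$wavelengths_nm, cube$scene_id)  # revalidate
  dialect <- match.arg(dialect, c("envi", "rds"))
  if (dialect == "envi") {
    write_envi(cube, path, interleave = interleave, data_type = data_type)
  } else {
    saveRDS(list(data = cube$data, wavelengths_nm = cube$wavelengths_nm,
                 scene_id = cube$scene_id), path)
  }
  invisible(path)
}

# ---- masks -----------------------------------------------------------------

#' Read a binary label mask
#'
#' Accepts an 8-bit grayscale PNG encoding classes as \{0, 255\} or \{0, 1\},
#' or an RDS file holding an integer matrix.
#'
#' @param path Path to a `.png` or `.rds` mask file.
#' @return A [label_mask] with in-memory values \{0, 1\}.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    return(label_mask(readRDS(path)))
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  bytes <- round(img * 255)
  vals <- sort(unique(as.vector(bytes)))
  if (all(vals %in% c(0, 255))) {
    m <- matrix(as.integer(bytes == 255), nrow(bytes), ncol(bytes))
  } else if (all(vals %in% c(0, 1))) {
    m <- matrix(as.integer(bytes), nrow(bytes), ncol(bytes))
  } else {
    stop("mask pixel values outside the permitted encodings {0,255}/{0,1}: ",
         paste(utils::head(setdiff(vals, c(0, 1, 255)), 10), collapse = ", "),
         call. = FALSE)
  }
  label_mask(m)
}

#' Write a binary label mask
#'
#' @param mask A [label_mask] or binary matrix.
#' @param path Output path; `.png` writes 8-bit grayscale with tumor = 255,
#'   `.rds` stores the integer matrix.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- label_mask(unclass(mask))
  if (grepl("\\.rds$", path, ignore.case = TRUE)) {
    saveRDS(matrix(as.integer(mask), nrow(mask), ncol(mask)), path)
  } else {
    png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  }
  invisible(path)
}

# ---- manifest --------------------------------------------------------------

#' Load a dataset manifest
#'
#' A manifest is a CSV with columns `scene_id,cube,mask,split` listing every
#' scene, its cube file, its mask file (may be empty for unlabeled scenes),
#' and its split (`labeled`, `unlabeled`, or `test`). Relative paths are
#' resolved against the manifest's directory. Masks listed for unlabeled
#' scenes are used only for evaluation reporting, never for training.
#'
#' @param path Path to the manifest CSV.
#' @param quiet Suppress the split-count message.
#' @return A tibble with columns `scene_id`, `cube`, `mask`, `split`.
#' @export
load_manifest <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  required <- c("scene_id", "cube", "mask", "split")
  if (!all(required %in% names(df))) {
    stop("manifest must have columns ", paste(required, collapse = ","),
         call. = FALSE)
  }
  df$mask[is.na(df$mask)] <- ""
  if (anyDuplicated(df$scene_id)) {
    stop("duplicate scene_id in manifest: ",
         paste(unique(df$scene_id[duplicated(df$scene_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!all(df$split %in% c("labeled", "unlabeled", "test"))) {
    stop("split must be one of labeled/unlabeled/test", call. = FALSE)
  }
  need_mask <- df$split %in% c("labeled", "test") & df$mask == ""
  if (any(need_mask)) {
    stop("labeled/test entries without a mask: ",
         paste(df$scene_id[need_mask], collapse = ", "), call. = FALSE)
  }
  root <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(p == "" | grepl("^/", p), p, file.path(root, p))
  }
  out <- tibble::tibble(scene_id = df$scene_id,
                        cube = resolve(df$cube),
                        mask = resolve(df$mask),
                        split = df$split)
  if (!quiet) {
    n <- table(factor(out$split, c("labeled", "unlabeled", "test")))
    message(sprintf("manifest: %d labeled (M), %d unlabeled (N), %d test",
                    n[["labeled"]], n[["unlabeled"]], n[["test"]]))
  }
  out
}

#' Write a dataset manifest
#'
#' @param manifest Tibble with columns `scene_id`, `cube`, `mask`, `split`.
#' @param path Output CSV path. Paths under the manifest's directory are
#'   written relative to it.
#' @return The path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  root <- paste0(normalizePath(dirname(path)), "/")
  rel <- function(p) ifelse(startsWith(p, root), substring(p, nchar(root) + 1), p)
  df <- data.frame(scene_id = manifest$scene_id,
                   cube = rel(manifest$cube),
                   mask = rel(manifest$mask),
                   split = manifest$split)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
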