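# Readers and writers: MetaImage / NIfTI volumes, TIFF/PNG section series,
# plain-text landmark files, YAML configs.

#' Read a 3D volume (MetaImage or NIfTI)
#'
#' Spacing, origin and direction are taken from the header (defaulting to
#' identity direction when absent). MetaImage headers are plain text, so a
#' MetaImage round trip is lossless to full double precision; NIfTI stores
#' geometry as 32-bit floats.
#'
#' @param path file with extension .mha, .mhd, .nii or .nii.gz.
#' @return a \code{\link{volume_image}}.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(sub("^.*?(\\.[a-zA-Z0-9.]+)$", "\\1", basename(path)))
  if (ext %in% c(".mha", ".mhd")) read_metaimage(path)
  else if (ext %in% c(".nii", ".nii.gz") || grepl("\\.nii(\\.gz)?$", path))
    read_nifti_volume(path)
  else stop("unknown volume format: ", ext,
            " (supported: .mha, .mhd, .nii, .nii.gz)")
}

#' Write a 3D volume (MetaImage or NIfTI), format chosen by extension
#'
#' @param image a \code{\link{volume_image}}.
#' @param path output path (.mha, .mhd, .nii, .nii.gz).
#' @param element_type MetaImage element type (\code{"float"} = 32-bit,
#'   \code{"double"} = 64-bit).
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(image, path, element_type = c("float", "double")) {
  element_type <- match.arg(element_type)
  ext <- tolower(sub("^.*?(\\.[a-zA-Z0-9.]+)$", "\\1", basename(path)))
  if (ext %in% c(".mha", ".mhd"))
    write_metaimage(image, path, element_type)
  else if (grepl("\\.nii(\\.gz)?$", path))
    write_nifti_volume(image, path)
  else stop("unknown volume format: ", ext)
  invisible(path)
}

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("expected a 3D NIfTI volume: ", path)
  attributes(arr) <- list(dim = dim(arr))
  xf <- RNifti::xform(img)
  sp <- sqrt(colSums(xf[1:3, 1:3]^2))
  if (any(sp <= 0)) sp <- RNifti::pixdim(img)[1:3]
  dirm <- sweep(xf[1:3, 1:3], 2, sp, "/")
  if (max(abs(crossprod(dirm) - diag(3))) > 1e-4 || det(dirm) < 0)
    dirm <- diag(3) # fall back for unusual/flipped orientations
  # re-orthonormalize float32 header rounding
  sv <- svd(dirm)
  dirm <- sv$u %*% t(sv$v)
  volume_image(arr * 1.0, spacing = sp, origin = xf[1:3, 4], direction = dirm)
}

write_nifti_volume <- function(image, path) {
  img <- RNifti::asNifti(image$values * 1.0)
  RNifti::pixdim(img) <- image$spacing
  m <- rbind(cbind(image$direction %*% diag(image$spacing), image$origin),
             c(0, 0, 0, 1))
  RNifti::sform(img) <- structure(m, code = 2L)
  RNifti::qform(img) <- structure(m, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

# ---- MetaImage (hand-rolled: plain-text header + raw little-endian data) ---

write_metaimage <- function(image, path, element_type = "float") {
  d <- dim(image$values)
  met <- c(float = "MET_FLOAT", double = "MET_DOUBLE")[[element_type]]
  ext <- tolower(sub("^.*\\.", "", path))
  data_file <- if (ext == "mhd") paste0(sub("\\.mhd$", "", basename(path)), ".raw")
               else "LOCAL"
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           "CompressedData = False",
           paste("TransformMatrix =",
                 paste(sprintf("%.17g", t(image$direction)), collapse = " ")),
           paste("Offset =", paste(sprintf("%.17g", image$origin), collapse = " ")),
           "CenterOfRotation = 0 0 0",
           paste("ElementSpacing =",
                 paste(sprintf("%.17g", image$spacing), collapse = " ")),
           paste("DimSize =", paste(d, collapse = " ")),
           paste("ElementType =", met),
           paste("ElementDataFile =", data_file))
  vals <- as.numeric(image$values)
  size <- if (element_type == "float") 4L else 8L
  con <- file(path, "wb")
  writeLines(hdr, con, sep = "\n")
  if (data_file == "LOCAL")
    writeBin(vals, con, size = size, endian = "little")
  close(con)
  if (data_file != "LOCAL") {
    con2 <- file(file.path(dirname(path), data_file), "wb")
    writeBin(vals, con2, size = size, endian = "little")
    close(con2)
  }
  invisible(path)
}

read_metaimage <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (!length(line)) stop("malformed MetaImage header: ",
                            "no ElementDataFile key found in ", path)
    kv <- regmatches(line, regexec("^([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(kv) != 3) stop("malformed MetaImage header line: ", line)
    hdr[[kv[2]]] <- trimws(kv[3])
    if (kv[2] == "ElementDataFile") break
  }
  need <- c("DimSize", "ElementType", "ElementDataFile")
  if (!all(need %in% names(hdr)))
    stop("malformed MetaImage header: missing ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  d <- as.integer(strsplit(hdr$DimSize, "\\s+")[[1]])
  if (length(d) != 3L || any(is.na(d)) || any(d < 1))
    stop("malformed MetaImage header: bad DimSize")
  n <- prod(d)
  size <- switch(hdr$ElementType, MET_FLOAT = 4L, MET_DOUBLE = 8L,
                 MET_UCHAR = 1L, MET_SHORT = 2L, MET_USHORT = 2L,
                 stop("unsupported MetaImage element type: ", hdr$ElementType))
  signed <- !hdr$ElementType %in% c("MET_UCHAR", "MET_USHORT")
  what <- if (hdr$ElementType %in% c("MET_FLOAT", "MET_DOUBLE")) "double"
          else "integer"
  if (identical(hdr$ElementDataFile, "LOCAL")) {
    vals <- readBin(con, what, n = n, size = size, signed = signed,
                    endian = "little")
  } else {
    rawpath <- file.path(dirname(path), hdr$ElementDataFile)
    if (!file.exists(rawpath)) stop("MetaImage data file not found: ", rawpath)
    vals <- readBin(rawpath, what, n = n, size = size, signed = signed,
                    endian = "little")
  }
  if (length(vals) < n)
    stop("malformed MetaImage file: truncated data (got ", length(vals),
         " of ", n, " values)")
  spacing <- if (!is.null(hdr$ElementSpacing))
    as.numeric(strsplit(hdr$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(hdr$Offset))
    as.numeric(strsplit(hdr$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  dirm <- if (!is.null(hdr$TransformMatrix))
    t(matrix(as.numeric(strsplit(hdr$TransformMatrix, "\\s+")[[1]]), 3, 3))
  else diag(3)
  volume_image(array(as.numeric(vals), d), spacing = spacing, origin = origin,
               direction = dirm)
}

# ---- section series --------------------------------------------------------

natural_order <- function(x) {
  key <- gsub("([0-9]+)", "~\\1~", x)
  parts <- strsplit(key, "~")
  maxlen <- max(lengths(parts))
  keys <- vapply(parts, function(p) {
    p <- c(p, rep("", maxlen - length(p)))
    tok <- vapply(p, function(x)
      if (grepl("^[0-9]+$", x)) sprintf("%020.0f", as.numeric(x)) else x, "")
    paste(tok, collapse = "")
  }, "")
  order(keys)
}

read_section_image <- function(path) {
  ext <- tolower(sub("^.*\\.", "", path))
  if (ext %in% c("tif", "tiff")) {
    x <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(x, "bits.per.sample")
    if (is.null(bits)) bits <- 8L
    img <- round(unclass(x) * (2^bits - 1))
    attributes(img) <- list(dim = dim(x))
  } else if (ext == "png") {
    img <- round(png::readPNG(path) * 255)
    bits <- 8L
  } else stop("unsupported section format: ", ext)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3] # drop alpha
  # image files are row-major (y, x); internal convention is (x, y)
  list(img = aperm(img, c(2, 1, 3)), bits = bits)
}

#' Read a series of section images into a section stack
#'
#' @param paths character vector of TIFF/PNG files, or a directory (all
#'   .tif/.tiff/.png files inside). Ordered by natural filename sort unless
#'   \code{order_file} (one filename per line) is given.
#' @param pixel_size in-plane pixel size.
#' @param interval physical distance between consecutive sections.
#' @param units units of the two sizes (default micrometers, converted to mm).
#' @param order_file optional explicit ordering file.
#' @inheritParams section_stack
#' @return a \code{\link{section_stack}}.
#' @export
read_sections <- function(paths, pixel_size, interval, units = c("um", "mm"),
                          order_file = NULL, pad_value = 255) {
  units <- match.arg(units)
  if (length(paths) == 1L && dir.exists(paths)) {
    dirp <- paths
    paths <- list.files(dirp, pattern = "\\.(tif|tiff|png)$",
                        ignore.case = TRUE, full.names = TRUE)
  }
  if (!length(paths)) stop("no readable section images found")
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("section image not found: ", paste(missing, collapse = ", "))
  if (!is.null(order_file)) {
    ord <- readLines(order_file, warn = FALSE)
    ord <- ord[nzchar(trimws(ord))]
    m <- match(trimws(ord), basename(paths))
    if (anyNA(m)) stop("ordering file names missing sections: ",
                       paste(ord[is.na(m)], collapse = ", "))
    paths <- paths[m]
  } else {
    paths <- paths[natural_order(basename(paths))]
  }
  imgs <- lapply(paths, read_section_image)
  bits <- unique(vapply(imgs, `[[`, 0L, "bits"))
  if (length(bits) > 1L)
    stop("mixed bit depths across sections: ", paste(bits, collapse = ", "))
  section_stack(lapply(imgs, `[[`, "img"), pixel_size = pixel_size,
                interval = interval, units = units, pad_value = pad_value)
}

#' Write a section stack as a series of 8-bit TIFF files
#'
#' @param stack a \code{\link{section_stack}}.
#' @param dir output directory (created if needed).
#' @param prefix filename prefix; files are \code{<prefix>_<k>.tif}.
#' @return the file paths, invisibly.
#' @export
write_sections <- function(stack, dir, prefix = "section") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, sprintf("%s_%03d.tif", prefix,
                                  seq_along(stack$sections)))
  for (i in seq_along(stack$sections)) {
    img <- aperm(stack$sections[[i]], c(2, 1, 3)) / 255
    tiff::writeTIFF(pmin(pmax(img, 0), 1), paths[i], bits.per.sample = 8L)
  }
  invisible(paths)
}

# ---- landmark files --------------------------------------------------------

#' Read and write plain-text landmark files
#'
#' One point per line, \code{id x y z} in mm, with header comments naming
#' the observer and the parent image.
#' @param lm a \code{\link{landmark_set}}.
#' @param path file path.
#' @export
write_landmarks <- function(lm, path) {
  lines <- c(paste("# observer:", lm$observer),
             paste("# image:", lm$image),
             sprintf("%s %.17g %.17g %.17g", rownames(lm$points),
                     lm$points[, 1], lm$points[, 2], lm$points[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  lines <- readLines(path, warn = FALSE)
  obs <- sub("^# observer:\\s*", "", grep("^# observer:", lines, value = TRUE))
  img <- sub("^# image:\\s*", "", grep("^# image:", lines, value = TRUE))
  data <- lines[!grepl("^\\s*(#|$)", lines)]
  tok <- strsplit(trimws(data), "\\s+")
  if (any(lengths(tok) != 4)) stop("malformed landmark file: ", path)
  pts <- t(vapply(tok, function(x) as.numeric(x[2:4]), numeric(3)))
  rownames(pts) <- vapply(tok, `[`, "", 1)
  landmark_set(pts, observer = if (length(obs)) obs[1] else "",
               image = if (length(img)) img[1] else "")
}

# ---- configuration files ---------------------------------------------------

#' Read and write pipeline configuration files (YAML)
#'
#' The file has one section per pipeline stage (\code{stack},
#' \code{stack2ex}, \code{ex2in}, \code{phantom}) plus top-level defaults;
#' every \code{\link{registration_config}} field can be overridden per
#' stage.
#' @param cfg a named list of stage sections.
#' @param path file path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

# merge a stage section of a config list into a registration_config
stage_registration_config <- function(cfg_list, stage, seed = NULL, ...) {
  base <- list(...)
  top <- cfg_list[setdiff(names(cfg_list),
                          c("stack", "stack2ex", "ex2in", "phantom", "seed"))]
  sec <- cfg_list[[stage]]
  args <- modifyList(modifyList(base, top %||% list()), sec %||% list())
  if (!is.null(seed) && is.null(args$seed)) args$seed <- seed
  do.call(registration_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
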