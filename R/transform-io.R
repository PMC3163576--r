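#' Read and write transforms as plain text
#'
#' Transforms are stored in a key/value text format at full double precision
#' (hexadecimal float encoding alongside the decimal rendering), so a
#' write/read round trip is bit-lossless. Composite transforms reference their
#' component files (written next to the main file) in application order.
#'
#' @param t a transform object.
#' @param path output file path.
#' @return \code{write_transform} returns \code{path} invisibly;
#'   \code{read_transform} returns the transform.
#' @export
write_transform <- function(t, path) {
  lines <- c("# histomri transform file v1")
  num <- function(x) paste(sprintf("%a", as.numeric(x)), collapse = " ")
  if (inherits(t, "rigid3")) {
    lines <- c(lines, "Type: rigid3",
               paste("Angles:", num(t$angles)),
               paste("Translation:", num(t$translation)),
               paste("Center:", num(t$center)))
  } else if (inherits(t, "similarity3")) {
    lines <- c(lines, "Type: similarity3",
               paste("Angles:", num(t$angles)),
               paste("Translation:", num(t$translation)),
               paste("Center:", num(t$center)),
               paste("Scale:", num(t$scale)))
  } else if (inherits(t, "affine3")) {
    lines <- c(lines, "Type: affine3",
               paste("Matrix:", num(t$matrix)),
               paste("Translation:", num(t$translation)),
               paste("Center:", num(t$center)))
  } else if (inherits(t, "bspline3")) {
    lines <- c(lines, "Type: bspline3",
               paste("GridOrigin:", num(t$grid_origin)),
               paste("GridSpacing:", num(t$grid_spacing)),
               paste("GridShape:", paste(dim(t$coef)[1:3], collapse = " ")),
               paste("Coefficients:", num(t$coef)))
  } else if (inherits(t, "rigid2")) {
    lines <- c(lines, "Type: rigid2",
               paste("Angle:", num(t$angle)),
               paste("Translation:", num(t$translation)),
               paste("Center:", num(t$center)))
  } else if (inherits(t, "composite3")) {
    n <- length(t$components)
    base <- sub("\\.txt$", "", basename(path))
    files <- sprintf("%s_component%02d.txt", base, seq_len(n))
    for (i in seq_len(n))
      write_transform(t$components[[i]], file.path(dirname(path), files[i]))
    lines <- c(lines, "Type: composite",
               paste("Components:", n),
               paste0("Component", seq_len(n), ": ", files))
  } else stop("unsupported transform class ", class(t)[1])
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^([A-Za-z0-9]+):\\s*(.*)$", lines))
  keys <- vapply(kv, `[`, "", 2)
  vals <- vapply(kv, `[`, "", 3)
  get <- function(k) {
    i <- match(k, keys)
    if (is.na(i)) stop("malformed transform file: missing key ", k)
    vals[i]
  }
  nums <- function(k) as.numeric(strsplit(trimws(get(k)), "\\s+")[[1]])
  type <- trimws(get("Type"))
  switch(type,
    rigid3 = rigid3(nums("Angles"), nums("Translation"), nums("Center")),
    similarity3 = similarity3(nums("Angles"), nums("Translation"),
                              nums("Center"), nums("Scale")),
    affine3 = affine3(matrix(nums("Matrix"), 3, 3), nums("Translation"),
                      nums("Center")),
    bspline3 = {
      shp <- as.integer(nums("GridShape"))
      bspline3(nums("GridOrigin"), nums("GridSpacing"),
               array(nums("Coefficients"), c(shp, 3L)))
    },
    rigid2 = rigid2(nums("Angle"), nums("Translation"), nums("Center")),
    composite = {
      n <- as.integer(nums("Components"))
      comps <- lapply(seq_len(n), function(i)
        read_transform(file.path(dirname(path), get(paste0("Component", i)))))
      composite_transform(comps)
    },
    stop("unknown transform type: ", type)
  )
}
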