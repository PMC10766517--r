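#' Write / read the placement text format
#'
#' One neuron per line, whitespace separated: `GID x y z class`, with
#' coordinates in micrometres at six significant digits. Reading validates
#' the format (numeric coordinates, known class labels, unique GIDs) and
#' reports the first offending line.
#'
#' @param placement placement data frame with assigned classes.
#' @param path file path.
#' @return `write_placement_text` the path invisibly;
#'   `read_placement_text` a placement data frame.
#' @export
write_placement_text <- function(placement, path) {
  if (anyNA(placement$class)) stop("placement has unassigned classes")
  lines <- paste(placement$gid,
                 formatC(placement$x, digits = 6, format = "g"),
                 formatC(placement$y, digits = 6, format = "g"),
                 formatC(placement$z, digits = 6, format = "g"),
                 placement$class)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_placement_text
#' @export
read_placement_text <- function(path) {
  lines <- readLines(path)
  parts <- strsplit(trimws(lines), "\\s+")
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 5)
      stop("malformed placement line ", i, ": expected 5 fields, got ",
           length(p))
    nums <- suppressWarnings(as.numeric(p[2:4]))
    if (anyNA(nums))
      stop("malformed placement line ", i, ": non-numeric coordinate")
    if (!p[5] %in% scaffold_classes())
      stop("malformed placement line ", i, ": unknown class '", p[5], "'")
  }
  df <- data.frame(
    gid = as.integer(vapply(parts, `[`, character(1), 1)),
    x = as.numeric(vapply(parts, `[`, character(1), 2)),
    y = as.numeric(vapply(parts, `[`, character(1), 3)),
    z = as.numeric(vapply(parts, `[`, character(1), 4)),
    class = vapply(parts, `[`, character(1), 5),
    stringsAsFactors = FALSE)
  if (anyDuplicated(df$gid))
    stop("duplicate GID in placement file: ",
         df$gid[anyDuplicated(df$gid)])
  df$type <- ifelse(df$class == "PC", "exc", "inh")
  df
}

connectome_key <- function(pre_class, post_class)
  paste0(pre_class, "__", post_class)

#' Write / read a connectome as HDF5
#'
#' One gzip-compressed integer dataset per (presynaptic class,
#' postsynaptic class) pair under the key `preclass__postclass`, each an
#' n x 2 matrix of (pre GID, post GID) rows; class pairs without
#' connections are written as explicit empty datasets when listed in
#' `all_pairs`. Reading reconstructs the exact `connection_set`.
#'
#' @param connections a `connection_set`.
#' @param path HDF5 file path (overwritten).
#' @param all_pairs optional character matrix / data frame of class pairs
#'   that must be present even when empty.
#' @return the path invisibly; `read_connectome_hdf5` a `connection_set`.
#' @export
write_connectome_hdf5 <- function(connections, path, all_pairs = NULL) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  key <- connectome_key(connections$pre_class, connections$post_class)
  keys <- unique(key)
  if (!is.null(all_pairs))
    keys <- union(keys, connectome_key(all_pairs[[1]], all_pairs[[2]]))
  for (k in sort(keys)) {
    rows <- which(key == k)
    m <- cbind(connections$pre_gid[rows], connections$post_gid[rows])
    storage.mode(m) <- "integer"
    rhdf5::h5createDataset(path, k, dims = dim(m), storage.mode = "integer",
                           level = 6)
    if (nrow(m)) rhdf5::h5write(m, path, k)
  }
  rhdf5::h5closeAll()
  invisible(path)
}

#' @rdname write_connectome_hdf5
#' @export
read_connectome_hdf5 <- function(path) {
  if (!file.exists(path)) stop("no such connectome file: ", path)
  keys <- rhdf5::h5ls(path)$name
  pre <- post <- integer(0)
  pre_c <- post_c <- character(0)
  for (k in keys) {
    cls <- strsplit(k, "__", fixed = TRUE)[[1]]
    if (length(cls) != 2)
      stop("corrupt connectome key: '", k, "'")
    m <- tryCatch(rhdf5::h5read(path, k),
                  error = function(e)
                    stop("unreadable connectome key '", k, "': ",
                         conditionMessage(e)))
    if (length(m)) {
      pre <- c(pre, as.integer(m[, 1]))
      post <- c(post, as.integer(m[, 2]))
      pre_c <- c(pre_c, rep(cls[1], nrow(m)))
      post_c <- c(post_c, rep(cls[2], nrow(m)))
    }
  }
  rhdf5::h5closeAll()
  connection_set(pre, post, pre_c, post_c, "loaded")
}

#' Write a grayscale stack as multi-page TIFF or numbered PNGs
#'
#' @param stack rows x cols x slices array of 0..255 values.
#' @param path for TIFF a file path; for PNG a directory (files
#'   `slice_0000.png`, ...).
#' @param format `"tiff"` or `"png"`.
#' @return the path invisibly.
#' @export
write_stack <- function(stack, path, format = c("tiff", "png")) {
  format <- match.arg(format)
  norm <- lapply(seq_len(dim(stack)[3]),
                 function(s) stack[, , s] / 255)
  if (format == "tiff") {
    tiff::writeTIFF(norm, path, bits.per.sample = 8L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (s in seq_along(norm))
      png::writePNG(norm[[s]],
                    file.path(path, sprintf("slice_%04d.png", s - 1)))
  }
  invisible(path)
}

#' Read a stack written by [write_stack()]
#'
#' @param path TIFF file or PNG directory.
#' @return rows x cols x slices array of 0..255 values.
#' @export
read_stack <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (!length(files)) stop("no PNG slices found in ", path)
    slices <- lapply(files, function(f) {
      m <- png::readPNG(f)
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    })
  } else {
    slices <- tiff::readTIFF(path, all = TRUE)
    slices <- lapply(slices, function(m) {
      if (length(dim(m)) == 3) m <- m[, , 1]
      m
    })
  }
  out <- array(0, c(dim(slices[[1]]), length(slices)))
  for (s in seq_along(slices)) out[, , s] <- slices[[s]] * 255
  out
}
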