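# Minimal NRRD (v4) reader/writer for scalar volumes. Only the subset the
# package emits is supported: 3-D, little-endian raw or ascii encoding,
# space "left-posterior-superior", axis-aligned space directions.

#' Write a voxel grid to an NRRD file
#'
#' @param grid a `voxel_grid`.
#' @param path output file path (`.nrrd`).
#' @param encoding `"raw"` (little-endian binary payload) or `"ascii"`
#'   (text payload, diffable).
#' @param type stored element type: `"double"`, `"float"` or `"uint8"`
#'   (for label masks).
#' @export
write_nrrd <- function(grid, path, encoding = c("raw", "ascii"),
                       type = c("double", "float", "uint8")) {
  encoding <- match.arg(encoding); type <- match.arg(type)
  stopifnot(inherits(grid, "voxel_grid"))
  hdr <- c(
    "NRRD0004",
    "# produced by adaptrt",
    paste0("type: ", type),
    "dimension: 3",
    "space: left-posterior-superior",
    paste0("sizes: ", paste(grid$shape, collapse = " ")),
    paste0("space directions: ",
           paste(sprintf("(%.10g,%.10g,%.10g)",
                         c(grid$spacing[1], 0, 0),
                         c(0, grid$spacing[2], 0),
                         c(0, 0, grid$spacing[3])), collapse = " ")),
    "kinds: domain domain domain",
    if (type != "uint8") "endian: little" else NULL,
    paste0("encoding: ", encoding),
    paste0("space origin: (", paste(sprintf("%.10g", grid$origin),
                                    collapse = ","), ")")
  )
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  vals <- as.numeric(grid$values)
  if (encoding == "ascii") {
    writeLines(paste(format(vals, digits = 17, trim = TRUE,
                            scientific = TRUE), collapse = " "), con)
  } else {
    if (type == "uint8") {
      writeBin(as.raw(as.integer(round(vals))), con)
    } else {
      writeBin(vals, con, size = if (type == "float") 4L else 8L,
               endian = "little")
    }
  }
  invisible(path)
}

#' Read an NRRD file written in the package's dialect
#'
#' Errors name the missing geometry field if `sizes`, `space directions`
#' or `space origin` are absent.
#'
#' @param path file path.
#' @return a `voxel_grid`.
#' @export
read_nrrd <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) stop("unexpected end of header in ", path)
    if (ln == "") break
    if (grepl("^#", ln)) next
    kv <- regmatches(ln, regexpr(":", ln), invert = TRUE)[[1]]
    fields[[trimws(kv[1])]] <- trimws(sub("^\\s*", "", kv[2]))
  }
  need <- function(f) {
    if (is.null(fields[[f]])) stop("NRRD header missing required field: ", f)
    fields[[f]]
  }
  sizes <- as.integer(strsplit(need("sizes"), "\\s+")[[1]])
  dirs <- need("space directions")
  vecs <- regmatches(dirs, gregexpr("\\(([^)]*)\\)", dirs))[[1]]
  dmat <- vapply(vecs, function(v)
    as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]]), numeric(3))
  spacing <- sqrt(colSums(dmat^2))
  org <- need("space origin")
  origin <- as.numeric(strsplit(gsub("[()]", "", org), ",")[[1]])
  type <- need("type"); encoding <- need("encoding")
  n <- prod(sizes)
  vals <- switch(encoding,
    ascii = {
      txt <- readLines(con)
      as.numeric(strsplit(paste(txt, collapse = " "), "\\s+")[[1]])
    },
    raw = {
      if (type %in% c("uint8", "unsigned char"))
        as.numeric(readBin(con, "raw", n = n))
      else
        readBin(con, "double", n = n,
                size = if (type == "float") 4L else 8L, endian = "little")
    },
    stop("unsupported NRRD encoding: ", encoding))
  if (length(vals) != n) stop("NRRD payload size mismatch in ", path)
  voxel_grid(array(vals, sizes), origin, spacing)
}
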