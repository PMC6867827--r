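#' Read and write the package's tabular formats
#'
#' Plain-CSV readers/writers for spot tables (`cell_id`, `channel`, `x_nm`,
#' `y_nm`, `z_nm`, `intensity`, `sigma_nm`, `copies`), Ct tables (`sample`,
#' `condition`, `replicate`, `gene`, `ct`) and sweep sets (long format:
#' `sweep_id`, `time_s`, `voltage_mV`, `current_pA`).
#'
#' @param x Object to write.
#' @param path File path.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_spot_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_spot_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "channel", "x_nm", "y_nm", "intensity")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("spot table missing columns: ",
                         paste(miss, collapse = ", "))
  x
}

#' @rdname table_io
#' @export
write_ct_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_ct_table <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "condition", "gene", "ct")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("Ct table missing columns: ",
                         paste(miss, collapse = ", "))
  x
}

#' @rdname table_io
#' @export
write_sweep_set <- function(x, path) {
  stopifnot(inherits(x, "sweep_set"))
  long <- do.call(rbind, lapply(seq_along(x$voltage_mV), function(j) {
    data.frame(sweep_id = j, time_s = x$time_s,
               voltage_mV = x$voltage_mV[j], current_pA = x$current[, j])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname table_io
#' @export
read_sweep_set <- function(path) {
  long <- utils::read.csv(path)
  need <- c("sweep_id", "time_s", "voltage_mV", "current_pA")
  miss <- setdiff(need, names(long))
  if (length(miss)) stop("sweep table missing columns: ",
                         paste(miss, collapse = ", "))
  ids <- sort(unique(long$sweep_id))
  time_s <- sort(unique(long$time_s))
  cur <- sapply(ids, function(j) {
    s <- long[long$sweep_id == j, ]
    s$current_pA[order(s$time_s)]
  })
  v <- vapply(ids, function(j) long$voltage_mV[long$sweep_id == j][1],
              numeric(1))
  dt <- stats::median(diff(time_s))
  structure(list(time_s = time_s, current = cur, voltage_mV = v,
                 epochs = list(pre = NULL, step = range(time_s), tail = NULL),
                 dt_s = dt, protocol = NULL, model = NULL),
            class = "sweep_set")
}

#' Write / read a 16-bit TIFF image stack
#'
#' Images are stored as multi-page unsigned 16-bit TIFF.  Values are
#' rounded to integers and clipped at 65535 on write; masks survive a
#' round trip exactly.
#'
#' @param img Matrix or `[ny, nx, nz]` array of non-negative values.
#' @param path File path.
#' @export
write_image_stack <- function(img, path) {
  if (is.matrix(img)) img <- array(img, dim = c(dim(img), 1))
  pages <- lapply(seq_len(dim(img)[3]), function(p) {
    m <- pmin(pmax(round(img[, , p]), 0), 65535)
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_image_stack
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- simplify2array(lapply(pages, function(m) round(m * 65535)))
  if (length(dim(stack)) == 3L && dim(stack)[3] == 1L) stack[, , 1] else stack
}
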