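# File round trips: spectral stacks as multi-page TIFF with a JSON sidecar,
# decay histograms and IRFs as CSV, tables as CSV, GP maps as TIFF.
# Counts are stored as 16-bit integer pages (bit-exact round trip); GP maps
# are affinely mapped from [-1, 1] onto the 16-bit range, with the mapping
# recorded in the sidecar (worst-case quantization error ~3e-5 GP units).

sidecar_path <- function(path) sub("\\.tiff?$", ".json", path)

#' Write a spectral stack to a multi-page TIFF with JSON sidecar
#'
#' @param stack a [spectral_stack()]; counts must not exceed 65535.
#' @param path output TIFF path; the sidecar JSON (channel centres, pixel
#'   size, metadata) is written next to it.
#' @return `path`, invisibly.
#' @export
save_stack <- function(stack, path) {
  stopifnot(inherits(stack, "spectral_stack"))
  if (max(stack$data) > 65535)
    stop("counts exceed the 16-bit TIFF range")
  pages <- lapply(seq_len(dim(stack$data)[1]),
                  function(k) stack$data[k, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, reduce = FALSE)
  meta <- stack$meta
  meta$registration <- NULL   # data.frame-laden; not JSON round-trip safe
  jsonlite::write_json(
    list(channel_centers_nm = stack$channel_centers,
         pixel_size_um = stack$pixel_size, meta = meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a spectral stack written by [save_stack()]
#'
#' @param path TIFF path; the JSON sidecar is looked up next to it.  A
#'   missing sidecar or missing `channel_centers_nm` field falls back to the
#'   default 565-695 nm grid with a warning.
#' @return a [spectral_stack()].
#' @export
load_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
  sc <- sidecar_path(path)
  centers <- NULL; px <- NULL; meta <- list()
  if (file.exists(sc)) {
    side <- jsonlite::read_json(sc, simplifyVector = TRUE)
    centers <- side$channel_centers_nm
    px <- side$pixel_size_um
    meta <- if (is.null(side$meta)) list() else side$meta
  }
  if (is.null(centers)) {
    warning("no channel_centers_nm in sidecar; assuming the default ",
            "565-695 nm grid")
    centers <- default_channel_centers()[seq_len(length(pages))]
  }
  spectral_stack(arr, centers, pixel_size = px, meta = meta)
}

#' Write a GP image as TIFF with JSON sidecar
#'
#' GP values in `[-1, 1]` are stored affinely mapped to the 16-bit range
#' (`NA` outside the mask maps to 0, recorded in the sidecar).
#'
#' @param gp_image a [compute_gp()] result.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
save_gp_image <- function(gp_image, path) {
  stopifnot(inherits(gp_image, "gp_image"))
  enc <- (gp_image$gp + 1) / 2
  enc[is.na(enc)] <- 0
  tiff::writeTIFF(enc, path, bits.per.sample = 16, reduce = FALSE)
  jsonlite::write_json(
    list(encoding = "gp = 2*value/65535 - 1; unmasked pixels stored as 0",
         lambda_blue_nm = gp_image$lambda_blue,
         lambda_red_nm = gp_image$lambda_red,
         min_counts = gp_image$min_counts,
         n_dropped_low_counts = gp_image$n_dropped_low_counts),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a decay histogram (and its IRF) to CSV
#'
#' Columns: `time_ns` (left bin edge), `counts`, `irf_counts`.  The
#' repetition period is recoverable from the grid (last edge + bin width).
#'
#' @param hist a [decay_histogram()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_decay <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  df <- data.frame(time_ns = hist$bin_edges[-length(hist$bin_edges)],
                   counts = hist$counts, irf_counts = hist$irf_counts)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a decay histogram written by [save_decay()]
#'
#' @param path CSV path with columns `time_ns`, `counts` and (optionally)
#'   `irf_counts`.
#' @param rep_period repetition period in ns; `NULL` infers it from the time
#'   grid assuming the bins tile one full period.
#' @return a [decay_histogram()].
#' @export
load_decay <- function(path, rep_period = NULL) {
  df <- read.csv(path)
  if (!all(c("time_ns", "counts") %in% names(df)))
    stop("decay CSV must have columns time_ns and counts (file: ", path, ")")
  if (any(diff(df$time_ns) <= 0))
    stop("time_ns column is not strictly increasing (file: ", path, ")")
  dt <- diff(df$time_ns)
  if (max(dt) - min(dt) > 1e-6 * mean(dt))
    stop("time_ns column is not an even grid (file: ", path, ")")
  edges <- c(df$time_ns, df$time_ns[length(df$time_ns)] + mean(dt))
  if (is.null(rep_period)) rep_period <- max(edges)
  irf <- if ("irf_counts" %in% names(df)) df$irf_counts else
    stop("decay CSV has no irf_counts column (file: ", path, ")")
  decay_histogram(edges, df$counts, irf, rep_period = rep_period)
}

#' Write / read tabular results
#'
#' Thin CSV wrappers that keep units in the header row and fail loudly on
#' malformed input.
#'
#' @param table data.frame to write.
#' @param path CSV path.
#' @return `save_table`: `path`, invisibly; `load_table`: a data.frame.
#' @export
save_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname save_table
#' @export
load_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  read.csv(path, check.names = FALSE)
}
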