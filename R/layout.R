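#' Electrode layouts
#'
#' An `electrode_layout` maps each channel to a grid position (row, col) and a
#' physical position (x_um, y_um). Physical coordinates are used by the
#' spatio-temporal filter (link length / delay gives an apparent propagation
#' velocity) and by the electrode-decimation study.
#'
#' @param channel_ids character vector of channel labels.
#' @param row,col integer grid indices (1-based).
#' @param pitch_um inter-electrode spacing in micrometers.
#' @param x_um,y_um physical coordinates; default `(col-1)*pitch`,
#'   `(row-1)*pitch`.
#' @return an object of class `electrode_layout` (a data.frame with attribute
#'   `pitch_um`).
#' @export
electrode_layout <- function(channel_ids, row, col, pitch_um,
                             x_um = (col - 1) * pitch_um,
                             y_um = (row - 1) * pitch_um) {
  stopifnot(pitch_um > 0,
            length(row) == length(channel_ids),
            length(col) == length(channel_ids))
  if (anyDuplicated(cbind(row, col))) stop("duplicate electrode positions")
  if (anyDuplicated(channel_ids)) stop("duplicate channel ids in layout")
  df <- data.frame(channel_id = as.character(channel_ids), row = as.integer(row),
                   col = as.integer(col), x_um = x_um, y_um = y_um,
                   stringsAsFactors = FALSE)
  attr(df, "pitch_um") <- pitch_um
  class(df) <- c("electrode_layout", "data.frame")
  df
}

#' 60-channel MEA preset: 8 x 8 grid minus the four corners, 200 um pitch
#' @return an [electrode_layout()] with 60 channels.
#' @export
layout_mea60 <- function() {
  g <- expand.grid(row = 1:8, col = 1:8)
  corner <- (g$row %in% c(1, 8)) & (g$col %in% c(1, 8))
  g <- g[!corner, ]
  g <- g[order(g$row, g$col), ]
  electrode_layout(sprintf("ch%02d", seq_len(nrow(g))), g$row, g$col, 200)
}

#' 4096-channel high-density MEA preset: 64 x 64 grid, 42 um pitch
#' @return an [electrode_layout()] with 4096 channels.
#' @export
layout_mea4k <- function() {
  g <- expand.grid(row = 1:64, col = 1:64)
  g <- g[order(g$row, g$col), ]
  electrode_layout(sprintf("ch%04d", seq_len(nrow(g))), g$row, g$col, 42)
}

#' Regular grid layout
#' @param nrow,ncol grid dimensions.
#' @param pitch_um inter-electrode spacing in micrometers.
#' @param channel_ids optional labels, row-major order.
#' @return an [electrode_layout()].
#' @export
layout_grid <- function(nrow, ncol, pitch_um, channel_ids = NULL) {
  g <- expand.grid(col = seq_len(ncol), row = seq_len(nrow))
  if (is.null(channel_ids)) channel_ids <- sprintf("ch%04d", seq_len(nrow * ncol))
  electrode_layout(channel_ids, g$row, g$col, pitch_um)
}

#' Load / save electrode layouts (CSV `channel_id,row,col,x_um,y_um` with a
#' `# pitch_um:` header line)
#' @param path file path.
#' @rdname layout_io
#' @return [load_layout()] returns an [electrode_layout()];
#'   [save_layout()] returns `path` invisibly.
#' @export
load_layout <- function(path) {
  if (!file.exists(path)) stop("cannot read layout file: ", path)
  hdr <- readLines(path, n = 3L)
  ln <- grep("^#\\s*pitch_um:", hdr, value = TRUE)
  if (length(ln) == 0) stop("layout CSV missing '# pitch_um:' header")
  pitch <- as.numeric(trimws(sub("^#\\s*pitch_um:", "", ln[1])))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  electrode_layout(df$channel_id, df$row, df$col, pitch, df$x_um, df$y_um)
}

#' @param layout an [electrode_layout()].
#' @rdname layout_io
#' @export
save_layout <- function(layout, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# pitch_um: %.10g", attr(layout, "pitch_um")), con)
  write.csv(as.data.frame(layout), con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Euclidean inter-electrode distances (um) for a set of channels
#' @param layout an [electrode_layout()].
#' @param channel_ids channels to include, in order.
#' @return a distance matrix in micrometers.
#' @export
electrode_distances <- function(layout, channel_ids) {
  idx <- match(channel_ids, layout$channel_id)
  if (anyNA(idx)) stop("channels missing from layout: ",
                       paste(channel_ids[is.na(idx)], collapse = ", "))
  x <- layout$x_um[idx]; y <- layout$y_um[idx]
  as.matrix(stats::dist(cbind(x, y)))
}

#' Uniform-stride spatial decimation of a grid layout
#'
#' Selects a regular subgrid with a stride chosen as the largest that still
#' leaves at least `n` electrodes, then keeps the first `n` of the subgrid in
#' row-major order (deterministic, anchored at the grid origin).
#'
#' @param layout an [electrode_layout()].
#' @param n number of electrodes to keep.
#' @return character vector of selected channel ids.
#' @export
decimate_layout <- function(layout, n) {
  if (n > nrow(layout)) stop("requested more electrodes than available")
  rows <- sort(unique(layout$row)); cols <- sort(unique(layout$col))
  stride <- 1L
  repeat {
    s <- stride + 1L
    keep <- layout$row %in% rows[seq(1, length(rows), by = s)] &
            layout$col %in% cols[seq(1, length(cols), by = s)]
    if (sum(keep) < n) break
    stride <- s
  }
  keep <- layout$row %in% rows[seq(1, length(rows), by = stride)] &
          layout$col %in% cols[seq(1, length(cols), by = stride)]
  sel <- layout[keep, ]
  sel <- sel[order(sel$row, sel$col), ]
  sel$channel_id[seq_len(n)]
}
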