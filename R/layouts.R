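#' Construct an electrode layout
#'
#' An electrode layout is a set of electrode centre coordinates in
#' micrometres with unique integer identifiers. Convention: `y` runs along
#' the shank (increasing toward the tip, origin at the topmost electrode),
#' `x` across the shank, `z` out of the probe plane (0 for planar probes).
#'
#' @param electrodes Data frame with columns `id`, `x`, `y`, `z`.
#' @param name Label for the layout.
#' @return An object of class `electrode_layout`.
#' @export
electrode_layout <- function(electrodes, name = "layout") {
  electrodes <- as.data.frame(electrodes)
  needed <- c("id", "x", "y", "z")
  missing_cols <- setdiff(needed, names(electrodes))
  if (length(missing_cols)) {
    stop("electrode table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  electrodes <- electrodes[needed]
  if (nrow(electrodes) < 1) stop("layout must contain at least one electrode", call. = FALSE)
  dup <- electrodes$id[duplicated(electrodes$id)]
  if (length(dup)) {
    stop("duplicate electrode id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(electrodes$x, electrodes$y, electrodes$z)
  if (anyDuplicated(key)) stop("electrode positions must be unique", call. = FALSE)
  structure(list(name = name, electrodes = electrodes),
            class = "electrode_layout")
}

#' Number of electrodes in a layout
#' @param layout An `electrode_layout`.
#' @return Integer electrode count.
#' @export
n_electrodes <- function(layout) nrow(layout$electrodes)

#' Nearest-neighbour distance of a layout
#'
#' The effective inter-electrode distance (pitch) of a layout is defined
#' as the minimum centre-to-centre distance between any two electrodes.
#' `NA` for single-electrode layouts.
#'
#' @param layout An `electrode_layout`.
#' @return Pitch in micrometres, or `NA_real_` if `m < 2`.
#' @export
layout_pitch <- function(layout) {
  e <- layout$electrodes
  if (nrow(e) < 2) return(NA_real_)
  min(stats::dist(e[c("x", "y", "z")]))
}

layout_coords <- function(layout) {
  as.matrix(layout$electrodes[c("x", "y", "z")])
}

#' @export
print.electrode_layout <- function(x, ...) {
  p <- layout_pitch(x)
  cat(sprintf("Electrode layout '%s': %d electrodes, pitch %s um\n",
              x$name, n_electrodes(x),
              if (is.na(p)) "NA" else sprintf("%.2f", p)))
  invisible(x)
}

#' Linear equidistant layout
#'
#' Collinear electrodes spaced `d` micrometres apart along the shank axis.
#'
#' @param m Electrode count (>= 1).
#' @param d Inter-electrode distance, micrometres (> 0).
#' @param name Layout label.
#' @return An `electrode_layout`.
#' @export
linear_layout <- function(m, d, name = sprintf("linear_%dch_%gum", m, d)) {
  if (m < 1 || m != round(m)) stop("m must be a positive integer", call. = FALSE)
  if (d <= 0) stop("inter-electrode distance must be positive", call. = FALSE)
  electrode_layout(
    data.frame(id = seq_len(m) - 1L, x = 0, y = (seq_len(m) - 1) * d, z = 0),
    name = name
  )
}

#' Two-column zig-zag layout
#'
#' Electrodes alternate between two columns at `x = 0` and
#' `x = col_offset`, with `y` advancing by `row_pitch` per electrode, as on
#' two-column high-density probes. The resulting pitch is
#' `sqrt(row_pitch^2 + col_offset^2)`. With `col_offset = 0` the layout
#' degenerates to a linear array.
#'
#' @param m Electrode count (>= 2).
#' @param row_pitch Vertical advance per electrode, micrometres.
#' @param col_offset Lateral distance between the two columns, micrometres.
#' @param name Layout label.
#' @return An `electrode_layout`.
#' @export
zigzag_layout <- function(m, row_pitch, col_offset,
                          name = sprintf("zigzag_%dch", m)) {
  if (m < 2 || m != round(m)) stop("m must be an integer >= 2", call. = FALSE)
  if (row_pitch <= 0) stop("row_pitch must be positive", call. = FALSE)
  if (col_offset < 0) stop("col_offset must be non-negative", call. = FALSE)
  if (col_offset == 0) return(linear_layout(m, row_pitch, name = name))
  i <- seq_len(m) - 1L
  electrode_layout(
    data.frame(id = i, x = ifelse(i %% 2 == 0, 0, col_offset),
               y = i * row_pitch, z = 0),
    name = name
  )
}

#' Built-in probe presets
#'
#' `rodent_probe()` is a 256-electrode two-column zig-zag laminar probe
#' (12 um per-column vertical pitch in two columns 6 um apart, i.e. a
#' 6 um row advance and 6 um lateral offset, 8.49 um nearest-neighbour
#' pitch). `human_probe()` is the 192-electrode two-column pair of a
#' Neuropixels-style probe (20 um row advance, 16 um lateral offset,
#' 25.6 um pitch).
#'
#' @return An `electrode_layout`.
#' @export
rodent_probe <- function() zigzag_layout(256, row_pitch = 6, col_offset = 6,
                                         name = "rodent_256ch")

#' @rdname rodent_probe
#' @export
human_probe <- function() zigzag_layout(192, row_pitch = 20, col_offset = 16,
                                        name = "human_192ch")

#' Spatially downsample a layout
#'
#' Keeps every `keep_every`-th electrode of a layout ordered along the
#' shank axis, emulating recordings of lower spatial resolution. With the
#' default `offset = keep_every - 1` the k-th, 2k-th, ... electrodes are
#' retained, which composes under nested downsampling
#' (`downsample(downsample(L, a), b)` keeps the same electrodes as
#' `downsample(L, a * b)`) and reproduces the published channel-count
#' series of the presets. Any `offset` in `0:(keep_every - 1)` selects the
#' corresponding shifted configuration.
#'
#' @param layout An `electrode_layout` with electrodes ordered along `y`.
#' @param keep_every Positive integer decimation factor.
#' @param offset Integer in `0:(keep_every - 1)`; electrodes at 0-based
#'   sequence indices congruent to `offset` (mod `keep_every`) are kept.
#' @return The downsampled `electrode_layout`.
#' @examples
#' layout_pitch(downsample(rodent_probe(), 8))  # 48 um, 32 channels
#' @export
downsample <- function(layout, keep_every, offset = keep_every - 1) {
  if (keep_every < 1 || keep_every != round(keep_every)) {
    stop("keep_every must be a positive integer", call. = FALSE)
  }
  if (offset < 0 || offset >= keep_every) {
    stop("offset must lie in 0:(keep_every - 1)", call. = FALSE)
  }
  e <- layout$electrodes
  e <- e[order(e$y, e$x, e$z), , drop = FALSE]
  keep <- (seq_len(nrow(e)) - 1L) %% keep_every == offset
  if (!any(keep)) stop("downsampling removed every electrode", call. = FALSE)
  electrode_layout(e[keep, , drop = FALSE],
                   name = sprintf("%s_k%d_o%d", layout$name, keep_every, offset))
}

#' Enumerate all shifted downsampled configurations
#'
#' Returns the `keep_every` distinct vertical-shift variants of a
#' downsampling, one per offset. The variants share the same pitch (up to
#' boundary effects) but differ in channel membership, mirroring the
#' construction of shifted subsampled recordings.
#'
#' @inheritParams downsample
#' @return A list of `electrode_layout` objects, one per offset.
#' @export
enumerate_shifted_configs <- function(layout, keep_every) {
  lapply(seq_len(keep_every) - 1L,
         function(o) downsample(layout, keep_every, offset = o))
}

#' Table of preset configuration series
#'
#' The downsampling series used throughout: the rodent 256-channel probe
#' decimated to 128/64/32/16 channels, and the human 192-channel column
#' pair decimated to 96/64/48/38/19 channels.
#'
#' @return Named list of `electrode_layout` objects ordered by pitch.
#' @export
rodent_config_set <- function() {
  base <- rodent_probe()
  c(list(base), lapply(c(2, 4, 8, 16), function(k) downsample(base, k)))
}

#' @rdname rodent_config_set
#' @export
human_config_set <- function() {
  base <- human_probe()
  c(list(base), lapply(c(2, 3, 4, 5, 10), function(k) downsample(base, k)))
}

#' Read or write a layout as JSON
#'
#' JSON dialect: `{"name": str, "units": "um", "electrodes":
#' [{"id": int, "x": num, "y": num, "z": num}, ...]}`. Unknown top-level
#' fields are preserved on round trip. Duplicate ids or missing fields are
#' reported with the offending record.
#'
#' @param path File path.
#' @return `read_layout` returns an `electrode_layout`; `write_layout`
#'   returns `path` invisibly.
#' @export
read_layout <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
                  error = function(e) stop("malformed layout JSON: ",
                                           conditionMessage(e), call. = FALSE))
  if (is.null(obj$electrodes)) stop("layout JSON lacks 'electrodes'", call. = FALSE)
  e <- as.data.frame(obj$electrodes)
  for (col in c("id", "x", "y", "z")) {
    if (is.null(e[[col]])) stop("electrode records lack field '", col, "'", call. = FALSE)
  }
  layout <- electrode_layout(e, name = if (is.null(obj$name)) "layout" else obj$name)
  extra <- obj[setdiff(names(obj), c("name", "units", "electrodes"))]
  if (length(extra)) attr(layout, "extra_fields") <- extra
  layout
}

#' @rdname read_layout
#' @param layout An `electrode_layout`.
#' @export
write_layout <- function(layout, path) {
  obj <- list(name = layout$name, units = "um", electrodes = layout$electrodes)
  extra <- attr(layout, "extra_fields")
  if (!is.null(extra)) obj <- c(obj, extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

# TRUE when the layout is collinear with equal spacing (within rel. tol),
# so the exact linear-array formulas apply.
is_linear_equidistant <- function(layout, tol = 1e-8) {
  xy <- layout_coords(layout)
  m <- nrow(xy)
  if (m == 1) return(TRUE)
  dirs <- sweep(xy, 2, xy[1, ])
  v <- dirs[m, ]
  len <- sqrt(sum(v^2))
  if (len == 0) return(FALSE)
  v <- v / len
  proj <- drop(dirs %*% v)
  perp <- dirs - outer(proj, v)
  if (max(abs(perp)) > tol * max(len, 1)) return(FALSE)
  s <- sort(proj)
  gaps <- diff(s)
  if (any(gaps <= 0)) return(FALSE)
  abs(max(gaps) - min(gaps)) <= tol * max(gaps)
}
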