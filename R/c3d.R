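#' Read a c3d motion-capture file
#'
#' Supports the common modern subset of the c3d standard: Intel (little
#' endian) byte order with floating-point point data (negative POINT:SCALE).
#' Coordinates are converted to millimetres using POINT:UNITS; a point is
#' masked invalid on a frame when the file flags it (negative residual) or
#' when all three coordinates are exactly zero, the other convention vendor
#' exports use for missing reconstructions.
#'
#' @param path Path to the c3d file.
#' @param label_map Optional named vector renaming vendor labels to geometry
#'   labels (see [rename_markers()]).
#' @return A [new_trial()] `mocap_trial` in millimetres.
#' @export
read_c3d <- function(path, label_map = NULL) {
  if (!file.exists(path)) stop("c3d file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 512) stop("corrupt c3d: file shorter than one block", call. = FALSE)
  if (as.integer(raw[2]) != 0x50) {
    stop("corrupt c3d: missing 0x50 signature byte", call. = FALSE)
  }
  param_block <- as.integer(raw[1])

  p0 <- 512L * (param_block - 1L)
  if (length(raw) < p0 + 4) stop("corrupt c3d: parameter section truncated", call. = FALSE)
  proc <- as.integer(raw[p0 + 4])
  if (proc != 84L) {
    stop("unsupported c3d processor type ", proc,
         " (only Intel, 84, is supported)", call. = FALSE)
  }
  params <- parse_c3d_params(raw, p0)
  point <- params[["POINT"]]
  if (is.null(point)) stop("corrupt c3d: no POINT group", call. = FALSE)

  as_uint16 <- function(v) { v <- as.integer(v); ifelse(v < 0, v + 65536L, v) }
  n_points <- as_uint16(point$USED)
  n_frames <- as_uint16(point$FRAMES)
  rate <- as.numeric(point$RATE)
  scale <- as.numeric(point$SCALE)
  data_start <- as.integer(point$DATA_START)
  units <- trimws(point$UNITS %||% "mm")
  labels <- trimws(point$LABELS)[seq_len(n_points)]
  if (scale >= 0) {
    stop("integer-scaled c3d point data is not supported (POINT:SCALE = ",
         scale, "); export as floating point", call. = FALSE)
  }
  unit_factor <- switch(tolower(units),
                        "mm" = 1, "cm" = 10, "m" = 1000,
                        stop("unknown c3d POINT:UNITS value '", units, "'",
                             call. = FALSE))

  d0 <- 512L * (data_start - 1L)
  n_vals <- n_frames * n_points * 4L
  pos <- array(NA_real_, c(n_frames, n_points, 3))
  valid <- matrix(FALSE, n_frames, n_points)
  if (n_vals > 0) {
    if (length(raw) < d0 + 4L * n_vals) {
      stop("corrupt c3d: point data truncated", call. = FALSE)
    }
    con <- rawConnection(raw[seq.int(d0 + 1L, length(raw))])
    on.exit(close(con))
    vals <- readBin(con, "numeric", n = n_vals, size = 4, endian = "little")
    # frame-major: frames vary slowest, then points, then x/y/z/residual
    dim(vals) <- c(4L, n_points, n_frames)
    plane <- function(k) t(matrix(vals[k, , ], n_points, n_frames))
    for (k in 1:3) pos[, , k] <- plane(k) * unit_factor
    resid <- plane(4)
    zero3 <- plane(1) == 0 & plane(2) == 0 & plane(3) == 0
    valid <- (resid >= 0) & !zero3
  }
  trial <- new_trial(pos, labels, rate, valid = valid, source = path)
  rename_markers(trial, label_map)
}

parse_c3d_params <- function(raw, p0) {
  i <- p0 + 5L  # skip 4 param-header bytes
  int8 <- function(at) {
    v <- as.integer(raw[at]); if (v > 127) v - 256L else v
  }
  uint16 <- function(at) as.integer(raw[at]) + 256L * as.integer(raw[at + 1L])
  int16 <- function(at) { v <- uint16(at); if (v > 32767) v - 65536L else v }
  chars <- function(at, n) rawToChar(raw[seq.int(at, length.out = n)])
  read_values <- function(at, type, count) {
    con <- rawConnection(raw[seq.int(at, length.out = abs(type) * count)])
    on.exit(close(con))
    switch(as.character(type),
           "-1" = chars(at, count),
           "1" = as.integer(raw[seq.int(at, length.out = count)]),
           "2" = readBin(con, "integer", n = count, size = 2, endian = "little"),
           "4" = readBin(con, "numeric", n = count, size = 4, endian = "little"),
           stop("corrupt c3d: parameter type ", type, call. = FALSE))
  }
  groups <- list()        # id -> name
  params <- list()        # name -> named list
  repeat {
    if (i + 1L > length(raw)) break
    name_len <- int8(i)
    id <- int8(i + 1L)
    if (name_len == 0L || id == 0L) break
    nm <- chars(i + 2L, abs(name_len))
    off_at <- i + 2L + abs(name_len)
    offset <- int16(off_at)
    if (id < 0L) {  # group record
      groups[[as.character(-id)]] <- nm
    } else {        # parameter record
      type <- int8(off_at + 2L)
      n_dims <- int8(off_at + 3L)
      dims <- if (n_dims > 0) as.integer(raw[seq.int(off_at + 4L, length.out = n_dims)]) else integer()
      count <- prod(c(1L, dims))
      data_at <- off_at + 4L + n_dims
      vals <- read_values(data_at, type, count)
      if (type == -1L && length(dims) >= 2) {
        # char matrix: first dim is string length
        step <- dims[1]
        s <- chars(data_at, count)
        vals <- vapply(seq_len(count / step) - 1L,
                       function(k) substr(s, k * step + 1L, (k + 1L) * step),
                       character(1))
      }
      gid <- as.character(id)
      params[[gid]] <- c(params[[gid]], stats::setNames(list(vals), nm))
    }
    if (offset == 0L) break
    i <- off_at + offset
  }
  out <- list()
  for (gid in names(params)) {
    gname <- groups[[gid]] %||% gid
    out[[gname]] <- params[[gid]]
  }
  out
}

#' Write a trial to a c3d file
#'
#' Writes Intel byte order, floating-point point data, POINT:UNITS = "mm".
#' Invalid points are stored with zero coordinates and residual -1, the
#' conventions [read_c3d()] masks on. The c3d header stores the last frame in
#' 16 bits, so trials longer than 65535 frames are refused.
#'
#' @param trial A `mocap_trial`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_c3d <- function(trial, path) {
  arr <- trial_array(trial)
  n <- dim(arr$positions)[1]
  m <- dim(arr$positions)[2]
  if (n > 65535) stop("c3d stores at most 65535 frames", call. = FALSE)
  labels <- formatC(substr(arr$labels, 1, 32), width = 32, flag = "-")
  lab_len <- 32L

  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  as_int16 <- function(x) { x <- as.integer(x); ifelse(x > 32767L, x - 65536L, x) }
  w8 <- function(x) writeBin(as.integer(x), con, size = 1, endian = "little")
  w16 <- function(x) writeBin(as_int16(x), con, size = 2, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wchr <- function(s) writeBin(charToRaw(s), con)

  # --- parameter section (block 2..), assembled first to know its size
  pcon <- rawConnection(raw(0), "wb")
  p8 <- function(x) writeBin(as.integer(x), pcon, size = 1, endian = "little")
  p16 <- function(x) writeBin(as_int16(x), pcon, size = 2, endian = "little")
  pf <- function(x) writeBin(as.numeric(x), pcon, size = 4, endian = "little")
  pchr <- function(s) writeBin(charToRaw(s), pcon)
  sint8 <- function(x) ifelse(x < 0, x + 256L, x)

  group <- function(id, name) {
    p8(nchar(name)); p8(sint8(-id)); pchr(name)
    p16(3L); p8(0L)  # offset to next record; empty description
  }
  param <- function(id, name, type, dims, write_data, data_bytes) {
    p8(nchar(name)); p8(id); pchr(name)
    offset <- 2L + 1L + 1L + length(dims) + data_bytes + 1L
    p16(offset)
    p8(sint8(type)); p8(length(dims))
    for (d in dims) p8(d)
    write_data()
    p8(0L)  # empty description
  }
  group(1L, "POINT")
  param(1L, "USED", 2L, integer(), function() p16(m), 2L)
  param(1L, "FRAMES", 2L, integer(), function() p16(n), 2L)
  param(1L, "RATE", 4L, integer(), function() pf(trial_rate(trial)), 4L)
  param(1L, "SCALE", 4L, integer(), function() pf(-1), 4L)
  param(1L, "UNITS", -1L, 2L, function() pchr("mm"), 2L)
  param(1L, "LABELS", -1L, c(lab_len, m),
        function() pchr(paste(labels, collapse = "")), lab_len * m)
  # DATA_START placeholder patched below once the section size is known
  param(1L, "DATA_START", 2L, integer(), function() p16(0L), 2L)
  p8(0L); p8(0L)  # terminator record
  pbytes <- rawConnectionValue(pcon)
  close(pcon); on.exit(close(con))

  n_param_blocks <- ceiling((length(pbytes) + 4L) / 512)
  data_start <- 2L + n_param_blocks
  # patch DATA_START value: last parameter before terminator; its 2 data
  # bytes sit 3 bytes before the end (value, desc-len 0, terminator 2 bytes)
  ds_at <- length(pbytes) - 5L
  ds_raw <- writeBin(as.integer(data_start), raw(), size = 2, endian = "little")
  pbytes[ds_at + 1L] <- ds_raw[1]
  pbytes[ds_at + 2L] <- ds_raw[2]

  # --- header block
  w8(2L); w8(0x50)
  w16(m); w16(0L)               # points used; analog channels
  w16(min(n, 1L)); w16(n)       # first, last frame
  w16(0L); wf(-1)               # max gap; scale (negative = float)
  w16(data_start); w16(0L)      # data start block; analog per frame
  wf(trial_rate(trial))
  writeBin(raw(512 - 24), con)

  # --- parameter header + records, padded to whole blocks
  w8(2L + n_param_blocks)       # historically: first data block pointer
  w8(0x50)
  w8(n_param_blocks)
  w8(84L)                       # Intel
  writeBin(pbytes, con)
  pad <- n_param_blocks * 512L - (length(pbytes) + 4L)
  writeBin(raw(pad), con)

  # --- point data: x, y, z, residual per point per frame
  pos <- arr$positions
  valid <- arr$valid
  out <- array(0, c(4L, m, max(n, 0L)))
  if (n > 0 && m > 0) {
    for (k in 1:3) {
      v <- t(pos[, , k]); v[t(!valid)] <- 0
      out[k, , ] <- v
    }
    out[4, , ] <- t(ifelse(valid, 0, -1))
  }
  wf(as.numeric(out))
  bytes <- rawConnectionValue(con)
  fcon <- file(path, "wb")
  writeBin(bytes, fcon)
  close(fcon)
  invisible(path)
}
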