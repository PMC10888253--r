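# FCS 3.0/3.1 list-mode file input/output, spillover compensation and
# intensity transforms.
#
# The reader understands plain FCS 3.0/3.1 files and LMD containers, which
# prepend an FCS 2.0 dataset: the embedded FCS 3.0 segment is located by
# scanning for its header signature and all offsets are interpreted
# relative to the segment start.  The writer emits standards-conformant
# FCS 3.1: list mode, $DATATYPE F (32-bit float), little-endian.
# Escaped TEXT-segment delimiters are not supported.

#' Construct an in-memory cytometry sample
#'
#' @param events numeric matrix, events x channels; column names are
#'   detector names.
#' @param channels data frame with columns `name`, `stain`, `range`
#'   (one row per events column).
#' @param time per-event acquisition time in seconds, or `NULL`.
#' @param keywords named list of FCS TEXT keywords.
#' @return a `cg_sample`.
#' @export
cg_sample <- function(events, channels, time = NULL, keywords = list()) {
  stopifnot(is.matrix(events), nrow(channels) == ncol(events))
  colnames(events) <- channels$name
  structure(list(
    events = events,
    channels = channels,
    time = time,
    keywords = keywords,
    transformed = FALSE,
    transform = NULL,
    compensated = FALSE,
    marker_map = NULL,
    tube = NA_character_
  ), class = "cg_sample")
}

#' @export
print.cg_sample <- function(x, ...) {
  cat(sprintf("<cg_sample> %d events x %d channels%s%s\n",
              nrow(x$events), ncol(x$events),
              if (x$transformed) ", transformed" else "",
              if (is.na(x$tube)) "" else paste0(", tube ", x$tube)))
  invisible(x)
}

n_events <- function(sample) nrow(sample$events)

#' Read an FCS 3.0/3.1 event file
#'
#' Performs the stage-1 integrity check: the declared `$TOT` must be
#' consistent with the DATA segment length, the datatype must be supported,
#' and the decoded event matrix must be finite.  A `$SPILLOVER` (or
#' `$COMP`) matrix, when present, is applied to the fluorescence channels.
#' Events are ordered by acquisition time when a TIME channel is present.
#'
#' @param path path to an FCS or LMD file.
#' @param compensate apply the stored spillover matrix if present
#'   (default `TRUE`).
#' @return a `cg_sample`.
#' @export
read_fcs <- function(path, compensate = TRUE) {
  if (!file.exists(path)) cg_stop("cg_io_error", "file not found: %s", path)
  raw <- readBin(path, "raw", n = file.size(path))
  hits <- grepRaw("FCS3\\.[01]", raw, all = TRUE)
  if (length(hits) == 0) {
    if (length(grepRaw("FCS2\\.0", raw, all = FALSE)))
      cg_stop("cg_integrity_error",
              "%s: only an FCS 2.0 dataset found (no embedded FCS 3.x segment)", path)
    cg_stop("cg_integrity_error", "%s: no FCS 3.0/3.1 header found", path)
  }
  off <- hits[1] - 1L  # 0-based offset of the segment start

  hdr_int <- function(from, len) {
    s <- gsub(" ", "", rawToChar(raw[(off + from):(off + from + len - 1)]))
    if (s == "") 0 else suppressWarnings(as.numeric(s))
  }
  ts <- hdr_int(11, 8); te <- hdr_int(19, 8)
  ds <- hdr_int(27, 8); de <- hdr_int(35, 8)
  if (is.na(ts) || is.na(te) || te <= ts)
    cg_stop("cg_integrity_error", "%s: malformed FCS header offsets", path)

  txt <- rawToChar(raw[(off + ts + 1):(off + te + 1)])
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) < 2 || length(parts) %% 2 == 1)
    parts <- parts[seq_len(length(parts) - length(parts) %% 2)]
  kw <- as.list(parts[seq(2, length(parts), by = 2)])
  names(kw) <- toupper(trimws(parts[seq(1, length(parts), by = 2)]))

  need <- function(key) {
    if (is.null(kw[[key]]))
      cg_stop("cg_integrity_error", "%s: missing required keyword %s", path, key)
    kw[[key]]
  }
  tot <- as.integer(need("$TOT"))
  par <- as.integer(need("$PAR"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- gsub(" ", "", need("$BYTEORD"))
  endian <- if (byteord %in% c("1,2,3,4", "1,2")) "little"
            else if (byteord %in% c("4,3,2,1", "2,1")) "big"
            else cg_stop("cg_integrity_error", "%s: unsupported $BYTEORD '%s'",
                         path, byteord)

  if (ds == 0 || de == 0) {
    ds <- as.numeric(need("$BEGINDATA")); de <- as.numeric(need("$ENDDATA"))
  }
  nbytes <- de - ds + 1

  pnb <- vapply(seq_len(par), function(i)
    as.integer(kw[[sprintf("$P%dB", i)]] %||% NA_integer_), 1L)
  if (dtype == "F") {
    size <- 4L
  } else if (dtype == "D") {
    size <- 8L
  } else if (dtype == "I") {
    if (length(unique(pnb)) != 1 || !(pnb[1] %in% c(16L, 32L)))
      cg_stop("cg_integrity_error",
              "%s: $DATATYPE I supported only with uniform $PnB 16 or 32", path)
    size <- pnb[1] %/% 8L
  } else {
    cg_stop("cg_integrity_error", "%s: unsupported $DATATYPE '%s'", path, dtype)
  }

  expected <- as.numeric(tot) * par * size
  if (off + de + 1 > length(raw) || nbytes < expected)
    cg_stop("cg_integrity_error",
            "%s: DATA segment truncated ($TOT %d needs %.0f bytes, found %.0f)",
            path, tot, expected, max(0, nbytes))
  if (nbytes != expected)
    cg_stop("cg_integrity_error",
            "%s: $TOT inconsistent with DATA segment length (%.0f vs %.0f bytes)",
            path, expected, nbytes)

  con <- raw[(off + ds + 1):(off + ds + expected)]
  vals <- if (dtype == "I")
    readBin(con, "integer", n = tot * par, size = size, signed = size > 2,
            endian = endian)
  else
    readBin(con, "numeric", n = tot * par, size = size, endian = endian)
  events <- matrix(as.numeric(vals), nrow = tot, ncol = par, byrow = TRUE)
  if (!all(is.finite(events)))
    cg_stop("cg_integrity_error", "%s: non-finite values in DATA segment", path)

  channels <- data.frame(
    name = vapply(seq_len(par), function(i) kw[[sprintf("$P%dN", i)]] %||% sprintf("P%d", i), ""),
    stain = vapply(seq_len(par), function(i) kw[[sprintf("$P%dS", i)]] %||% "", ""),
    range = vapply(seq_len(par), function(i) as.numeric(kw[[sprintf("$P%dR", i)]] %||% NA), 1),
    stringsAsFactors = FALSE
  )
  colnames(events) <- channels$name

  time <- NULL
  ti <- which(gsub("[^A-Z0-9]", "", toupper(channels$name)) == "TIME")
  if (length(ti) == 1) {
    step <- as.numeric(kw[["$TIMESTEP"]] %||% 1)
    time <- events[, ti] * step
    if (is.unsorted(time)) {
      ord <- order(time)
      events <- events[ord, , drop = FALSE]
      time <- time[ord]
    }
  }

  sample <- cg_sample(events, channels, time = time, keywords = kw)
  spill <- kw[["$SPILLOVER"]] %||% kw[["SPILL"]] %||% kw[["$COMP"]]
  if (compensate && !is.null(spill)) sample <- apply_compensation(sample, spill)
  sample
}

parse_spillover <- function(spec) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  n <- as.integer(parts[1])
  chans <- trimws(parts[2:(n + 1)])
  vals <- as.numeric(parts[(n + 2):(n + 1 + n * n)])
  S <- matrix(vals, nrow = n, ncol = n, byrow = TRUE,
              dimnames = list(chans, chans))
  S
}

apply_compensation <- function(sample, spill) {
  if (sample$compensated)
    cg_stop("cg_state_error", "sample is already compensated")
  S <- if (is.matrix(spill)) spill else parse_spillover(spill)
  idx <- match(rownames(S), sample$channels$name)
  if (anyNA(idx)) idx <- match(rownames(S), sample$channels$stain)
  if (anyNA(idx))
    cg_stop("cg_integrity_error", "spillover channels not found in sample")
  if (!isTRUE(all.equal(S, diag(nrow(S)), check.attributes = FALSE)))
    sample$events[, idx] <- sample$events[, idx] %*% solve(S)
  sample$compensated <- TRUE
  sample
}

#' Write a sample as FCS 3.1
#'
#' Emits list-mode, 32-bit float, little-endian FCS 3.1.  Reading the file
#' back recovers the event matrix up to float32 rounding.
#'
#' @param sample a `cg_sample` on the raw (untransformed) scale.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fcs <- function(sample, path) {
  stopifnot(inherits(sample, "cg_sample"))
  if (n_events(sample) == 0)
    cg_stop("cg_io_error", "refusing to write an FCS file with 0 events")
  if (sample$transformed)
    warning("writing a transformed sample; FCS files conventionally hold raw intensities")
  events <- sample$events
  n <- nrow(events); p <- ncol(events)

  kw <- character(0)
  add <- function(k, v) kw <<- c(kw, k, as.character(v))
  add("$BEGINANALYSIS", 0); add("$ENDANALYSIS", 0)
  add("$BEGINSTEXT", 0); add("$ENDSTEXT", 0)
  add("$BEGINDATA", "%BDATA###%"); add("$ENDDATA", "%EDATA###%")
  add("$BYTEORD", "1,2,3,4"); add("$DATATYPE", "F")
  add("$MODE", "L"); add("$NEXTDATA", 0)
  add("$TOT", n); add("$PAR", p)
  if (!is.null(sample$time)) add("$TIMESTEP",
    as.character(sample$keywords[["$TIMESTEP"]] %||% 1))
  for (i in seq_len(p)) {
    add(sprintf("$P%dN", i), sample$channels$name[i])
    if (nzchar(sample$channels$stain[i])) add(sprintf("$P%dS", i), sample$channels$stain[i])
    add(sprintf("$P%dB", i), 32)
    add(sprintf("$P%dE", i), "0,0")
    rng <- sample$channels$range[i]
    add(sprintf("$P%dR", i), if (is.na(rng)) 1048576 else format(rng, scientific = FALSE))
  }
  delim <- "/"
  text <- paste0(delim, paste(kw, collapse = delim), delim)

  ts <- 58L
  te <- ts + nchar(text, type = "bytes") - 1L  # placeholders are value-width
  dbytes <- n * p * 4
  dstart <- te + 1L
  dend <- dstart + dbytes - 1L
  text <- sub("%BDATA###%", sprintf("%010d", dstart), text, fixed = TRUE)
  text <- sub("%EDATA###%", sprintf("%010d", dend), text, fixed = TRUE)
  if (dend > 99999999)
    cg_stop("cg_io_error", "file too large for 8-character header offsets")

  fmt8 <- function(x) formatC(as.integer(x), width = 8, format = "d", flag = " ")
  header <- paste0("FCS3.1    ", fmt8(ts), fmt8(te), fmt8(dstart), fmt8(dend),
                   fmt8(0), fmt8(0))
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  writeBin(as.vector(t(events)), con, size = 4, endian = "little")
  invisible(path)
}

#' Intensity transform specification
#'
#' Fluorescence channels are mapped through `asinh(x / cofactor)`
#' (default cofactor 150, conventional for this instrument class); scatter
#' and time channels stay linear.  The asinh map is strictly monotone and
#' exactly invertible.
#'
#' @param cofactor positive asinh cofactor for fluorescence channels.
#' @return a `cg_transform`.
#' @export
cg_transform <- function(cofactor = 150) {
  stopifnot(cofactor > 0)
  structure(list(cofactor = cofactor), class = "cg_transform")
}

#' Apply the analysis-scale transform to a sample
#'
#' @param sample an untransformed `cg_sample`.
#' @param spec a [cg_transform()].
#' @return the transformed sample (`$transformed` set).
#' @export
apply_transform <- function(sample, spec = cg_transform()) {
  stopifnot(inherits(sample, "cg_sample"), inherits(spec, "cg_transform"))
  if (sample$transformed)
    cg_stop("cg_state_error", "sample is already transformed")
  fluor <- !.is_scatter_or_time(sample$channels$name)
  sample$events[, fluor] <- asinh(sample$events[, fluor] / spec$cofactor)
  sample$transformed <- TRUE
  sample$transform <- spec
  sample
}

# Inverse of the fluorescence transform (used by the simulator to emit
# raw-scale FCS values from template draws on the transformed scale).
inverse_transform_values <- function(t, cofactor = 150) sinh(t) * cofactor

# Matrix of transformed marker intensities, columns named by normalized
# marker; requires match_tube() to have set the marker map.
marker_matrix <- function(sample) {
  if (is.null(sample$marker_map))
    cg_stop("cg_state_error", "sample has no marker map; call match_tube() first")
  m <- sample$events[, sample$marker_map, drop = FALSE]
  colnames(m) <- names(sample$marker_map)
  m
}

scatter_columns <- function(sample, tube) {
  sc <- tube$scatter_channels
  idx <- match(sc, colnames(sample$events))
  if (anyNA(idx))
    cg_stop("cg_integrity_error", "scatter channels [%s] missing from sample",
            paste(sc[is.na(idx)], collapse = ", "))
  m <- sample$events[, idx, drop = FALSE]
  colnames(m) <- names(sc)
  m
}
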