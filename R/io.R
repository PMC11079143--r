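#' Read an EEG recording from disk
#'
#' Supported formats: BrainVision (`.vhdr` header + binary `.eeg`), EDF, and
#' the package's plain-text `fixture-csv` dialect. Data are returned in
#' microvolts; EDF physical dimensions are passed through unchanged.
#'
#' @param path Path to the file (`.vhdr` for BrainVision).
#' @param format One of `"brainvision"`, `"edf"`, `"fixture-csv"`. Guessed
#'   from the extension when omitted.
#' @return An [recording()] object.
#' @export
read_recording <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     vhdr = "brainvision", edf = "edf", csv = "fixture-csv",
                     stop("cannot guess format from extension of ", path,
                          call. = FALSE))
  }
  switch(format,
         "fixture-csv" = read_fixture_csv(path),
         "edf" = read_edf(path),
         "brainvision" = read_brainvision(path),
         stop("unknown format: ", format, call. = FALSE))
}

#' Write an EEG recording to disk
#'
#' `fixture-csv` round-trips bit-exactly with [read_recording()]; EDF
#' quantizes to 16 bits over the per-channel physical range.
#'
#' @param rec An [recording()] object.
#' @param path Output path.
#' @param format `"fixture-csv"` or `"edf"`.
#' @export
write_recording <- function(rec, path, format = c("fixture-csv", "edf")) {
  stopifnot(inherits(rec, "eeg_recording"))
  format <- match.arg(format)
  switch(format,
         "fixture-csv" = write_fixture_csv(rec, path),
         "edf" = write_edf(rec, path))
  invisible(path)
}

# fixture-csv: one header line `#fs=<Hz>;channels=<comma list>`, then one
# comma-separated row per sample, full-precision decimal floats.
write_fixture_csv <- function(rec, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  header <- sprintf("#fs=%s;channels=%s", format_full(rec$fs),
                    paste(rec$channel_names, collapse = ","))
  writeLines(header, con)
  rows <- apply(rec$data, 1L, function(r)
    paste(vapply(r, format_full, character(1)), collapse = ","))
  writeLines(rows, con)
}

format_full <- function(x) {
  if (is.finite(x) && x == trunc(x) && abs(x) < 2^53)
    return(sprintf("%.0f", x))
  s <- sprintf("%.17g", x)
  # shortest representation that still round-trips exactly
  for (d in 1:16) {
    c <- sprintf(paste0("%.", d, "g"), x)
    if (as.numeric(c) == x) return(c)
  }
  s
}

read_fixture_csv <- function(path) {
  con <- file(path, open = "r")
  on.exit(close(con))
  header <- readLines(con, n = 1L)
  m <- regmatches(header, regexec("^#fs=([^;]+);channels=(.*)$", header))[[1]]
  if (length(m) != 3L)
    stop("malformed fixture-csv header in ", path, call. = FALSE)
  fs <- as.numeric(m[2])
  channels <- strsplit(m[3], ",", fixed = TRUE)[[1]]
  body <- readLines(con)
  body <- body[nzchar(body)]
  if (!length(body)) stop("fixture-csv has no samples: ", path, call. = FALSE)
  vals <- strsplit(body, ",", fixed = TRUE)
  ncol_seen <- lengths(vals)
  if (any(ncol_seen != length(channels)))
    stop("fixture-csv row width does not match declared channel count",
         call. = FALSE)
  data <- matrix(as.numeric(unlist(vals)), nrow = length(body),
                 ncol = length(channels), byrow = TRUE)
  recording(data, fs, channels)
}

# ---- EDF (16-bit, 1-second data records) -----------------------------------

pad_field <- function(x, width) {
  s <- substr(as.character(x), 1L, width)
  formatC(s, width = width, flag = "-")
}

write_edf <- function(rec, path) {
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  ns <- ncol(rec$data)
  n <- nrow(rec$data)
  nrec <- ceiling(n / fs)
  npad <- nrec * fs - n
  data <- rbind(rec$data,
                matrix(0, nrow = npad, ncol = ns))
  pmax_ <- apply(abs(data), 2L, max)
  pmax_[pmax_ == 0] <- 1
  pmax_ <- signif(pmax_ * 1.0001, 6)
  con <- file(path, open = "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8),
    pad_field("X X X X", 80),
    pad_field("Startdate X X X X", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (1 + ns), 8),
    pad_field("", 44),
    pad_field(nrec, 8),
    pad_field("1", 8),
    pad_field(ns, 4),
    paste(vapply(rec$channel_names, pad_field, character(1), width = 16),
          collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field("uV", 8), ns), collapse = ""),
    paste(vapply(-pmax_, pad_field, character(1), width = 8), collapse = ""),
    paste(vapply(pmax_, pad_field, character(1), width = 8), collapse = ""),
    paste(rep(pad_field("-32768", 8), ns), collapse = ""),
    paste(rep(pad_field("32767", 8), ns), collapse = ""),
    paste(rep(pad_field("", 80), ns), collapse = ""),
    paste(rep(pad_field(fs, 8), ns), collapse = ""),
    paste(rep(pad_field("", 32), ns), collapse = ""))
  writeChar(hdr, con, eos = NULL)
  scale <- (2 * pmax_) / (32767 - (-32768))
  for (r in seq_len(nrec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    for (ch in seq_len(ns)) {
      dig <- round((data[idx, ch] - (-pmax_[ch])) / scale[ch]) - 32768
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2L, endian = "little")
    }
  }
}

read_edf <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  rd <- function(w) {
    trimws(rawToChar(readBin(con, "raw", w)))
  }
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                      # header bytes
  rd(44)
  nrec <- suppressWarnings(as.integer(rd(8)))
  recdur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (anyNA(c(nrec, recdur, ns)) || ns < 1 || nrec < 1 || recdur <= 0)
    stop("not a valid EDF header (truncated or corrupt)", call. = FALSE)
  labels <- vapply(seq_len(ns), function(i) rd(16), character(1))
  for (i in seq_len(ns)) rd(80)          # transducer
  for (i in seq_len(ns)) rd(8)           # phys dim
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  dmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(ns)) rd(80)          # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), integer(1))
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("EDF reader supports a single sampling rate across channels",
         call. = FALSE)
  fs <- spr[1] / recdur
  out <- matrix(NA_real_, nrow = nrec * spr[1], ncol = ns)
  scale <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(nrec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(dig) != spr[ch])
        stop("EDF data truncated: header declares more records than present",
             call. = FALSE)
      idx <- ((r - 1L) * spr[ch] + 1L):(r * spr[ch])
      out[idx, ch] <- (dig - dmin_[ch]) * scale[ch] + pmin_[ch]
    }
  }
  recording(out, fs, labels)
}

# ---- BrainVision (.vhdr + multiplexed binary .eeg) -------------------------

parse_vhdr <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section <- ""
  kv <- list()
  for (ln in lines) {
    ln <- sub(";.*$", "", ln)
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      kv[[section]] <- list()
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq > 0 && nzchar(section)) {
      key <- trimws(substr(ln, 1L, eq - 1L))
      val <- trimws(substr(ln, eq + 1L, nchar(ln)))
      kv[[section]][[key]] <- val
    }
  }
  kv
}

read_brainvision <- function(vhdr_path) {
  kv <- parse_vhdr(vhdr_path)
  ci <- kv[["Common Infos"]]
  bi <- kv[["Binary Infos"]]
  chi <- kv[["Channel Infos"]]
  if (is.null(ci)) stop("not a BrainVision header: ", vhdr_path, call. = FALSE)
  if (!identical(toupper(ci$DataFormat), "BINARY"))
    stop("only BINARY BrainVision data supported", call. = FALSE)
  if (!identical(toupper(ci$DataOrientation), "MULTIPLEXED"))
    stop("only MULTIPLEXED BrainVision data supported", call. = FALSE)
  nchan <- as.integer(ci$NumberOfChannels)
  fs <- 1e6 / as.numeric(ci$SamplingInterval)
  fmt <- toupper(bi$BinaryFormat)
  chdefs <- lapply(seq_len(nchan), function(i) {
    v <- chi[[sprintf("Ch%d", i)]]
    if (is.null(v)) stop("missing Ch", i, " in Channel Infos", call. = FALSE)
    parts <- strsplit(v, ",", fixed = TRUE)[[1]]
    res <- if (length(parts) >= 3 && nzchar(parts[3])) as.numeric(parts[3]) else 1
    list(name = parts[1], resolution = res)
  })
  datafile <- file.path(dirname(vhdr_path), ci$DataFile)
  nbytes <- file.size(datafile)
  con <- file(datafile, open = "rb")
  on.exit(close(con))
  if (fmt == "IEEE_FLOAT_32") {
    nval <- nbytes %/% 4L
    raw <- readBin(con, "numeric", n = nval, size = 4L, endian = "little")
  } else if (fmt == "INT_16") {
    nval <- nbytes %/% 2L
    raw <- readBin(con, "integer", n = nval, size = 2L, signed = TRUE,
                   endian = "little")
  } else stop("unsupported BinaryFormat: ", fmt, call. = FALSE)
  if (nval %% nchan != 0L)
    stop("BrainVision data size is not a multiple of the channel count ",
         "declared in the header", call. = FALSE)
  nsamp <- nval %/% nchan
  data <- matrix(raw, nrow = nsamp, ncol = nchan, byrow = TRUE)
  res <- vapply(chdefs, `[[`, numeric(1), "resolution")
  data <- sweep(data, 2L, res, `*`)
  labels <- vapply(chdefs, `[[`, character(1), "name")
  recording(data, fs, labels)
}

# Internal: write a BrainVision pair (.vhdr/.eeg, IEEE_FLOAT_32 multiplexed)
# for building read-back fixtures at test time.
write_brainvision <- function(rec, basepath) {
  eegfile <- paste0(basename(basepath), ".eeg")
  vhdr <- paste0(basepath, ".vhdr")
  lines <- c(
    "Brain Vision Data Exchange Header File Version 1.0",
    "[Common Infos]",
    paste0("DataFile=", eegfile),
    "DataFormat=BINARY",
    "DataOrientation=MULTIPLEXED",
    paste0("NumberOfChannels=", ncol(rec$data)),
    paste0("SamplingInterval=", format_full(1e6 / rec$fs)),
    "[Binary Infos]",
    "BinaryFormat=IEEE_FLOAT_32",
    "[Channel Infos]",
    sprintf("Ch%d=%s,,1,µV", seq_along(rec$channel_names),
            rec$channel_names))
  writeLines(lines, vhdr, useBytes = TRUE)
  con <- file(paste0(basepath, ".eeg"), open = "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(rec$data)), con, size = 4L, endian = "little")
  invisible(vhdr)
}
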