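## Minimal RIFF/WAVE reader and writer: multi-channel, PCM 16-bit or IEEE
## float 32-bit, which covers what the recording hardware and the simulator
## produce. Samples are held as a numeric matrix (samples x channels) in
## [-1, 1].

#' Write a multi-channel WAV file
#'
#' @param samples numeric matrix, samples x channels, values in `[-1, 1]`
#'   (a vector is treated as one channel).
#' @param path output file path.
#' @param sample_rate sampling rate in Hz.
#' @param bits 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, path, sample_rate = 384000, bits = 32) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  storage.mode(samples) <- "double"
  nch <- ncol(samples)
  n <- nrow(samples)
  if (!bits %in% c(16L, 32L)) stopf("bits must be 16 or 32")
  fmt_code <- if (bits == 32) 3L else 1L   # 3 = IEEE float, 1 = PCM
  block_align <- nch * bits / 8
  data_bytes <- n * block_align
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x, size) writeBin(as.integer(x), con, size = size, endian = "little")
  writeChar("RIFF", con, eos = NULL)
  wi(36 + data_bytes, 4)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  wi(16, 4); wi(fmt_code, 2); wi(nch, 2); wi(sample_rate, 4)
  wi(sample_rate * block_align, 4); wi(block_align, 2); wi(bits, 2)
  writeChar("data", con, eos = NULL)
  wi(data_bytes, 4)
  inter <- as.numeric(t(samples))          # interleave channels
  if (bits == 32) {
    writeBin(inter, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(pmin(pmax(inter, -1), 1) * 32767)), con,
             size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a WAV file
#'
#' @param path WAV file path (PCM 16-bit or IEEE float 32-bit).
#' @return list with `samples` (numeric matrix, samples x channels, in
#'   `[-1, 1]`) and `sample_rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(size, signed = TRUE)
    readBin(con, "integer", n = 1, size = size, endian = "little", signed = signed)
  if (readChar(con, 4) != "RIFF") stopf("%s: not a RIFF file", path)
  ri(4)
  if (readChar(con, 4) != "WAVE") stopf("%s: not a WAVE file", path)
  fmt <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- ri(4)
    if (id == "fmt ") {
      fmt <- list(code = ri(2), nch = ri(2), rate = ri(4))
      ri(4); ri(2)
      fmt$bits <- ri(2)
      if (size > 16) readBin(con, "raw", n = size - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stopf("%s: data chunk before fmt chunk", path)
      nsamp <- size / (fmt$bits / 8)
      raw_vals <- if (fmt$code == 3 && fmt$bits == 32) {
        readBin(con, "double", n = nsamp, size = 4, endian = "little")
      } else if (fmt$code == 1 && fmt$bits == 16) {
        readBin(con, "integer", n = nsamp, size = 2, endian = "little",
                signed = TRUE) / 32767
      } else {
        stopf("%s: unsupported WAV format (code %d, %d bits)",
              path, fmt$code, fmt$bits)
      }
      samples <- t(matrix(raw_vals, nrow = fmt$nch))
      break
    } else {
      readBin(con, "raw", n = size + size %% 2)
    }
  }
  if (is.null(samples)) stopf("%s: no data chunk found", path)
  list(samples = samples, sample_rate = fmt$rate)
}
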