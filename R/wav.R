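#' Write a mono WAV file
#'
#' Minimal RIFF/WAVE writer. The default encoding is 32-bit IEEE float, which
#' stores rendered samples without quantization confounds (values outside
#' +/-1 are legal); `"pcm16"` writes 16-bit integer PCM and refuses to clip:
#' samples with `|x| > 1` raise an error naming the peak unless the waveform
#' is normalized first.
#'
#' @param waveform An `stm_waveform` or numeric vector.
#' @param path Output file path.
#' @param sample_rate Required when `waveform` is a bare vector.
#' @param format `"float32"` or `"pcm16"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(waveform, path, sample_rate = NULL,
                      format = c("float32", "pcm16")) {
  format <- match.arg(format)
  if (inherits(waveform, "stm_waveform")) {
    x <- waveform$samples
    sample_rate <- waveform$sample_rate
  } else {
    x <- as.numeric(waveform)
    if (is.null(sample_rate)) stop_domain("'sample_rate' required")
  }
  sr <- as.integer(round(sample_rate))
  n <- length(x)
  bytes_per_sample <- if (format == "float32") 4L else 2L
  data_size <- n * bytes_per_sample
  fmt_code <- if (format == "float32") 3L else 1L
  bits <- bytes_per_sample * 8L

  if (format == "pcm16" && max(abs(x)) > 1)
    stop_domain(
      "peak %.4g exceeds full scale for 16-bit PCM; normalize first",
      max(abs(x)))

  con <- file(path, "wb")
  on.exit(close(con))
  wr_str <- function(s) writeChar(s, con, eos = NULL)
  wr_u32 <- function(v) writeBin(as.integer(v), con, size = 4,
                                 endian = "little")
  wr_u16 <- function(v) writeBin(as.integer(v), con, size = 2,
                                 endian = "little")
  # fact chunk (required for non-PCM formats)
  fact_size <- if (format == "float32") 12L else 0L
  wr_str("RIFF"); wr_u32(4L + 24L + fact_size + 8L + data_size); wr_str("WAVE")
  wr_str("fmt "); wr_u32(16L)
  wr_u16(fmt_code); wr_u16(1L)            # format, channels
  wr_u32(sr); wr_u32(sr * bytes_per_sample)
  wr_u16(bytes_per_sample); wr_u16(bits)  # block align, bits/sample
  if (format == "float32") { wr_str("fact"); wr_u32(4L); wr_u32(n) }
  wr_str("data"); wr_u32(data_size)
  if (format == "float32") {
    writeBin(x, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(round(x * 32767)), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read a mono WAV file
#'
#' Reads files written by [write_wav()] (and other mono float32/PCM16 WAVs),
#' skipping unknown chunks. PCM samples are rescaled to `[-1, 1]`.
#'
#' @param path WAV file path.
#' @return List with `samples`, `sample_rate` and `format`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(k) readChar(con, k, useBytes = TRUE)
  rd_u32 <- function() readBin(con, integer(), size = 4, endian = "little")
  rd_u16 <- function() readBin(con, integer(), size = 2, endian = "little",
                               signed = FALSE)
  if (rd_str(4) != "RIFF") stop_domain("not a RIFF file: %s", path)
  rd_u32()
  if (rd_str(4) != "WAVE") stop_domain("not a WAVE file: %s", path)
  fmt_code <- NULL; sr <- NULL; bits <- NULL; samples <- NULL
  repeat {
    id <- rd_str(4)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- rd_u32()
    if (id == "fmt ") {
      fmt_code <- rd_u16(); ch <- rd_u16()
      sr <- rd_u32(); rd_u32(); rd_u16(); bits <- rd_u16()
      if (ch != 1L) stop_domain("only mono WAV is supported")
      if (size > 16) readBin(con, raw(), size - 16)
    } else if (id == "data") {
      if (is.null(fmt_code)) stop_domain("malformed WAV: data before fmt")
      if (fmt_code == 3L && bits == 32L) {
        samples <- readBin(con, numeric(), n = size / 4, size = 4,
                           endian = "little")
        format <- "float32"
      } else if (fmt_code == 1L && bits == 16L) {
        samples <- readBin(con, integer(), n = size / 2, size = 2,
                           endian = "little") / 32767
        format <- "pcm16"
      } else stop_domain("unsupported WAV encoding (format %d, %d bit)",
                         fmt_code, bits)
      if (size %% 2 == 1) readBin(con, raw(), 1)
    } else {
      readBin(con, raw(), size + size %% 2)
    }
    if (!is.null(samples)) break
  }
  if (is.null(samples)) stop_domain("no data chunk found in %s", path)
  list(samples = samples, sample_rate = sr, format = format)
}
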