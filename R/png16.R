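# Minimal 16-bit grayscale PNG writer. Deflate comes from memCompress()
# (zlib/RFC-1950 stream, as PNG's IDAT requires); chunk CRC32 is computed
# here since base R does not expose one.

crc32_table <- local({
  tab <- integer(256)
  poly <- -306674912L  # 0xEDB88320 as signed 32-bit
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(poly, bitwShiftR(c, 1L))
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[i + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  c <- -1L
  ints <- as.integer(bytes)
  for (b in ints) {
    c <- bitwXor(crc32_table[bitwAnd(bitwXor(c, b), 255L) + 1L],
                 bitwShiftR(c, 8L))
  }
  bitwXor(c, -1L)
}

png_chunk <- function(type, payload) {
  body <- c(charToRaw(type), payload)
  c(writeBin(length(payload), raw(), size = 4, endian = "big"),
    body,
    writeBin(crc32(body), raw(), size = 4, endian = "big"))
}

# vals: integer matrix (rows = image rows, top to bottom) in [0, 65535]
write_png16 <- function(vals, path) {
  h <- nrow(vals); w <- ncol(vals)
  ihdr <- c(writeBin(as.integer(c(w, h)), raw(), size = 4, endian = "big"),
            as.raw(c(16, 0, 0, 0, 0)))  # bit depth 16, grayscale
  rows <- lapply(seq_len(h), function(r) {
    c(as.raw(0), writeBin(as.integer(vals[r, ]), raw(), size = 2, endian = "big"))
  })
  idat <- memCompress(unlist(rows), type = "gzip")
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           png_chunk("IHDR", ihdr),
           png_chunk("IDAT", idat),
           png_chunk("IEND", raw(0)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}
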