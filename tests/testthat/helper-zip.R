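# Minimal STORE-method zip writer used to build archive fixtures at test
# time (no external zip tool needed). CRC32 is recovered from the trailer
# of a gzip stream produced by memCompress.

crc32_raw <- function(data) {
  gz <- memCompress(data, type = "gzip")
  n <- length(gz)
  gz[(n - 7):(n - 4)]
}

int_le <- function(x, size) writeBin(as.integer(x), raw(), size = size,
                                     endian = "little")

make_store_zip <- function(path, members) {
  # members: named list of character vectors (file name -> lines)
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(0)
  central <- raw(0)
  pos <- 0L
  for (nm in names(members)) {
    data <- charToRaw(paste0(paste(members[[nm]], collapse = "\n"), "\n"))
    crc <- crc32_raw(data)
    fname <- charToRaw(nm)
    hdr <- c(charToRaw("PK\x03\x04"), int_le(20, 2), int_le(0, 2),
             int_le(0, 2), int_le(0, 2), int_le(0, 2), crc,
             int_le(length(data), 4), int_le(length(data), 4),
             int_le(length(fname), 2), int_le(0, 2), fname)
    writeBin(hdr, con)
    writeBin(data, con)
    cd <- c(charToRaw("PK\x01\x02"), int_le(20, 2), int_le(20, 2),
            int_le(0, 2), int_le(0, 2), int_le(0, 2), int_le(0, 2), crc,
            int_le(length(data), 4), int_le(length(data), 4),
            int_le(length(fname), 2), int_le(0, 2), int_le(0, 2),
            int_le(0, 2), int_le(0, 2), int_le(0, 4), int_le(pos, 4), fname)
    central <- c(central, cd)
    pos <- pos + length(hdr) + length(data)
  }
  writeBin(central, con)
  eocd <- c(charToRaw("PK\x05\x06"), int_le(0, 2), int_le(0, 2),
            int_le(length(members), 2), int_le(length(members), 2),
            int_le(length(central), 4), int_le(pos, 4), int_le(0, 2))
  writeBin(eocd, con)
  invisible(path)
}
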