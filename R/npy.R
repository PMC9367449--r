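# Minimal reader/writer for 1-D numpy ".npy" arrays and ".npz" containers
# (a zip of .npy members). Covers exactly what per-cell tracker exports need:
# little-endian f8/f4/i4/i8 vectors. Writing always emits f8, stored (no
# compression) zip entries with correct CRC32 so any unzip tool accepts them.

npy_read <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 6L)
  if (length(magic) < 6L || !identical(rawToChar(magic[2:6]), "NUMPY")) {
    abort(sprintf("'%s' is not a numpy array file.", path))
  }
  ver <- readBin(con, "raw", n = 2L)
  hlen <- if (as.integer(ver[1]) >= 2L) {
    readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  } else {
    readBin(con, "integer", n = 1L, size = 2L, signed = FALSE, endian = "little")
  }
  header <- rawToChar(readBin(con, "raw", n = hlen))
  descr <- sub(".*'descr'\\s*:\\s*'([^']+)'.*", "\\1", header)
  shape_txt <- sub(".*'shape'\\s*:\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape_txt), ",")[[1]])
  dims <- dims[!is.na(dims)]
  n <- if (length(dims) == 0L) 1L else prod(dims)
  if (length(dims) > 1L) {
    abort(sprintf("'%s': only 1-D arrays are supported (shape (%s)).", path, shape_txt))
  }
  out <- switch(descr,
    "<f8" = readBin(con, "numeric", n = n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "numeric", n = n, size = 4L, endian = "little"),
    "<i4" = as.numeric(readBin(con, "integer", n = n, size = 4L, endian = "little")),
    "<i8" = {
      words <- readBin(con, "integer", n = 2L * n, size = 4L, endian = "little")
      lo <- words[seq(1L, 2L * n, by = 2L)]
      hi <- words[seq(2L, 2L * n, by = 2L)]
      # frame/coordinate magnitudes fit in a double exactly
      (lo + ifelse(lo < 0, 2^32, 0)) + hi * 2^32
    },
    abort(sprintf("'%s': unsupported dtype '%s'.", path, descr))
  )
  if (length(out) != n) abort(sprintf("'%s': truncated array payload.", path))
  out
}

npy_write <- function(x, path) {
  payload <- writeBin(as.numeric(x), raw(), size = 8L, endian = "little")
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d,), }", length(x))
  # total preamble (10 bytes + header) padded to a multiple of 64, newline-terminated
  total <- 10L + nchar(header) + 1L
  pad <- (64L - total %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1L, 0L))), con)
  writeBin(nchar(header), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(payload, con)
  invisible(path)
}

crc32_table <- local({
  tab <- integer(256L)
  for (i in 0:255) {
    c <- i
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), -306674912L) # 0xEDB88320
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[i + 1L] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  for (b in as.integer(bytes)) {
    crc <- bitwXor(bitwShiftR(crc, 8L), crc32_table[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  }
  bitwXor(crc, -1L)
}

# Write a zip archive of stored (uncompressed) members. `members` is a named
# list of raw vectors; names are member file names.
zip_write_stored <- function(members, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  u32 <- function(v) writeBin(as.integer(v), con, size = 4L, endian = "little")
  u16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  offsets <- integer(length(members))
  crcs <- integer(length(members))
  pos <- 0L
  for (i in seq_along(members)) {
    name <- charToRaw(names(members)[i])
    data <- members[[i]]
    crcs[i] <- crc32(data)
    offsets[i] <- pos
    writeBin(charToRaw("PK\003\004"), con)
    u16(20L); u16(0L); u16(0L); u16(0L); u16(33L) # version, flags, method=stored, time, date
    u32(crcs[i]); u32(length(data)); u32(length(data))
    u16(length(name)); u16(0L)
    writeBin(name, con)
    writeBin(data, con)
    pos <- pos + 30L + length(name) + length(data)
  }
  cd_start <- pos
  for (i in seq_along(members)) {
    name <- charToRaw(names(members)[i])
    data <- members[[i]]
    writeBin(charToRaw("PK\001\002"), con)
    u16(20L); u16(20L); u16(0L); u16(0L); u16(0L); u16(33L)
    u32(crcs[i]); u32(length(data)); u32(length(data))
    u16(length(name)); u16(0L); u16(0L); u16(0L); u16(0L)
    u32(0L); u32(offsets[i])
    writeBin(name, con)
    pos <- pos + 46L + length(name)
  }
  writeBin(charToRaw("PK\005\006"), con)
  u16(0L); u16(0L); u16(length(members)); u16(length(members))
  u32(pos - cd_start); u32(cd_start); u16(0L)
  invisible(path)
}

# Read all members of an npz container into a named list of numeric vectors.
npz_read <- function(path) {
  exdir <- tempfile("npz_")
  dir.create(exdir)
  on.exit(unlink(exdir, recursive = TRUE))
  files <- utils::unzip(path, exdir = exdir)
  if (length(files) == 0L) abort(sprintf("'%s' is not a readable npz container.", path))
  out <- lapply(files, npy_read)
  names(out) <- sub("\\.npy$", "", basename(files))
  out
}

# Write named numeric vectors as an npz container (zip of f8 .npy members).
npz_write <- function(arrays, path) {
  stopifnot(is.list(arrays), !is.null(names(arrays)), all(nzchar(names(arrays))))
  members <- lapply(arrays, function(x) {
    tmp <- tempfile(fileext = ".npy")
    on.exit(unlink(tmp))
    npy_write(x, tmp)
    readBin(tmp, "raw", n = file.size(tmp))
  })
  names(members) <- paste0(names(arrays), ".npy")
  zip_write_stored(members, path)
  invisible(path)
}
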