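# Minimal deterministic ZIP writer.
#
# Entries are written in the order given, with a fixed DOS timestamp, so
# the archive is byte-identical for identical content — a property the
# report bundle relies on for reproducibility.  Compression is DEFLATE:
# memCompress() emits a zlib stream, whose 2-byte header and 4-byte
# Adler-32 trailer are stripped to obtain the raw deflate data a ZIP
# member stores; CRC-32 comes from digest.  Archives are readable with
# utils::unzip().

# fixed timestamp for all members: 2020-01-01 00:00:00 (DOS encoding)
DOS_DATE <- bitwOr(bitwOr(bitwShiftL(2020L - 1980L, 9L), bitwShiftL(1L, 5L)), 1L)
DOS_TIME <- 0L

le_bytes <- function(value, n) {
  as.raw(floor(value / 256^(0:(n - 1))) %% 256)
}

crc32_of <- function(data) {
  hex <- digest::digest(data, algo = "crc32", serialize = FALSE)
  hex <- sprintf("%8s", hex)
  hex <- gsub(" ", "0", hex)
  strtoi(substr(hex, 1, 4), 16L) * 65536 + strtoi(substr(hex, 5, 8), 16L)
}

raw_deflate <- function(data) {
  z <- memCompress(data, type = "gzip")  # zlib stream despite the name
  z[3:(length(z) - 4L)]
}

#' Create a ZIP archive (pure R, deterministic)
#'
#' Writes the given files into a ZIP archive with DEFLATE compression,
#' fixed member timestamps and the exact member order given, so a fixed
#' input always produces a byte-identical archive.  Member names ending
#' in `/` are stored as directory entries.
#'
#' @param zipfile Output path.
#' @param members Character vector of member names (relative paths, `/`
#'   separators; trailing `/` marks a directory).
#' @param root Directory against which file members are resolved.
#' @return `zipfile`, invisibly.
#' @seealso [zip_inventory()]
#' @export
zip_create <- function(zipfile, members, root = ".") {
  con <- file(zipfile, "wb")
  on.exit(close(con), add = TRUE)

  offsets <- integer(length(members))
  crcs <- numeric(length(members))
  csizes <- integer(length(members))
  usizes <- integer(length(members))
  methods <- integer(length(members))
  offset <- 0L

  payloads <- vector("list", length(members))
  for (i in seq_along(members)) {
    name <- members[i]
    if (grepl("/$", name)) {
      data <- raw(0)
      comp <- raw(0)
      methods[i] <- 0L
    } else {
      path <- file.path(root, name)
      if (!file.exists(path)) stop("bundle member missing: ", path, call. = FALSE)
      data <- readBin(path, "raw", file.info(path)$size)
      comp <- raw_deflate(data)
      methods[i] <- 8L
      if (length(comp) >= length(data)) {  # incompressible: store
        comp <- data
        methods[i] <- 0L
      }
    }
    crcs[i] <- if (length(data)) crc32_of(data) else 0
    csizes[i] <- length(comp)
    usizes[i] <- length(data)
    payloads[[i]] <- comp

    nm <- charToRaw(name)
    header <- c(
      le_bytes(0x04034b50, 4), le_bytes(20, 2), le_bytes(0, 2),
      le_bytes(methods[i], 2), le_bytes(DOS_TIME, 2), le_bytes(DOS_DATE, 2),
      le_bytes(crcs[i], 4), le_bytes(csizes[i], 4), le_bytes(usizes[i], 4),
      le_bytes(length(nm), 2), le_bytes(0, 2), nm
    )
    writeBin(header, con)
    if (length(comp)) writeBin(comp, con)
    offsets[i] <- offset
    offset <- offset + length(header) + length(comp)
  }

  cd_start <- offset
  cd_size <- 0L
  for (i in seq_along(members)) {
    nm <- charToRaw(members[i])
    ext_attr <- if (grepl("/$", members[i])) 0x10 else 0
    entry <- c(
      le_bytes(0x02014b50, 4), le_bytes(20, 2), le_bytes(20, 2),
      le_bytes(0, 2), le_bytes(methods[i], 2),
      le_bytes(DOS_TIME, 2), le_bytes(DOS_DATE, 2),
      le_bytes(crcs[i], 4), le_bytes(csizes[i], 4), le_bytes(usizes[i], 4),
      le_bytes(length(nm), 2), le_bytes(0, 2), le_bytes(0, 2),
      le_bytes(0, 2), le_bytes(0, 2), le_bytes(ext_attr, 4),
      le_bytes(offsets[i], 4), nm
    )
    writeBin(entry, con)
    cd_size <- cd_size + length(entry)
  }
  eocd <- c(
    le_bytes(0x06054b50, 4), le_bytes(0, 2), le_bytes(0, 2),
    le_bytes(length(members), 2), le_bytes(length(members), 2),
    le_bytes(cd_size, 4), le_bytes(cd_start, 4), le_bytes(0, 2)
  )
  writeBin(eocd, con)
  invisible(zipfile)
}

#' List the members of a ZIP archive
#'
#' @param zipfile Archive path.
#' @return Character vector of member names in archive order.
#' @export
zip_inventory <- function(zipfile) {
  utils::unzip(zipfile, list = TRUE)$Name
}
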