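# Minimal FCS 3.0/3.1 reader.
#
# Supports list-mode ($MODE/L) files with float ($DATATYPE/F), double (/D)
# or unsigned integer (/I, 8/16/32 bit) events and a constant byte order.
# No compensation, gating or transformation is applied: the reader returns
# raw event values exactly as stored. Writing FCS is out of scope.

#' Read an FCS 3.0/3.1 file
#'
#' @param path path to an FCS file
#' @return a list with `data` (events x channels numeric matrix, column
#'   names = `$PnN` short channel names), `channels` (character vector) and
#'   `keywords` (named character vector of the TEXT segment)
#' @export
read_fcs <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58, useBytes = TRUE)
  version <- substr(header, 1, 6)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("parse error: unsupported FCS version '", version,
      "' (FCS 3.0/3.1 only)",
      call. = FALSE
    )
  }
  offs <- function(a, b) as.numeric(trimws(substr(header, a, b)))
  text_start <- offs(11, 18)
  text_end <- offs(19, 26)
  data_start <- offs(27, 34)
  data_end <- offs(35, 42)

  seek(con, text_start)
  text_raw <- readChar(con, text_end - text_start + 1, useBytes = TRUE)
  delim <- substr(text_raw, 1, 1)
  parts <- strsplit(substr(text_raw, 2, nchar(text_raw)), delim,
    fixed = TRUE
  )[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  kw <- setNames(
    parts[seq(2, length(parts), by = 2)],
    toupper(trimws(parts[seq(1, length(parts), by = 2)]))
  )

  need <- function(key) {
    if (!key %in% names(kw)) {
      stop("parse error: FCS TEXT segment lacks required keyword ", key,
        call. = FALSE
      )
    }
    kw[[key]]
  }
  n_par <- as.integer(need("$PAR"))
  n_tot <- as.integer(need("$TOT"))
  dtype <- toupper(need("$DATATYPE"))
  byteord <- need("$BYTEORD")
  mode <- toupper(need("$MODE"))
  if (mode != "L") {
    stop("parse error: only list-mode ($MODE/L) FCS data is supported",
      call. = FALSE
    )
  }
  endian <- if (identical(byteord, "1,2,3,4")) "little" else "big"

  bits <- vapply(seq_len(n_par), function(i) {
    as.integer(need(sprintf("$P%dB", i)))
  }, integer(1))
  channels <- vapply(seq_len(n_par), function(i) {
    nm <- kw[[sprintf("$P%dN", i)]]
    if (is.null(nm) || !nzchar(nm)) sprintf("P%d", i) else nm
  }, character(1))

  if (data_start == 0 || data_end == 0) {
    data_start <- as.numeric(need("$BEGINDATA"))
    data_end <- as.numeric(need("$ENDDATA"))
  }
  seek(con, data_start)

  if (dtype %in% c("F", "D")) {
    size <- if (dtype == "F") 4L else 8L
    if (any(bits != size * 8L)) {
      stop("parse error: $PnB inconsistent with $DATATYPE", call. = FALSE)
    }
    vals <- readBin(con, "double",
      n = n_par * n_tot, size = size,
      endian = endian
    )
  } else if (dtype == "I") {
    if (length(unique(bits)) != 1 || !bits[1] %in% c(8L, 16L, 32L)) {
      stop("parse error: integer FCS data requires uniform $PnB of 8, 16 or 32",
        call. = FALSE
      )
    }
    size <- bits[1] / 8L
    if (size == 4L) {
      vals <- readBin(con, "integer", n = n_par * n_tot, size = 4L,
        endian = endian
      )
      vals <- as.numeric(vals)
      vals[vals < 0] <- vals[vals < 0] + 4294967296
    } else {
      vals <- as.numeric(readBin(con, "integer",
        n = n_par * n_tot,
        size = size, signed = FALSE, endian = endian
      ))
    }
  } else {
    stop("parse error: unsupported $DATATYPE '", dtype, "'", call. = FALSE)
  }
  if (length(vals) != n_par * n_tot) {
    stop("parse error: FCS data segment truncated (expected ",
      n_par * n_tot, " values, read ", length(vals), ")",
      call. = FALSE
    )
  }
  mat <- matrix(vals, nrow = n_tot, ncol = n_par, byrow = TRUE)
  colnames(mat) <- channels
  list(data = mat, channels = channels, keywords = kw)
}
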