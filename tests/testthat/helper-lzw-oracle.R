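# Independent pure-R decoder for Unix compress (.Z) streams, written from
# the format description (LSB-first codes, widths 9..16, block-mode CLEAR,
# code groups padded to n_bits bytes per width segment). Used as an oracle
# for the package coder; kept free of any shared code.
lzw_oracle_decompress <- function(z) {
  stopifnot(is.raw(z), length(z) >= 3,
            z[1] == as.raw(0x1F), z[2] == as.raw(0x9D))
  flags <- as.integer(z[3])
  maxbits <- bitwAnd(flags, 0x1F)
  block <- bitwAnd(flags, 0x80) != 0L
  payload <- as.integer(z[-(1:3)])
  total_bits <- 8L * length(payload)
  n_bits <- 9L
  maxmax <- bitwShiftL(1L, maxbits)
  maxcode <- bitwShiftL(1L, n_bits) - 1L
  free_ent <- if (block) 257L else 256L
  prefix <- integer(maxmax)
  suffix <- integer(maxmax)
  suffix[1:256] <- 0:255
  posbits <- 0L
  seg_start <- 0L
  oldcode <- -1L
  finchar <- 0L
  out <- integer(0)

  get_code <- function() {
    if (posbits + n_bits > total_bits) return(-1L)
    b <- posbits %/% 8L
    chunk <- payload[b + 1L]
    if (b + 2L <= length(payload)) chunk <- chunk + payload[b + 2L] * 256L
    if (b + 3L <= length(payload)) chunk <- chunk + payload[b + 3L] * 65536L
    code <- bitwAnd(bitwShiftR(chunk, posbits %% 8L),
                    bitwShiftL(1L, n_bits) - 1L)
    posbits <<- posbits + n_bits
    code
  }
  realign <- function() {
    g <- n_bits * 8L
    rel <- posbits - seg_start
    posbits <<- seg_start + ((rel + g - 1L) %/% g) * g
    seg_start <<- posbits
  }

  repeat {
    if (free_ent > maxcode) {
      realign()
      n_bits <- n_bits + 1L
      maxcode <- if (n_bits == maxbits) maxmax else bitwShiftL(1L, n_bits) - 1L
    }
    code <- get_code()
    if (code < 0L) break
    if (oldcode == -1L) {
      finchar <- oldcode <- code
      out <- c(out, code)
      next
    }
    if (code == 256L && block) {
      free_ent <- 257L
      realign()
      n_bits <- 9L
      maxcode <- bitwShiftL(1L, n_bits) - 1L
      code <- get_code()
      if (code < 0L) break
      finchar <- oldcode <- code
      out <- c(out, code)
      next
    }
    incode <- code
    stack <- integer(0)
    if (code >= free_ent) {            # KwKwK
      stopifnot(code == free_ent)
      stack <- finchar
      code <- oldcode
    }
    while (code >= 256L) {
      stack <- c(stack, suffix[code + 1L])
      code <- prefix[code + 1L]
    }
    finchar <- suffix[code + 1L]
    stack <- c(stack, finchar)
    out <- c(out, rev(stack))
    if (free_ent < maxmax) {
      prefix[free_ent + 1L] <- oldcode
      suffix[free_ent + 1L] <- finchar
      free_ent <- free_ent + 1L
    }
    oldcode <- incode
  }
  as.raw(out)
}

# reference system decoder (the gzip/uncompress codebase understands .Z)
reference_uncompress <- function(z) {
  f <- tempfile(fileext = ".Z")
  on.exit(unlink(c(f, out)), add = TRUE)
  writeBin(z, f)
  out <- tempfile()
  status <- suppressWarnings(
    system2("gzip", c("-dc", shQuote(f)), stdout = out, stderr = FALSE)
  )
  if (!identical(status, 0L)) return(NULL)
  readBin(out, "raw", n = file.size(out))
}
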