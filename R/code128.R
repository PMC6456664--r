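## Code 128 module-width patterns, values 0..106 (index value + 1).
## Each of values 0..102 is 6 widths (3 bars + 3 spaces, 11 modules, even
## number of bar modules); 103..105 are the start codes; 106 is the stop
## pattern (7 widths, 13 modules, ends on a bar).
CODE128_PATTERNS <- c(
  "212222", "222122", "222221", "121223", "121322", "131222", "122213",
  "122312", "132212", "221213", "221312", "231212", "112232", "122132",
  "122231", "113222", "123122", "123221", "223211", "221132", "221231",
  "213212", "223112", "312131", "311222", "321122", "321221", "312212",
  "322112", "322211", "212123", "212321", "232121", "111323", "131123",
  "131321", "112313", "132113", "132311", "211313", "231113", "231311",
  "112133", "112331", "132131", "113123", "113321", "133121", "313121",
  "211331", "231131", "213113", "213311", "213131", "311123", "311321",
  "331121", "312113", "312311", "332111", "314111", "221411", "431111",
  "111224", "111422", "121124", "121421", "141122", "141221", "112214",
  "112412", "122114", "122411", "142112", "142211", "241211", "221114",
  "413111", "241112", "134111", "111242", "121142", "121241", "114212",
  "124112", "124211", "411212", "421112", "421211", "212141", "214121",
  "412121", "111143", "111341", "131141", "114113", "114311", "411113",
  "411311", "113141", "114131", "311141", "411131", "211412", "211214",
  "211232", "2331112"
)
CODE128_START_B <- 104L
CODE128_STOP <- 106L

patternWidths <- function(value) {
  as.integer(strsplit(CODE128_PATTERNS[value + 1L], "", fixed = TRUE)[[1L]])
}

#' Encode text as a Code 128 (set B) symbol
#'
#' Produces the standard-conformant symbol for an ASCII payload using code
#' set B only (printable ASCII 32..126, which covers the A/C/G/T tags this
#' package generates): Start-B, one symbol per character, the weighted
#' mod-103 checksum, and the stop pattern. Total module count is 11 per
#' symbol plus 13 for the stop.
#'
#' @param text nonempty ASCII string.
#' @return A \linkS4class{Code128Symbol}.
#' @examples
#' sym <- encodeCode128("AC")
#' sym@values    # 104 33 35 1 106
#' sym@checksum  # (104 + 1*33 + 2*35) %% 103 = 1
#' @export
encodeCode128 <- function(text) {
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    stop("payload must be a single nonempty string")
  codes <- utf8ToInt(text)
  if (any(codes < 32L | codes > 126L))
    stop("character not encodable in Code 128 set B: ",
         intToUtf8(codes[codes < 32L | codes > 126L][1L]))
  values <- codes - 32L
  checksum <- as.integer(
    (CODE128_START_B + sum(seq_along(values) * values)) %% 103L)
  all <- c(CODE128_START_B, values, checksum, CODE128_STOP)
  modules <- unlist(lapply(all, patternWidths))
  new("Code128Symbol", text = text, values = as.integer(all),
      checksum = checksum, modules = as.integer(modules))
}

#' Decode a Code 128 module-width pattern
#'
#' Independent decoder used to round-trip-check the encoder: parses the
#' bar/space width sequence back into symbol values, verifies the start
#' code, stop pattern and checksum, and recovers the set-B payload.
#'
#' @param modules integer vector of alternating bar/space widths (bar
#'   first), as in \code{Code128Symbol@modules}.
#' @return The decoded payload string.
#' @export
decodeCode128 <- function(modules) {
  if (length(modules) < 6L + 6L + 7L || (length(modules) - 7L) %% 6L != 0L)
    stop("module sequence has invalid length")
  nSym <- (length(modules) - 7L) %/% 6L
  stop_w <- modules[(6L * nSym + 1L):length(modules)]
  if (!identical(as.integer(stop_w), patternWidths(CODE128_STOP)))
    stop("invalid stop pattern")
  lookup <- function(w) {
    key <- paste(w, collapse = "")
    v <- match(key, CODE128_PATTERNS) - 1L
    if (is.na(v)) stop("unrecognised symbol pattern: ", key)
    v
  }
  values <- vapply(seq_len(nSym), function(i)
    lookup(modules[(6L * (i - 1L) + 1L):(6L * i)]), integer(1L))
  if (values[1L] != CODE128_START_B)
    stop("symbol does not start with Start B")
  payload <- values[2L:(nSym - 1L)]
  check <- values[nSym]
  expected <- (values[1L] + sum(seq_along(payload) * payload)) %% 103L
  if (check != expected)
    stop(sprintf("checksum mismatch: read %d, computed %d", check, expected))
  if (any(payload > 94L))
    stop("payload contains non-character set-B symbols")
  intToUtf8(payload + 32L)
}

#' Render a Code 128 symbol to SVG or PNG
#'
#' Draws the bar/space pattern with quiet zones of at least 10 modules on
#' each side. SVG output is plain deterministic text (identical input and
#' parameters give byte-identical files) and carries a human-readable text
#' line under the bars by default; PNG output (via \pkg{png}) draws the
#' bars only.
#'
#' @param symbol a \linkS4class{Code128Symbol}.
#' @param path output file path.
#' @param format \code{"svg"} or \code{"png"}.
#' @param moduleWidth width of one module in pixels.
#' @param height bar height in pixels.
#' @param quietZone quiet zone width in modules (>= 10).
#' @param showText include the payload as a text line (SVG only).
#' @return \code{path}, invisibly.
#' @examples
#' f <- tempfile(fileext = ".svg")
#' renderBarcode(encodeCode128("ACGT"), f)
#' @export
renderBarcode <- function(symbol, path, format = c("svg", "png"),
                          moduleWidth = 2, height = 60, quietZone = 10,
                          showText = TRUE) {
  format <- match.arg(format)
  if (quietZone < 10) stop("quiet zone must be >= 10 modules")
  w <- symbol@modules
  isBar <- rep(c(TRUE, FALSE), length.out = length(w))
  starts <- quietZone + c(0L, cumsum(w)[-length(w)])
  totalModules <- 2L * quietZone + sum(w)
  if (format == "svg") {
    textPad <- if (showText) 16 else 0
    widthPx <- totalModules * moduleWidth
    heightPx <- height + textPad
    lines <- c(
      sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%s" ',
                     'height="%s" viewBox="0 0 %s %s">'),
              widthPx, heightPx, widthPx, heightPx),
      sprintf('<rect width="%s" height="%s" fill="white"/>',
              widthPx, heightPx),
      sprintf('<rect x="%s" y="0" width="%s" height="%s" fill="black"/>',
              starts[isBar] * moduleWidth, w[isBar] * moduleWidth, height))
    if (showText)
      lines <- c(lines, sprintf(
        paste0('<text x="%s" y="%s" text-anchor="middle" ',
               'font-family="monospace" font-size="12">%s</text>'),
        widthPx / 2, height + 12, symbol@text))
    lines <- c(lines, "</svg>")
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
  } else {
    cols <- rep(1, totalModules)  # white
    for (i in which(isBar))
      cols[(starts[i] + 1L):(starts[i] + w[i])] <- 0
    img <- matrix(rep(cols, each = height), nrow = height)
    big <- img[, rep(seq_len(ncol(img)), each = max(1L, round(moduleWidth)))]
    png::writePNG(big, target = path)
  }
  invisible(path)
}

#' Render one barcode image per species tag
#'
#' @param tags a \linkS4class{SpeciesTagSet}.
#' @param dir output directory (created if needed); files are named
#'   \code{<species_id>.<format>} with filesystem-unsafe characters in the
#'   identifier replaced by \code{_}.
#' @param format \code{"svg"} or \code{"png"}.
#' @param ... passed to \code{\link{renderBarcode}}.
#' @return Character vector of the written file paths.
#' @export
renderTagBarcodes <- function(tags, dir, format = c("svg", "png"), ...) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vapply(seq_along(tags@species), function(i) {
    safe <- gsub("[^A-Za-z0-9._-]+", "_", tags@species[i])
    f <- file.path(dir, paste0(safe, ".", format))
    renderBarcode(encodeCode128(tags@tag[i]), f, format = format, ...)
    f
  }, character(1L))
}
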