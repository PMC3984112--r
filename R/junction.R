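#' Fusion junction notation
#'
#' A fusion junction is a directed pair of stranded genomic positions written
#' `"<strand><chrom>:<pos>-><strand><chrom>:<pos>"`, e.g.
#' `"+chr17:5250220->+chr17:11532734"`. The donor position is the last base of
#' the preserved donor side and the acceptor position is the first base of the
#' preserved acceptor side; `+` denotes transcription on the top chromosome
#' strand, `-` on the bottom strand.
#'
#' @slot donorChrom,acceptorChrom chromosome names
#' @slot donorPos,acceptorPos 1-based base positions
#' @slot donorStrand,acceptorStrand `"+"` or `"-"`
#' @name Junction-class
#' @aliases Junction
#' @exportClass Junction
setClass("Junction",
  representation(
    donorChrom = "character", donorPos = "numeric", donorStrand = "character",
    acceptorChrom = "character", acceptorPos = "numeric", acceptorStrand = "character"
  )
)

setValidity("Junction", function(object) {
  msg <- NULL
  if (!object@donorStrand %in% c("+", "-") ||
      !object@acceptorStrand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  if (object@donorPos < 1 || object@acceptorPos < 1)
    msg <- c(msg, "positions are 1-based and must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' Construct a Junction from its parts
#' @param donorChrom,donorPos,donorStrand donor side (last preserved base)
#' @param acceptorChrom,acceptorPos,acceptorStrand acceptor side (first
#'   preserved base)
#' @return a [Junction-class] object
#' @export
Junction <- function(donorChrom, donorPos, donorStrand,
                     acceptorChrom, acceptorPos, acceptorStrand) {
  new("Junction",
      donorChrom = as.character(donorChrom), donorPos = as.numeric(donorPos),
      donorStrand = as.character(donorStrand),
      acceptorChrom = as.character(acceptorChrom),
      acceptorPos = as.numeric(acceptorPos),
      acceptorStrand = as.character(acceptorStrand))
}

.junction_re <- "^([+-])([^:>[:space:]]+):([0-9]+)->([+-])([^:>[:space:]]+):([0-9]+)$"

#' Parse a junction string
#'
#' @param s a junction string such as `"+chr17:5250220->+chr17:11532734"`
#' @return a [Junction-class]; `parseJunction` is the inverse of
#'   [formatJunction()]
#' @examples
#' j <- parseJunction("+chr17:5250220->+chr17:11532734")
#' formatJunction(j)
#' @export
parseJunction <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  m <- regmatches(s, regexec(.junction_re, s))[[1]]
  if (length(m) != 7L) {
    bad <- if (!grepl("->", s, fixed = TRUE)) s else {
      halves <- strsplit(s, "->", fixed = TRUE)[[1]]
      ok <- grepl("^[+-][^:>[:space:]]+:[0-9]+$", halves)
      if (any(!ok)) halves[!ok][1] else s
    }
    stop("malformed junction string, offending token: '", bad, "'")
  }
  Junction(m[3], as.numeric(m[4]), m[2], m[6], as.numeric(m[7]), m[5])
}

#' @describeIn parseJunction format a Junction back to its string form
#' @param x a [Junction-class]
#' @param ... unused
#' @export
setMethod("formatJunction", "Junction", function(x, ...) {
  paste0(x@donorStrand, x@donorChrom, ":", format(x@donorPos, scientific = FALSE),
         "->",
         x@acceptorStrand, x@acceptorChrom, ":",
         format(x@acceptorPos, scientific = FALSE))
})

setMethod("show", "Junction", function(object) {
  cat("Junction:", formatJunction(object), "\n")
})

# vectorized junction string assembly used by the pipeline tables
.junction_string <- function(dchrom, dpos, dstrand, achrom, apos, astrand) {
  paste0(dstrand, dchrom, ":", format(dpos, scientific = FALSE, trim = TRUE),
         "->", astrand, achrom, ":",
         format(apos, scientific = FALSE, trim = TRUE))
}
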