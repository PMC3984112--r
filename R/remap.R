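# Step 5: retrieve candidate reads per library, remap them to the pooled
# template index, and keep unique fusion-template junction support.

#' Select the reads of one library to remap against the template index
#'
#' Returns reads whose genomic alignment overlaps any template flank locus
#' padded by the read length, plus all (quality-passing) unmapped reads —
#' the reads that could carry junction evidence missed by genome alignment.
#'
#' @param aln the sample's alignment table from [mapReads()]
#' @param index a [TemplateIndex-class]
#' @param readLen pad width (read length)
#' @return character vector of read ids
#' @export
selectReadsForRemap <- function(aln, index, readLen = 50) {
  unmapped <- aln$read_id[aln$kind == "unmapped"]
  segs <- .segment_ranges(aln, uniqueOnly = FALSE)
  if (length(segs) == 0) return(unmapped)
  pad <- GenomicRanges::resize(index@loci, width(index@loci) + 2 * readLen,
                               fix = "center")
  ov <- findOverlaps(segs, pad, ignore.strand = TRUE)
  union(unmapped, unique(mcols(segs)$read_id[queryHits(ov)]))
}

#' Remap reads to the five-template index
#'
#' Contiguous (splice-free) best placement of each read across all templates;
#' `unique_best` is TRUE when exactly one (template, offset) attains the best
#' score. Placement is sense-strand only (directional protocol; templates are
#' written in transcript orientation). `junction_overhang` is the smaller
#' number of read bases on either side of the template midpoint, and
#' `clean_overhang` states that no mismatch lies within that many bases of
#' the midpoint.
#'
#' @param reads named [Biostrings::DNAStringSet] (quality-passing reads)
#' @param index a [TemplateIndex-class]
#' @param k seed length for placement search
#' @return `data.frame` of hits (one row per placed read): `read_id`, `role`,
#'   `junction`, `offset` (0-based), `matches`, `unique_best`,
#'   `junction_overhang`, `clean_overhang`, `seq`
#' @export
remapToTemplates <- function(reads, index, k = 15) {
  ids <- names(reads)
  rs <- as.character(reads)
  res <- .cppRemapTemplates(index@sequences, rs, as.integer(k))
  hit <- !is.na(res$template)
  if (!any(hit))
    return(data.frame(read_id = character(), role = character(),
                      junction = character(), offset = integer(),
                      matches = integer(), unique_best = logical(),
                      junction_overhang = integer(), clean_overhang = logical(),
                      seq = character(), stringsAsFactors = FALSE))
  half <- index@width / 2
  L <- nchar(rs[hit])
  off <- res$offset[hit]
  left <- pmax(0, half - off)
  right <- pmax(0, off + L - half)
  overhang <- pmin(left, right)
  misTpl <- mapply(function(m, o) .parse_mis(m) + o,
                   res$mismatch_q[hit], off, SIMPLIFY = FALSE)
  clean <- mapply(function(mt, oh) !any(mt > half - oh & mt <= half + oh),
                  misTpl, overhang)
  data.frame(read_id = ids[hit],
             role = index@role[res$template[hit]],
             junction = index@junction[res$template[hit]],
             offset = off, matches = res$matches[hit],
             unique_best = res$n_best[hit] == 1L,
             junction_overhang = as.integer(overhang),
             clean_overhang = as.logical(clean),
             seq = rs[hit], stringsAsFactors = FALSE)
}

#' Fusion junction support reads
#'
#' Keeps hits that are uniquely best on a fusion template, span the junction
#' with at least `overhangMin` bases on each side, and have no mismatch
#' within the overhang. Reads on donor/acceptor (pre-)mRNA templates are
#' controls, never support.
#'
#' @param hits output of [remapToTemplates()]
#' @param overhangMin minimum junction overhang (default 6)
#' @return the supporting subset of `hits`
#' @export
fusionSupportReads <- function(hits, overhangMin = 6) {
  hits[hits$role == "fusion" & hits$unique_best &
         hits$junction_overhang >= overhangMin & hits$clean_overhang, ,
       drop = FALSE]
}
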