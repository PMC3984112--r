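# Minimal SAM interchange for alignment tables: split placements are written
# as a primary line plus a supplementary (flag 2048) line sharing the read
# name; custom tags carry the placement kind, breakpoint, slide range and
# mismatch positions so the table round-trips. This covers desk-scale
# ingestion of external split alignments; it is not a general SAM library.

.cigar_for <- function(qs, qe, L, strand) {
  lead <- qs - 1L; m <- qe - qs + 1L; trail <- L - qe
  if (strand == "-") { tmp <- lead; lead <- trail; trail <- tmp }
  paste0(if (lead > 0) paste0(lead, "S"), m, "M",
         if (trail > 0) paste0(trail, "S"))
}

#' Write an alignment table as SAM
#'
#' @param aln alignment table from [mapReads()]
#' @param reads named [Biostrings::DNAStringSet] of the read sequences
#' @param quals named [Biostrings::BStringSet] of quality strings (optional)
#' @param path output path
#' @param genome named [Biostrings::DNAStringSet] for the header
#' @return the path, invisibly
#' @export
writeAlignmentsSam <- function(aln, reads, quals = NULL, path, genome) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (i in seq_along(genome))
    writeLines(paste0("@SQ\tSN:", names(genome)[i], "\tLN:",
                      length(genome[[i]])), con)
  seqs <- as.character(reads)
  qs <- if (is.null(quals)) NULL else as.character(quals)
  lines <- character(0)
  for (i in seq_len(nrow(aln))) {
    id <- aln$read_id[i]
    sq <- seqs[[id]]
    ql <- if (is.null(qs)) strrep("I", nchar(sq)) else qs[[id]]
    if (aln$kind[i] == "unmapped") {
      lines <- c(lines, paste(id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, sq, ql,
                              "XK:Z:unmapped", sep = "\t"))
      next
    }
    L <- nchar(sq)
    mapq <- if (isTRUE(aln$unique[i])) 60L else 0L
    f1 <- if (aln$strand1[i] == "-") 16L else 0L
    sq1 <- if (f1 == 16L) as.character(reverseComplement(DNAString(sq))) else sq
    ql1 <- if (f1 == 16L) paste(rev(strsplit(ql, "")[[1]]), collapse = "") else ql
    tags <- c(paste0("XK:Z:", aln$kind[i]),
              paste0("NM:i:", aln$nmis1[i]),
              paste0("XM:Z:", ifelse(is.na(aln$mis1[i]) | !nzchar(aln$mis1[i]),
                                     ".", aln$mis1[i])))
    if (aln$kind[i] != "local") {
      tags <- c(tags,
                paste0("XB:i:", aln$breakpoint[i]),
                paste0("XL:i:", aln$slide_lo[i]),
                paste0("XH:i:", aln$slide_hi[i]),
                paste0("XN:Z:", ifelse(is.na(aln$mis2[i]) | !nzchar(aln$mis2[i]),
                                       ".", aln$mis2[i])),
                paste0("XO:i:", aln$nmis2[i]))
    }
    lines <- c(lines, paste(id, f1, aln$chrom1[i], aln$gstart1[i], mapq,
                            .cigar_for(aln$qstart1[i], aln$qend1[i], L,
                                       aln$strand1[i]),
                            "*", 0L, 0L, sq1, ql1,
                            paste(tags, collapse = "\t"), sep = "\t"))
    if (aln$kind[i] != "local") {
      f2 <- 2048L + if (aln$strand2[i] == "-") 16L else 0L
      lines <- c(lines, paste(id, f2, aln$chrom2[i], aln$gstart2[i], mapq,
                              .cigar_for(aln$qstart2[i], aln$qend2[i], L,
                                         aln$strand2[i]),
                              "*", 0L, 0L, "*", "*", sep = "\t"))
    }
  }
  writeLines(lines, con)
  invisible(path)
}

.tag_value <- function(fields, tag) {
  hit <- grep(paste0("^", tag, ":"), fields, value = TRUE)
  if (length(hit) == 0) return(NA_character_)
  sub("^..:.:", "", hit[1])
}

.cigar_span <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  list(ref = sum(n[op %in% c("M", "D", "N", "=", "X")]),
       leadS = if (op[1] == "S") n[1] else 0L,
       m = sum(n[op %in% c("M", "=", "X")]),
       qlen = sum(n[op %in% c("M", "I", "S", "=", "X")]))
}

#' Read a SAM file written by [writeAlignmentsSam()] back into an alignment
#' table
#'
#' Split reads are reassembled from their primary + supplementary line pair.
#'
#' @param path SAM path
#' @return list with `aln` (alignment table), `reads` (DNAStringSet) and
#'   `quals` (BStringSet)
#' @export
readAlignmentsSam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  rows <- list(); seqs <- character(0); quals <- character(0)
  supp <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 2048L) > 0) { supp[[f[1]]] <- f; next }
    id <- f[1]
    sq <- f[10]; ql <- f[11]
    if (bitwAnd(flag, 16L) > 0) {
      sq <- as.character(reverseComplement(DNAString(sq)))
      ql <- paste(rev(strsplit(ql, "")[[1]]), collapse = "")
    }
    seqs[id] <- sq; quals[id] <- ql
    kind <- .tag_value(f[-(1:11)], "XK")
    if (is.na(kind)) kind <- if (bitwAnd(flag, 4L) > 0) "unmapped" else "local"
    row <- data.frame(read_id = id, kind = kind, score = NA_integer_,
                      unique = as.integer(f[5]) > 0, chrom1 = NA_character_,
                      strand1 = NA_character_, gstart1 = NA_integer_,
                      gend1 = NA_integer_, qstart1 = NA_integer_,
                      qend1 = NA_integer_, nmis1 = NA_integer_,
                      mis1 = NA_character_, chrom2 = NA_character_,
                      strand2 = NA_character_, gstart2 = NA_integer_,
                      gend2 = NA_integer_, qstart2 = NA_integer_,
                      qend2 = NA_integer_, nmis2 = NA_integer_,
                      mis2 = NA_character_, breakpoint = NA_integer_,
                      slide_lo = NA_integer_, slide_hi = NA_integer_,
                      donor_pos = NA_real_, acceptor_pos = NA_real_,
                      stringsAsFactors = FALSE)
    if (kind != "unmapped") {
      strand <- if (bitwAnd(flag, 16L) > 0) "-" else "+"
      cs <- .cigar_span(f[6])
      L <- nchar(sq)
      row$chrom1 <- f[3]; row$strand1 <- strand
      row$gstart1 <- as.integer(f[4]); row$gend1 <- as.integer(f[4]) + cs$ref - 1L
      qs <- if (strand == "+") cs$leadS + 1L else L - cs$leadS - cs$m + 1L
      row$qstart1 <- qs; row$qend1 <- qs + cs$m - 1L
      nm <- .tag_value(f[-(1:11)], "NM")
      row$nmis1 <- if (is.na(nm)) NA_integer_ else as.integer(nm)
      xm <- .tag_value(f[-(1:11)], "XM")
      row$mis1 <- if (is.na(xm) || xm == ".") "" else xm
      if (kind != "local") {
        xb <- .tag_value(f[-(1:11)], "XB")
        row$breakpoint <- as.integer(xb)
        row$slide_lo <- as.integer(.tag_value(f[-(1:11)], "XL"))
        row$slide_hi <- as.integer(.tag_value(f[-(1:11)], "XH"))
        xn <- .tag_value(f[-(1:11)], "XN")
        row$mis2 <- if (is.na(xn) || xn == ".") "" else xn
        xo <- .tag_value(f[-(1:11)], "XO")
        row$nmis2 <- if (is.na(xo)) NA_integer_ else as.integer(xo)
      }
    }
    rows[[id]] <- row
  }
  for (id in names(supp)) {
    f <- supp[[id]]
    if (is.null(rows[[id]])) next
    strand <- if (bitwAnd(as.integer(f[2]), 16L) > 0) "-" else "+"
    cs <- .cigar_span(f[6])
    L <- nchar(seqs[[id]])
    rows[[id]]$chrom2 <- f[3]; rows[[id]]$strand2 <- strand
    rows[[id]]$gstart2 <- as.integer(f[4])
    rows[[id]]$gend2 <- as.integer(f[4]) + cs$ref - 1L
    qs <- if (strand == "+") cs$leadS + 1L else L - cs$leadS - cs$m + 1L
    rows[[id]]$qstart2 <- qs; rows[[id]]$qend2 <- qs + cs$m - 1L
    b <- rows[[id]]$breakpoint
    row1 <- rows[[id]]
    dp <- if (row1$strand1 == "+") row1$gend1 else row1$gstart1
    ap <- if (strand == "+") rows[[id]]$gstart2 else rows[[id]]$gend2
    rows[[id]]$donor_pos <- as.numeric(dp)
    rows[[id]]$acceptor_pos <- as.numeric(ap)
  }
  aln <- do.call(rbind, rows)
  rownames(aln) <- NULL
  list(aln = aln, reads = DNAStringSet(seqs), quals = BStringSet(quals))
}
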