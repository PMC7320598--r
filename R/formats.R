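#' Read a FASTA file
#'
#' @param path FASTA file path.
#' @return Named character vector of uppercased sequences (multi-line records
#'   are concatenated).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path FASTQ file path.
#' @return List with `ids`, `seqs` (uppercased character vector) and `quals`
#'   (list of integer Phred vectors).
#' @export
read_fastq <- function(path) {
  # the reader notes that it drops (unused) metadata columns; silence that only
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  ids <- sub("\\s.*$", "", names(x))
  seqs <- toupper(as.character(x))
  quals <- as(Biostrings::quality(x), "IntegerList")
  quals <- lapply(seq_along(quals), function(i) as.integer(quals[[i]]))
  if (any(vapply(quals, length, integer(1)) != nchar(seqs)))
    stop(sprintf("%s: quality length differs from sequence length", path),
         call. = FALSE)
  list(ids = unname(ids), seqs = unname(seqs), quals = quals)
}

#' Write a FASTQ file (Phred+33)
#'
#' @param ids,seqs Character vectors of read names and sequences.
#' @param quals List of integer Phred vectors.
#' @param path Output path.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  stopifnot(length(ids) == length(seqs), length(quals) == length(seqs))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(ids)) {
    q <- quals[[i]]
    if (length(q) != nchar(seqs[i]))
      stop("quality length differs from sequence length", call. = FALSE)
    writeLines(c(paste0("@", ids[i]), seqs[i], "+",
                 intToUtf8(as.integer(q) + 33L)), con)
  }
  invisible(path)
}

#' Read the VCF subset used for graph construction
#'
#' Only `CHROM`, `POS`, `REF`, `ALT` and the `INFO/AF` field are consumed;
#' genotype columns are ignored.  For multi-allelic records the first `AF`
#' value is reported.
#'
#' @param path VCF file path (plain text).
#' @return Data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (comma-separated alternates) and `af` (`NA` when absent), suitable for
#'   [build_graph()].
#' @export
read_vcf_subset <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(as.data.frame(fix)) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), af = numeric(0)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  info <- v@fix[, "INFO"]
  af <- vapply(info, function(s) {
    m <- regmatches(s, regexec("(?:^|;)AF=([^;]+)", s))[[1]]
    if (length(m) < 2L) return(NA_real_)
    suppressWarnings(as.numeric(strsplit(m[2], ",", fixed = TRUE)[[1]][1]))
  }, numeric(1), USE.NAMES = FALSE)
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS), ref = fix$REF,
             alt = fix$ALT, af = af, stringsAsFactors = FALSE)
}

#' Write a minimal VCF
#'
#' @param variants Data frame with `pos`, `ref`, `alt` and optionally `af` and
#'   `chrom`.
#' @param path Output path.
#' @param ref_name Contig name used when `variants$chrom` is absent.
#' @param ref_length Contig length for the header.
#' @export
write_vcf <- function(variants, path, ref_name = "ref", ref_length = NA) {
  chrom <- if (!is.null(variants$chrom)) variants$chrom else
    rep(ref_name, nrow(variants))
  af <- if (!is.null(variants$af)) variants$af else rep(NA_real_, nrow(variants))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    if (!is.na(ref_length)) sprintf("##contig=<ID=%s,length=%d>", ref_name,
                                    as.integer(ref_length)) else
      sprintf("##contig=<ID=%s>", ref_name),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Allele Frequency\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants) > 0L) {
    info <- ifelse(is.na(af), ".", sprintf("AF=%g", af))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t%s", chrom,
                       as.integer(variants$pos), variants$ref, variants$alt,
                       info), con)
  }
  invisible(path)
}

## ---- SAM dialect -----------------------------------------------------------
## Custom tags (this package's documented, stable dialect):
##   AS:i optimal alignment score      mp:i best-stratum anchored position
##   mc:i best-stratum co-optimal count (locations >= one read-length apart)
##   ss:i second-best stratum score    sp:i its position   sc:i its count
## ss/sp/sc are omitted when no second stratum exists.

#' Write alignment results as SAM
#'
#' Emits a SAM header (`@HD`, `@SQ`, `@PG`) and one record per result.  The
#' optimal score is written as `AS:i`; the best/second-best strata go to the
#' custom tags `mp`/`mc`/`ss`/`sp`/`sc` (see Details).  `CIGAR` and `POS` are
#' populated only when a traceback was computed (linear references); otherwise
#' the CIGAR is `*` and `POS` carries the anchored rightmost-base coordinate
#' `mp`, with the score tags still present.
#'
#' Unaligned reads (local mode with no positive-scoring cell, or semiglobal
#' reads below `min_score`) are written with flag 4 and position 0.
#'
#' @param results Data frame from [align_batch()] / [align_file()] (columns
#'   `cigar`/`pos` used when present).
#' @param graph A `ref_graph`, source of the reference name and length.
#' @param path Output path.
#' @param seqs,quals Optional named read sequences / list of Phred vectors
#'   (by read id) for the SEQ/QUAL columns; `*` otherwise.
#' @param min_score Semiglobal reads scoring below this are written unaligned.
#' @param pg Program line text for `@PG`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(results, graph, path, seqs = NULL, quals = NULL,
                      min_score = -Inf, pg = "goldalign align") {
  stopifnot(inherits(graph, "ref_graph"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", graph$ref_name, graph$ref_length),
               sprintf("@PG\tID:goldalign\tPN:goldalign\tCL:%s", pg)), con)
  has_tb <- !is.null(results$cigar)
  for (k in seq_len(nrow(results))) {
    r <- results[k, ]
    seq <- if (!is.null(seqs)) seqs[[r$id]] else "*"
    qual <- if (!is.null(quals) && !is.null(quals[[r$id]]))
      intToUtf8(as.integer(quals[[r$id]]) + 33L) else "*"
    aligned <- isTRUE(r$aligned) && r$best_score >= min_score
    if (!aligned) {
      writeLines(paste(r$id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L, seq, qual,
                       sep = "\t"), con)
      next
    }
    cigar <- if (has_tb && !is.na(r$cigar)) r$cigar else "*"
    pos <- if (has_tb && !is.na(r$pos)) r$pos else r$best_pos
    tags <- c(sprintf("AS:i:%d", as.integer(r$best_score)),
              sprintf("mp:i:%d", as.integer(r$best_pos)),
              sprintf("mc:i:%d", as.integer(r$best_count)))
    if (!is.na(r$second_score))
      tags <- c(tags, sprintf("ss:i:%d", as.integer(r$second_score)),
                sprintf("sp:i:%d", as.integer(r$second_pos)),
                sprintf("sc:i:%d", as.integer(r$second_count)))
    writeLines(paste(r$id, 0L, graph$ref_name, as.integer(pos), 255L, cigar,
                     "*", 0L, 0L, seq, qual, paste(tags, collapse = "\t"),
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read a SAM text file
#'
#' Parses mandatory fields and typed optional tags (`i` integer, `f` float,
#' `A`/`Z` character).  Secondary (flag 0x100) and supplementary (flag 0x800)
#' records are flagged so that evaluations can keep primary alignments only.
#'
#' @param path SAM file path.
#' @return Data frame with columns `qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`, `unaligned`, `secondary`, `supplementary` and a
#'   list-column `tags` of named typed values; the header lines are attached
#'   as attribute `"header"`.  Use [sam_tag()] to extract one tag across
#'   records.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  recs <- vector("list", length(body))
  for (k in seq_along(recs)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    lineno <- which(lines == body[k])[1]
    if (length(f) < 11L)
      stop(sprintf("%s line %d: SAM record has %d fields (11 required)",
                   path, lineno, length(f)), call. = FALSE)
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    mapq <- suppressWarnings(as.integer(f[5]))
    if (is.na(flag) || is.na(pos) || is.na(mapq))
      stop(sprintf("%s line %d: non-numeric FLAG/POS/MAPQ", path, lineno),
           call. = FALSE)
    tags <- list()
    if (length(f) > 11L) {
      for (t in f[-(1:11)]) {
        p <- strsplit(t, ":", fixed = TRUE)[[1]]
        if (length(p) < 3L)
          stop(sprintf("%s line %d: malformed tag '%s'", path, lineno, t),
               call. = FALSE)
        val <- paste(p[-(1:2)], collapse = ":")
        tags[[p[1]]] <- switch(p[2],
                               i = as.integer(val),
                               f = as.numeric(val),
                               val)
      }
    }
    recs[[k]] <- list(qname = f[1], flag = flag, rname = f[3], pos = pos,
                      mapq = mapq, cigar = f[6], seq = f[10], qual = f[11],
                      tags = tags)
  }
  out <- data.frame(
    qname = vapply(recs, `[[`, character(1), "qname"),
    flag  = vapply(recs, `[[`, integer(1), "flag"),
    rname = vapply(recs, `[[`, character(1), "rname"),
    pos   = vapply(recs, `[[`, integer(1), "pos"),
    mapq  = vapply(recs, `[[`, integer(1), "mapq"),
    cigar = vapply(recs, `[[`, character(1), "cigar"),
    seq   = vapply(recs, `[[`, character(1), "seq"),
    qual  = vapply(recs, `[[`, character(1), "qual"),
    stringsAsFactors = FALSE
  )
  out$unaligned <- bitwAnd(out$flag, 4L) != 0L
  out$secondary <- bitwAnd(out$flag, 256L) != 0L
  out$supplementary <- bitwAnd(out$flag, 2048L) != 0L
  out$tags <- lapply(recs, `[[`, "tags")
  attr(out, "header") <- hdr
  out
}

#' Extract one typed tag across SAM records
#'
#' @param records Data frame from [read_sam()].
#' @param tag Tag name, e.g. `"AS"`.
#' @return Vector of tag values, `NA` where the tag is absent.
#' @export
sam_tag <- function(records, tag) {
  vals <- lapply(records$tags, function(t) if (is.null(t[[tag]])) NA else t[[tag]])
  unlist(vals)
}
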