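## Batched, heuristic-free affine-gap alignment over linearized DAG columns.
##
## The dynamic program is query-parallel: one (row, column) cell is filled for
## every read in the batch at once (vectors across reads), so cell values are
## mutually independent and no repair step is needed.  Columns are processed
## in topological-linearized order; the first column of a node takes
## elementwise maxima of the H and E states carried from the last columns of
## all its in-neighbors.

.BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L, N = 5L)

.encode_seq <- function(seq) {
  codes <- .BASE_CODE[strsplit(toupper(seq), "", fixed = TRUE)[[1]]]
  if (anyNA(codes)) stop("sequence contains characters outside {A,C,G,T,N}",
                         call. = FALSE)
  unname(codes)
}

#' Construct a read batch
#'
#' A batch groups reads of one fixed length (with optional Phred base
#' qualities) for query-parallel alignment.  Results are independent of how a
#' read set is partitioned into batches.
#'
#' @param reads Character vector of read sequences over `{A,C,G,T,N}`, all the
#'   same length.
#' @param quals Optional list of integer Phred quality vectors, parallel to
#'   `reads` (each the read length), or a matrix with one column per read.
#' @param ids Read names; defaults to `read1`, `read2`, ...
#' @return An object of class `read_batch`.
#' @export
read_batch <- function(reads, quals = NULL, ids = NULL) {
  if (length(reads) == 0L) stop("batch must contain at least one read", call. = FALSE)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  stopifnot(length(ids) == length(reads))
  lens <- nchar(reads)
  if (length(unique(lens)) != 1L)
    stop("rejected: reads in a batch must all have the same length", call. = FALSE)
  m <- lens[1]
  if (m < 1L) stop("reads must be non-empty", call. = FALSE)
  codes <- matrix(0L, m, length(reads))
  for (r in seq_along(reads)) {
    codes[, r] <- tryCatch(.encode_seq(reads[r]), error = function(e)
      stop(sprintf("rejected read '%s': %s", ids[r], conditionMessage(e)),
           call. = FALSE))
  }
  qmat <- NULL
  if (!is.null(quals)) {
    if (is.matrix(quals)) quals <- lapply(seq_len(ncol(quals)), function(i) quals[, i])
    stopifnot(length(quals) == length(reads))
    if (any(vapply(quals, length, integer(1)) != m))
      stop("rejected: quality length differs from read length", call. = FALSE)
    qmat <- matrix(as.numeric(unlist(quals)), m, length(reads))
    if (any(qmat < 0)) stop("Phred qualities must be >= 0", call. = FALSE)
  }
  structure(list(reads = as.character(reads), codes = codes, quals = qmat,
                 ids = as.character(ids), read_length = m,
                 n = length(reads)),
            class = "read_batch")
}

#' @export
print.read_batch <- function(x, ...) {
  cat(sprintf("<read_batch> %d reads of length %d (%s qualities)\n",
              x$n, x$read_length, if (is.null(x$quals)) "no" else "with"))
  invisible(x)
}

# Per-read-base mismatch penalty matrix (m x n).
.penalty_matrix <- function(batch, model) {
  if (is.null(batch$quals))
    matrix(model$mismatch_max, batch$read_length, batch$n)
  else
    matrix(mismatch_penalty(model, batch$quals), batch$read_length, batch$n)
}

# Core column-wise DP.  Returns col_best: n x C matrix of the best
# alignment-ending score at each column (row m in semiglobal mode, the column
# maximum over rows in local mode).  Scores are clamped to the biased window
# [lo, hi] selected by the cell width; bottom saturation mimics unsigned
# saturating SIMD arithmetic and cannot overstate the optimum because the
# window floor is the score_range() worst-cost bound.
.dp_columns <- function(graph, batch, model, width) {
  m <- batch$read_length; n <- batch$n
  rng <- score_range(model, m)
  lo <- rng[["min_score"]]
  hi <- lo + if (width == "narrow") 255L else 65535L
  if (rng[["max_score"]] > hi)
    stop("selected cell width cannot represent the score range", call. = FALSE)
  local <- model$mode == "local"
  go <- model$gap_open; ge <- model$gap_extend; goe <- go + ge
  np <- model$ambig_penalty; bonus <- model$match
  pens <- .penalty_matrix(batch, model)
  codes <- batch$codes

  cols <- graph$columns
  C <- nrow(cols)
  nnode <- nrow(graph$nodes)
  node_seq_codes <- lapply(graph$nodes$seq, .encode_seq)
  preds <- split(graph$edges$from, factor(graph$edges$to, levels = seq_len(nnode)))

  # carried-in state for a source node: column 0 of the textbook recurrence.
  # Semiglobal permits a leading read gap (insertion chain) before the first
  # reference base; local cells restart freely at zero.
  src_H <- if (local) matrix(0, m, n) else
    matrix(pmax(-(go + seq_len(m) * ge), lo), m, n)
  src_E <- matrix(lo, m, n)

  out_H <- vector("list", nnode)  # last-column states, for join carry
  out_E <- vector("list", nnode)
  col_best <- matrix(NA_real_, n, C)
  zero_row <- numeric(n)
  j_global <- 0L

  for (v in seq_len(nnode)) {
    pv <- preds[[v]]
    if (length(pv) == 0L) {
      Hp <- src_H; Ep <- src_E
    } else {
      Hp <- out_H[[pv[1]]]; Ep <- out_E[[pv[1]]]
      for (p in pv[-1]) {
        Hp <- pmax(Hp, out_H[[p]]); Ep <- pmax(Ep, out_E[[p]])
      }
    }
    for (b in node_seq_codes[[v]]) {
      j_global <- j_global + 1L
      # substitution scores for this column, all rows x reads at once
      if (b == 5L) {
        S <- matrix(-np, m, n)
      } else {
        S <- ifelse(codes == b, bonus, -pens)
        S[codes == 5L] <- -np
      }
      E <- pmax(Hp - goe, Ep - ge)
      E[E < lo] <- lo
      Diag <- rbind(zero_row, Hp[-m, , drop = FALSE]) + S
      H <- matrix(0, m, n)
      f <- rep.int(lo, n)
      h_above <- zero_row  # H at row 0 is 0 at every column (free ref flank)
      best_in_col <- NULL
      for (i in seq_len(m)) {
        f <- pmax(h_above - goe, f - ge)
        f[f < lo] <- lo
        h <- pmax(Diag[i, ], E[i, ], f)
        if (local) h[h < 0] <- 0
        h[h < lo] <- lo; h[h > hi] <- hi
        H[i, ] <- h
        h_above <- h
        if (local) best_in_col <- if (is.null(best_in_col)) h else pmax(best_in_col, h)
      }
      col_best[, j_global] <- if (local) best_in_col else H[m, ]
      Hp <- H; Ep <- E
    }
    out_H[[v]] <- Hp; out_E[[v]] <- Ep
  }
  col_best
}

#' Align a batch of reads to a reference graph
#'
#' Computes, for every read, the guaranteed-optimal alignment score over all
#' source-to-sink-path alignments of the read to the graph under the scoring
#' model: semiglobal mode aligns every read base with free reference flanks;
#' local mode aligns any read substring with cell scores floored at zero.  No
#' heuristics are used — every cell of the dynamic program is filled.
#'
#' Along with the best score, the anchored reference coordinate of the
#' rightmost aligned read base, the count of equally scoring alignment
#' locations at least one read-length apart, and the runner-up (second-best)
#' score stratum at least one read-length away from every best location are
#' reported (see [track_optima()]).
#'
#' @param graph A `ref_graph` from [build_graph()] or [load_graph()].
#' @param batch A [read_batch()] (a character vector of reads is accepted and
#'   wrapped).
#' @param model A [scoring_model()].
#' @param width Score-cell width: `"auto"` (default) applies
#'   [select_cell_width()]; `"narrow"`/`"wide"` force a width (narrow must be
#'   able to represent the score range).
#' @return Data frame with one row per read: `id`, `aligned`, `best_score`,
#'   `best_pos`, `best_count`, `second_score`, `second_pos`, `second_count`.
#'   In local mode a read with no positive-scoring cell is reported unaligned.
#' @examples
#' g <- build_graph("ACGTACGTACGT")
#' m <- scoring_preset("sg-default")
#' align_batch(g, read_batch("GTAC"), m)
#' @export
align_batch <- function(graph, batch, model, width = c("auto", "narrow", "wide")) {
  stopifnot(inherits(graph, "ref_graph"), inherits(model, "scoring_model"))
  if (!inherits(batch, "read_batch")) batch <- read_batch(batch)
  width <- match.arg(width)
  if (width == "auto") width <- select_cell_width(model, batch$read_length)
  col_best <- .dp_columns(graph, batch, model, width)
  coords <- graph$columns$coord
  local <- model$mode == "local"
  res <- vector("list", batch$n)
  for (r in seq_len(batch$n)) {
    st <- track_optima(col_best[r, ], coords, batch$read_length,
                       zero_floor = local)
    res[[r]] <- st
  }
  out <- data.frame(
    id           = batch$ids,
    aligned      = vapply(res, `[[`, logical(1), "aligned"),
    best_score   = vapply(res, `[[`, numeric(1), "best_score"),
    best_pos     = vapply(res, `[[`, numeric(1), "best_pos"),
    best_count   = vapply(res, `[[`, numeric(1), "best_count"),
    second_score = vapply(res, `[[`, numeric(1), "second_score"),
    second_pos   = vapply(res, `[[`, numeric(1), "second_pos"),
    second_count = vapply(res, `[[`, numeric(1), "second_count"),
    stringsAsFactors = FALSE
  )
  attr(out, "width") <- width
  attr(out, "mode") <- model$mode
  out
}

#' Best and second-best score strata from per-column end scores
#'
#' The best stratum is the maximum alignment-ending score, the smallest
#' anchored coordinate attaining it, and the count of co-optimal locations at
#' least one read-length apart ([count_cooptimal()]).  The second stratum is
#' the highest score achieved at a column whose anchored coordinate lies at
#' least one read-length from every best-stratum coordinate; it is unset
#' (`NA`) when no such column exists.  Columns anchored to the same reference
#' coordinate (an alternate allele and the reference base it parallels) count
#' as one location.
#'
#' @param scores Numeric vector of best alignment-ending scores per column,
#'   for one read.
#' @param coords Anchored reference coordinate of each column
#'   (`graph$columns$coord`).
#' @param read_length Read length in bases.
#' @param zero_floor `TRUE` for local mode: a maximum of zero means no
#'   alignment exists.
#' @return List with `aligned`, `best_score`, `best_pos`, `best_count`,
#'   `second_score`, `second_pos`, `second_count` (`NA` where unset).
#' @export
track_optima <- function(scores, coords, read_length, zero_floor = FALSE) {
  stopifnot(length(scores) == length(coords))
  best <- max(scores)
  if (zero_floor && best <= 0)
    return(list(aligned = FALSE, best_score = 0, best_pos = NA_real_,
                best_count = 0, second_score = NA_real_, second_pos = NA_real_,
                second_count = NA_real_))
  bc <- sort(unique(coords[scores == best]))
  keep <- vapply(coords, function(x) min(abs(x - bc)) >= read_length, logical(1))
  if (!any(keep)) {
    second <- list(score = NA_real_, pos = NA_real_, count = NA_real_)
  } else {
    s2 <- max(scores[keep])
    if (zero_floor && s2 <= 0) {
      second <- list(score = NA_real_, pos = NA_real_, count = NA_real_)
    } else {
      c2 <- sort(unique(coords[keep & scores == s2]))
      second <- list(score = s2, pos = c2[1], count = count_cooptimal(c2, read_length))
    }
  }
  list(aligned = TRUE, best_score = best, best_pos = bc[1],
       best_count = count_cooptimal(bc, read_length),
       second_score = second$score, second_pos = second$pos,
       second_count = second$count)
}

#' Count co-optimal alignment locations at least one read-length apart
#'
#' Greedy left-to-right clustering of end coordinates: a new cluster starts
#' when a coordinate is at least `read_length` greater than the founding
#' coordinate of the previous cluster.  A difference of exactly one
#' read-length qualifies as "at least one read-length apart".
#'
#' @param coords Sorted ascending coordinates of equally scoring alignment
#'   ends.
#' @param read_length Read length in bases.
#' @return Integer cluster count (0 for an empty input).
#' @export
count_cooptimal <- function(coords, read_length) {
  if (length(coords) == 0L) return(0L)
  if (is.unsorted(coords)) stop("coords must be sorted ascending", call. = FALSE)
  count <- 1L
  founder <- coords[1]
  for (x in coords[-1]) {
    if (x - founder >= read_length) {
      count <- count + 1L
      founder <- x
    }
  }
  count
}
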