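#' Optimal alignment traceback for a linear reference
#'
#' Recomputes the full affine-gap dynamic-programming matrices for one read
#' against a linear (single-node) reference and traces the optimal alignment
#' back to a CIGAR string and a 1-based leftmost mapping position (POS).  The
#' CIGAR's score under the model equals the batch engine's `best_score` for
#' the same read.  Semiglobal CIGARs contain no soft clips; local CIGARs
#' soft-clip the unaligned read prefix/suffix.  Ties are broken
#' deterministically: the smallest end coordinate wins (in local mode the
#' longest aligned read suffix among those), and the traceback prefers a
#' diagonal over a vertical (read-gap) over a horizontal (reference-gap) move.
#'
#' @param reference Reference sequence: a character string or a single-node
#'   `ref_graph`.  A multi-node graph is an error — graph tracebacks are
#'   unsupported; only scores and anchored positions are reported for graphs.
#' @param read Read sequence.
#' @param quals Optional integer Phred qualities for `read`.
#' @param model A [scoring_model()].
#' @return List with `cigar`, `pos` (1-based leftmost mapped reference
#'   coordinate) and `score`.  An unaligned local read (no positive-scoring
#'   cell) returns `cigar = NA`, `pos = NA`, `score = 0`.
#' @examples
#' m <- scoring_preset("sg-default")
#' traceback_linear("ACGTACGT", "ACGTCGT", model = m)  # 4M1D3M, pos 1
#' @export
traceback_linear <- function(reference, read, quals = NULL, model) {
  stopifnot(inherits(model, "scoring_model"))
  if (inherits(reference, "ref_graph")) {
    if (nrow(reference$nodes) != 1L)
      stop("traceback is unsupported for multi-node graphs (linear references only)",
           call. = FALSE)
    reference <- reference$nodes$seq[1]
  }
  ref_codes <- .encode_seq(reference)
  read_codes <- .encode_seq(read)
  m <- length(read_codes); L <- length(ref_codes)
  local <- model$mode == "local"
  go <- model$gap_open; ge <- model$gap_extend; goe <- go + ge
  pen <- if (is.null(quals)) rep.int(model$mismatch_max, m) else
    mismatch_penalty(model, quals)
  subst <- function(i, j) {
    if (read_codes[i] == 5L || ref_codes[j] == 5L) -model$ambig_penalty
    else if (read_codes[i] == ref_codes[j]) model$match
    else -pen[i]
  }

  NEG <- -Inf
  H <- matrix(NEG, m + 1L, L + 1L)
  E <- matrix(NEG, m + 1L, L + 1L)
  F <- matrix(NEG, m + 1L, L + 1L)
  H[1L, ] <- 0  # row 0: free reference prefix in both modes
  if (local) {
    H[, 1L] <- 0
  } else {
    for (i in seq_len(m)) {  # column 0: leading read-gap chain
      F[i + 1L, 1L] <- max(H[i, 1L] - goe, F[i, 1L] - ge)
      H[i + 1L, 1L] <- F[i + 1L, 1L]
    }
  }
  for (j in seq_len(L)) {
    for (i in seq_len(m)) {
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - goe, E[i + 1L, j] - ge)
      F[i + 1L, j + 1L] <- max(H[i, j + 1L] - goe, F[i, j + 1L] - ge)
      h <- max(H[i, j] + subst(i, j), E[i + 1L, j + 1L], F[i + 1L, j + 1L])
      if (local && h < 0) h <- 0
      H[i + 1L, j + 1L] <- h
    }
  }

  if (local) {
    score <- max(H)
    if (score <= 0)
      return(list(cigar = NA_character_, pos = NA_integer_, score = 0))
    hits <- which(H == score, arr.ind = TRUE)
    j_end <- min(hits[, 2L]) - 1L
    i_end <- max(hits[hits[, 2L] == j_end + 1L, 1L]) - 1L
  } else {
    score <- max(H[m + 1L, ])
    i_end <- m
    j_end <- which(H[m + 1L, ] == score)[1] - 1L
  }

  ops <- character(0)
  i <- i_end; j <- j_end; state <- "H"
  repeat {
    if (state == "H") {
      if (i == 0L) break
      if (local && H[i + 1L, j + 1L] == 0) break
      if (j >= 1L && H[i + 1L, j + 1L] == H[i, j] + subst(i, j)) {
        ops <- c(ops, "M"); i <- i - 1L; j <- j - 1L
      } else if (H[i + 1L, j + 1L] == F[i + 1L, j + 1L]) {
        state <- "F"
      } else if (H[i + 1L, j + 1L] == E[i + 1L, j + 1L]) {
        state <- "E"
      } else stop("internal error: traceback dead end", call. = FALSE)
    } else if (state == "F") {
      ops <- c(ops, "I")
      from_h <- H[i, j + 1L] - goe
      i <- i - 1L
      if (F[i + 2L, j + 1L] == from_h) state <- "H"
    } else {  # E: horizontal, consumes a reference base
      ops <- c(ops, "D")
      from_h <- H[i + 1L, j] - goe
      j <- j - 1L
      if (E[i + 1L, j + 2L] == from_h) state <- "H"
    }
  }
  pos <- j + 1L
  ops <- rev(ops)
  if (local) {
    if (i > 0L) ops <- c(rep("S", i), ops)
    if (i_end < m) ops <- c(ops, rep("S", m - i_end))
  }
  list(cigar = .rle_cigar(ops), pos = as.integer(pos), score = score)
}

.rle_cigar <- function(ops) {
  r <- rle(ops)
  paste0(r$lengths, r$values, collapse = "")
}

.parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(NULL)
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  if (length(lens) != length(ops) || length(ops) == 0L)
    stop(sprintf("malformed CIGAR '%s'", cigar), call. = FALSE)
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

#' Score an existing CIGAR alignment under a model
#'
#' Replays a CIGAR against the reference and read and accumulates the model's
#' score: matches add the match bonus, mismatches subtract the quality-scaled
#' penalty, `I`/`D` runs cost `gap_open + len * gap_extend`, and soft-clipped
#' bases cost nothing.  Used to verify that emitted CIGARs reproduce the
#' engine's optimal score exactly.
#'
#' @param reference,read Sequences (character strings).
#' @param cigar CIGAR string with operations in `M`, `I`, `D`, `S`, `=`, `X`.
#' @param pos 1-based leftmost reference coordinate of the alignment.
#' @param quals Optional integer Phred qualities for `read`.
#' @param model A [scoring_model()].
#' @return List with `score`, `read_consumed`, `ref_consumed`.
#' @export
score_cigar <- function(reference, read, cigar, pos, quals = NULL, model) {
  stopifnot(inherits(model, "scoring_model"))
  ref_codes <- .encode_seq(reference)
  read_codes <- .encode_seq(read)
  pen <- if (is.null(quals)) rep.int(model$mismatch_max, length(read_codes)) else
    mismatch_penalty(model, quals)
  cg <- .parse_cigar(cigar)
  if (is.null(cg)) stop("cannot score an absent CIGAR", call. = FALSE)
  i <- 0L; j <- pos - 1L; score <- 0
  for (k in seq_len(nrow(cg))) {
    len <- cg$len[k]; op <- cg$op[k]
    if (op %in% c("M", "=", "X")) {
      for (t in seq_len(len)) {
        i <- i + 1L; j <- j + 1L
        if (read_codes[i] == 5L || ref_codes[j] == 5L)
          score <- score - model$ambig_penalty
        else if (read_codes[i] == ref_codes[j]) score <- score + model$match
        else score <- score - pen[i]
      }
    } else if (op == "I") {
      i <- i + len
      score <- score - (model$gap_open + len * model$gap_extend)
    } else if (op == "D") {
      j <- j + len
      score <- score - (model$gap_open + len * model$gap_extend)
    } else if (op == "S") {
      i <- i + len
    } else stop(sprintf("unsupported CIGAR op '%s'", op), call. = FALSE)
  }
  list(score = score, read_consumed = i, ref_consumed = j - (pos - 1L))
}

#' Align a read file against a graph
#'
#' Reads a FASTQ or FASTA file, groups reads of equal length into
#' query-parallel batches, aligns every batch with [align_batch()] and
#' returns results in the input order.  Per-read results are identical to
#' singleton [align_batch()] calls regardless of the batch partition.
#'
#' @param graph A `ref_graph`.
#' @param reads_path Path to a FASTQ (`.fastq`/`.fq`) or FASTA file.
#' @param model A [scoring_model()].
#' @param traceback If `TRUE` and the graph is linear (single node), also
#'   compute each read's CIGAR and leftmost POS via [traceback_linear()].
#' @param batch_size Maximum reads per batch (default: one batch per length
#'   group).
#' @param width Passed to [align_batch()].
#' @return Data frame as [align_batch()], in input order, with `cigar` and
#'   `pos` columns when `traceback = TRUE`.
#' @export
align_file <- function(graph, reads_path, model, traceback = FALSE,
                       batch_size = Inf, width = "auto") {
  stopifnot(inherits(graph, "ref_graph"))
  if (traceback && nrow(graph$nodes) != 1L)
    stop("traceback is unsupported for multi-node graphs (linear references only)",
         call. = FALSE)
  fq <- grepl("\\.(fastq|fq)(\\.gz)?$", reads_path, ignore.case = TRUE)
  rec <- if (fq) read_fastq(reads_path) else
    list(ids = names(read_fasta(reads_path)),
         seqs = unname(read_fasta(reads_path)), quals = NULL)
  if (length(rec$seqs) == 0L) {
    out <- data.frame(id = character(0), aligned = logical(0),
                      best_score = numeric(0), best_pos = numeric(0),
                      best_count = numeric(0), second_score = numeric(0),
                      second_pos = numeric(0), second_count = numeric(0))
    if (traceback) { out$cigar <- character(0); out$pos <- numeric(0) }
    return(out)
  }
  lens <- nchar(rec$seqs)
  pieces <- list()
  for (len in unique(lens)) {
    idx <- which(lens == len)
    for (start in seq(1L, length(idx), by = min(batch_size, length(idx)))) {
      sub <- idx[start:min(start + batch_size - 1L, length(idx))]
      batch <- read_batch(rec$seqs[sub],
                          quals = if (is.null(rec$quals)) NULL else rec$quals[sub],
                          ids = rec$ids[sub])
      res <- align_batch(graph, batch, model, width = width)
      res$.idx <- sub
      pieces[[length(pieces) + 1L]] <- res
    }
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$.idx), , drop = FALSE]
  out$.idx <- NULL
  rownames(out) <- NULL
  if (traceback) {
    refseq <- graph$nodes$seq[1]
    tb <- lapply(seq_len(nrow(out)), function(k) {
      i <- which(rec$ids == out$id[k])[1]
      traceback_linear(refseq, rec$seqs[i],
                       quals = if (is.null(rec$quals)) NULL else rec$quals[[i]],
                       model = model)
    })
    out$cigar <- vapply(tb, `[[`, character(1), "cigar")
    out$pos <- vapply(tb, function(x) as.numeric(x$pos), numeric(1))
  }
  out
}
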