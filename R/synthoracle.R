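## Synthetic references, variants and reads with known truth, plus the
## brute-force alignment oracle the engine is verified against.  The oracle
## enumerates source-to-sink paths and runs a plain, scalar, full-matrix
## affine-gap DP on each path — it shares no recurrence code with the batched
## engine, so the two cannot share a bug in join handling.

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a uniform-random genome
#'
#' @param length Genome length in bp, `>= 1`.
#' @param seed Optional integer seed; a fixed seed makes the output
#'   bit-reproducible.
#' @return Character string over `{A,C,G,T}`.
#' @export
simulate_genome <- function(length, seed = NULL) {
  if (!is.numeric(length) || length < 1)
    stop("genome length must be >= 1", call. = FALSE)
  .with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), as.integer(length), replace = TRUE),
          collapse = ""))
}

#' Simulate non-overlapping variants on a genome
#'
#' Plants SNPs and short indels at the given per-base rates, spaced so that no
#' two reference spans overlap (at least one untouched base between events,
#' and none at the sequence ends), with allele frequencies drawn uniformly.
#' The emitted records follow the VCF anchor-base convention for indels and
#' are always valid input for [build_graph()].
#'
#' @param genome Character string from [simulate_genome()] (or any sequence).
#' @param snp_rate,indel_rate Per-base event probabilities.
#' @param max_indel Maximum indel length in bp.
#' @param seed Optional integer seed.
#' @return Data frame with `chrom`, `pos`, `ref`, `alt`, `af`, sorted by
#'   `pos`.
#' @export
simulate_variants <- function(genome, snp_rate = 0.001, indel_rate = 2e-4,
                              max_indel = 3, seed = NULL) {
  stopifnot(snp_rate >= 0, snp_rate <= 1, indel_rate >= 0, indel_rate <= 1,
            max_indel >= 1)
  L <- nchar(genome)
  base_at <- function(p) substr(genome, p, p)
  .with_seed(seed, {
    events <- list()
    u <- stats::runif(L)
    v <- stats::runif(L)
    for (p in seq_len(L)) {
      if (p < 3L || p > L - max_indel - 2L) next
      if (u[p] < snp_rate) {
        events[[length(events) + 1L]] <- list(kind = "snp", pos = p, start = p, end = p)
      } else if (v[p] < indel_rate) {
        k <- sample.int(max_indel, 1L)
        if (stats::runif(1) < 0.5)
          events[[length(events) + 1L]] <- list(kind = "del", pos = p, k = k,
                                                start = p, end = p + k - 1L)
        else
          events[[length(events) + 1L]] <- list(kind = "ins", pos = p, k = k,
                                                start = p, end = p)
      }
    }
    kept <- list(); last_end <- -10L
    for (ev in events) {
      if (ev$start >= last_end + 2L) {  # >= 1 untouched base between spans
        kept[[length(kept) + 1L]] <- ev
        last_end <- ev$end
      }
    }
    rows <- lapply(kept, function(ev) {
      if (ev$kind == "snp") {
        ref <- base_at(ev$pos)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
        data.frame(pos = ev$pos, ref = ref, alt = alt)
      } else if (ev$kind == "del") {
        data.frame(pos = ev$pos - 1L,
                   ref = substr(genome, ev$pos - 1L, ev$pos + ev$k - 1L),
                   alt = base_at(ev$pos - 1L))
      } else {
        ins <- paste(sample(c("A", "C", "G", "T"), ev$k, replace = TRUE),
                     collapse = "")
        data.frame(pos = ev$pos, ref = base_at(ev$pos),
                   alt = paste0(base_at(ev$pos), ins))
      }
    })
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(pos = integer(0), ref = character(0), alt = character(0))
    out$af <- if (nrow(out)) round(stats::runif(nrow(out), 0.01, 0.99), 3) else numeric(0)
    out <- cbind(chrom = rep("ref", nrow(out)), out)
    out[order(out$pos), , drop = FALSE]
  })
}

#' Simulate reads with known truth coordinates
#'
#' Samples each read from a window of a random source-to-sink path of the
#' graph (for a linear reference, from the reference itself), injects
#' substitution errors at the given rate, draws per-base Phred qualities from
#' `quality_levels`, and records the truth: the anchored reference coordinate
#' of the window's rightmost base (the same anchoring the engine reports) and
#' the planted alignment score — the score of the error-bearing read aligned
#' back gaplessly at its window under `model` (the true optimum is at least
#' this).
#'
#' @param x A `ref_graph` or a character genome string.
#' @param n_reads Number of reads.
#' @param read_length Read length in bp (at most the shortest path length).
#' @param error_rate Per-base substitution error probability.
#' @param quality_levels Integer Phred values qualities are drawn from.
#' @param model Optional [scoring_model()] used for the planted score (`NA`
#'   otherwise).
#' @param seed Optional integer seed.
#' @return List with `ids`, `seqs`, `quals` and `truth`, a data frame
#'   (`id`, `coord`, `n_errors`, `planted_score`).
#' @export
simulate_reads <- function(x, n_reads = 100, read_length = 100,
                           error_rate = 0.005, quality_levels = 30:40,
                           model = NULL, seed = NULL) {
  graph <- if (inherits(x, "ref_graph")) x else build_graph(x)
  stopifnot(n_reads >= 1, read_length >= 1, error_rate >= 0, error_rate <= 1)
  nnode <- nrow(graph$nodes)
  succ <- split(graph$edges$to, factor(graph$edges$from, levels = seq_len(nnode)))
  sources <- which(!seq_len(nnode) %in% graph$edges$to)
  node_chars <- strsplit(graph$nodes$seq, "", fixed = TRUE)
  node_coords <- split(graph$columns$coord, graph$columns$node)

  .with_seed(seed, {
    ids <- sprintf("sim%0*d", nchar(n_reads) + 1L, seq_len(n_reads))
    seqs <- character(n_reads); quals <- vector("list", n_reads)
    coord <- integer(n_reads); n_err <- integer(n_reads)
    planted <- rep(NA_real_, n_reads)
    for (r in seq_len(n_reads)) {
      v <- if (length(sources) == 1L) sources else sample(sources, 1L)
      chars <- character(0); coords <- integer(0)
      repeat {
        chars <- c(chars, node_chars[[v]])
        coords <- c(coords, node_coords[[as.character(v)]])
        nxt <- succ[[v]]
        if (length(nxt) == 0L) break
        v <- if (length(nxt) == 1L) nxt else sample(nxt, 1L)
      }
      if (length(chars) < read_length)
        stop("read_length exceeds a source-to-sink path length", call. = FALSE)
      start <- sample.int(length(chars) - read_length + 1L, 1L)
      win <- start:(start + read_length - 1L)
      base <- chars[win]
      q <- if (length(quality_levels) == 1L) rep(quality_levels, read_length) else
        sample(quality_levels, read_length, replace = TRUE)
      err <- which(stats::runif(read_length) < error_rate)
      for (e in err)
        base[e] <- sample(setdiff(c("A", "C", "G", "T"), base[e]), 1L)
      seqs[r] <- paste(base, collapse = "")
      quals[[r]] <- as.integer(q)
      coord[r] <- coords[win[read_length]]
      n_err[r] <- length(err)
      if (!is.null(model))
        planted[r] <- (read_length - length(err)) * model$match -
          sum(mismatch_penalty(model, q[err]))
    }
    list(ids = ids, seqs = seqs, quals = quals,
         truth = data.frame(id = ids, coord = coord, n_errors = n_err,
                            planted_score = planted, stringsAsFactors = FALSE))
  })
}

#' Brute-force optimal alignment score by path enumeration
#'
#' Reference semantics for the engine: enumerates every source-to-sink path of
#' the graph (guarded by `limit`) and runs an independent, simple, scalar
#' affine-gap DP ([oracle_pairwise()]) of the read against each path sequence,
#' returning the maximum.  Implemented separately from the batched engine —
#' no recurrence code is shared — so it serves as an independent oracle in
#' property tests.
#'
#' @param graph A `ref_graph`.
#' @param read Read sequence.
#' @param quals Optional integer Phred qualities.
#' @param model A [scoring_model()].
#' @param limit Path-count guard (refuses larger graphs).
#' @return Optimal alignment score (numeric).
#' @export
oracle_align <- function(graph, read, quals = NULL, model, limit = 1e4) {
  paths <- enumerate_paths(graph, limit = limit)
  max(vapply(paths, function(p)
    oracle_pairwise(path_sequence(graph, p), read, quals, model),
    numeric(1)))
}

#' Simple scalar affine-gap pairwise DP (oracle)
#'
#' Textbook three-matrix affine-gap recurrence over one reference string and
#' one read, with `-Inf` initialization, written as plain nested loops; used
#' only as an oracle.
#'
#' @param ref Reference sequence (one path).
#' @param read Read sequence.
#' @param quals Optional integer Phred qualities.
#' @param model A [scoring_model()].
#' @return Optimal score: in semiglobal mode the maximum over the last read
#'   row; in local mode the maximum cell (at least 0).
#' @export
oracle_pairwise <- function(ref, read, quals = NULL, model) {
  stopifnot(inherits(model, "scoring_model"))
  a <- .encode_seq(ref); b <- .encode_seq(read)
  L <- length(a); m <- length(b)
  pen <- if (is.null(quals)) rep.int(model$mismatch_max, m) else
    mismatch_penalty(model, quals)
  go <- model$gap_open; ge <- model$gap_extend
  local <- model$mode == "local"
  H <- matrix(-Inf, m + 1L, L + 1L)
  E <- matrix(-Inf, m + 1L, L + 1L)
  F <- matrix(-Inf, m + 1L, L + 1L)
  H[1L, ] <- 0
  for (i in seq_len(m)) {
    F[i + 1L, 1L] <- max(H[i, 1L] - go - ge, F[i, 1L] - ge)
    H[i + 1L, 1L] <- if (local) 0 else F[i + 1L, 1L]
  }
  for (j in seq_len(L)) {
    for (i in seq_len(m)) {
      s <- if (b[i] == 5L || a[j] == 5L) -model$ambig_penalty
      else if (b[i] == a[j]) model$match else -pen[i]
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - go - ge, E[i + 1L, j] - ge)
      F[i + 1L, j + 1L] <- max(H[i, j + 1L] - go - ge, F[i, j + 1L] - ge)
      h <- max(H[i, j] + s, E[i + 1L, j + 1L], F[i + 1L, j + 1L])
      if (local && h < 0) h <- 0
      H[i + 1L, j + 1L] <- h
    }
  }
  if (local) max(H, 0) else max(H[m + 1L, ])
}
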