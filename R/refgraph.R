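#' Build a variation-graph reference from a linear sequence and variants
#'
#' Constructs a directed acyclic graph (DAG) whose source-to-sink paths spell
#' exactly the reference sequence plus every combination of the kept,
#' non-overlapping alternate alleles.  Genetic variants induce forks and joins:
#' a SNP or multi-allelic substitution becomes parallel branch nodes, an
#' insertion becomes an off-reference node with a bypass edge, and a deletion
#' becomes a bypass edge around the deleted reference node (never an empty
#' node, so every dynamic-programming column carries a character).
#'
#' Alleles are normalized before placement (shared prefix/suffix bases trimmed,
#' as for the anchor base VCF indel records carry); records whose normalized
#' reference spans coincide are merged into one multi-allelic fork, while
#' distinct partially-overlapping spans are rejected.  Maximal unbranched runs
#' of reference sequence are merged into single nodes.  Nodes on parallel
#' paths are right-aligned to the reference: every node carries the 1-based
#' reference coordinate of its last base (`ref_end`), so alignments on
#' alternate paths stay anchored to reference coordinates despite indel-induced
#' shifts.
#'
#' @param reference Reference sequence: a character string (or a named
#'   length-one character vector, e.g. from [read_fasta()]).
#' @param variants `NULL`, or a data frame with columns `pos` (1-based
#'   reference coordinate), `ref` (reference allele, must match the reference),
#'   `alt` (alternate allele; comma-separated for multi-allelic records) and
#'   optionally `af` (allele frequency in `[0,1]`, `NA` when unknown), sorted
#'   by `pos`.
#' @param min_af Variants with known allele frequency below `min_af` are
#'   dropped.  Records lacking a frequency are kept when `min_af = 0` and
#'   dropped otherwise (conservative).
#' @param ref_name Name recorded for the reference sequence; defaults to the
#'   name of `reference` when present.
#' @return An object of class `ref_graph`: a list with `nodes` (data frame
#'   `id`, `ref_end`, `span`, `is_ref`, `seq`, in topological order), `edges`
#'   (data frame `from`, `to`), `ref_name`, `ref_length` and `columns`, the
#'   linearized column index (see [linearize()]).
#' @examples
#' v <- data.frame(pos = c(5, 4), ref = c("A", "TA"), alt = c("T", "T"))
#' g <- build_graph("ACGTACGT", v[order(v$pos), ])
#' g$nodes$seq     # "ACGT" "A" "T" "CGT"
#' nrow(g$columns) # 9 dynamic-programming columns
#' @export
build_graph <- function(reference, variants = NULL, min_af = 0, ref_name = NULL) {
  if (is.null(ref_name))
    ref_name <- if (!is.null(names(reference))) names(reference)[1] else "ref"
  reference <- toupper(as.character(reference)[1])
  if (is.na(reference) || nchar(reference) < 1L)
    stop("reference sequence must be non-empty", call. = FALSE)
  if (grepl("[^ACGTN]", reference))
    stop("reference contains characters outside {A,C,G,T,N}", call. = FALSE)
  L <- nchar(reference)

  sites <- .collect_sites(reference, variants, min_af)

  nodes <- list(); edges_from <- integer(); edges_to <- integer()
  add_node <- function(seq, ref_end, span, is_ref) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, ref_end = as.integer(ref_end),
                         span = as.integer(span), is_ref = is_ref, seq = seq)
    id
  }
  add_edges <- function(from, to) {
    for (f in from) for (t in to) {
      edges_from <<- c(edges_from, f); edges_to <<- c(edges_to, t)
    }
  }

  cursor <- 1L
  tails <- integer(0)
  for (site in sites) {
    s <- site$start; e <- site$end
    if (s > cursor) {
      seg <- add_node(substr(reference, cursor, s - 1L), s - 1L, s - cursor, TRUE)
      add_edges(tails, seg)
      tails <- seg
    }
    branches <- integer(0)
    if (e >= s)  # non-empty reference span: the reference-path branch node
      branches <- add_node(substr(reference, s, e), e, e - s + 1L, TRUE)
    has_skip <- e < s  # pure insertion: reference path bypasses the alt node
    for (alt in site$alts) {
      if (nzchar(alt)) {
        branches <- c(branches, add_node(alt, max(e, s - 1L), max(e - s + 1L, 0L), FALSE))
      } else {
        has_skip <- TRUE  # deletion allele: bypass edge, no node
      }
    }
    add_edges(tails, branches)
    tails <- if (has_skip) c(tails, branches) else branches
    cursor <- e + 1L
  }
  if (cursor <= L) {
    seg <- add_node(substr(reference, cursor, L), L, L - cursor + 1L, TRUE)
    add_edges(tails, seg)
  }

  nodes_df <- data.frame(
    id      = vapply(nodes, `[[`, integer(1), "id"),
    ref_end = vapply(nodes, `[[`, integer(1), "ref_end"),
    span    = vapply(nodes, `[[`, integer(1), "span"),
    is_ref  = vapply(nodes, `[[`, logical(1), "is_ref"),
    seq     = vapply(nodes, `[[`, character(1), "seq"),
    stringsAsFactors = FALSE
  )
  edges_df <- unique(data.frame(from = edges_from, to = edges_to))
  rownames(edges_df) <- NULL
  g <- structure(list(nodes = nodes_df, edges = edges_df, ref_name = ref_name,
                      ref_length = L, columns = NULL),
                 class = "ref_graph")
  g$columns <- linearize(g)
  .validate_graph(g, reference)
  g
}

# Normalize, filter and group variant records into fork sites.
.collect_sites <- function(reference, variants, min_af) {
  if (is.null(variants) || nrow(as.data.frame(variants)) == 0L) return(list())
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  stopifnot(all(c("pos", "ref", "alt") %in% names(variants)))
  if (is.null(variants$af)) variants$af <- NA_real_
  if (is.unsorted(variants$pos)) stop("variants must be sorted by pos", call. = FALSE)
  if (min_af < 0 || min_af > 1) stop("'min_af' must be in [0,1]", call. = FALSE)
  if (min_af > 0)
    variants <- variants[!is.na(variants$af) & variants$af >= min_af, , drop = FALSE]
  if (nrow(variants) == 0L) return(list())

  sites <- list()  # keyed by "start:end" of the normalized span
  descr <- function(v) sprintf("pos %d %s>%s", v$pos, v$ref, v$alt)
  for (k in seq_len(nrow(variants))) {
    v <- variants[k, ]
    ref <- toupper(v$ref)
    if (substr(reference, v$pos, v$pos + nchar(ref) - 1L) != ref)
      stop(sprintf("variant at pos %d: ref allele '%s' does not match the reference",
                   v$pos, ref), call. = FALSE)
    for (alt in strsplit(toupper(v$alt), ",", fixed = TRUE)[[1]]) {
      if (!nzchar(ref) || !nzchar(alt))
        stop(sprintf("variant at pos %d: alleles must be non-empty (VCF anchor-base convention)",
                     v$pos), call. = FALSE)
      if (grepl("[^ACGTN]", alt))
        stop(sprintf("variant at pos %d: alt allele has characters outside {A,C,G,T,N}",
                     v$pos), call. = FALSE)
      n <- .normalize_allele(v$pos, ref, alt)
      key <- paste0(n$start, ":", n$end)
      if (is.null(sites[[key]]))
        sites[[key]] <- list(start = n$start, end = n$end, alts = character(0),
                             record = descr(v))
      sites[[key]]$alts <- unique(c(sites[[key]]$alts, n$alt))
    }
  }
  sites <- sites[order(vapply(sites, function(s) s$start - 0.5 * (s$end < s$start),
                              numeric(1)))]
  # reject partially overlapping (non-identical) spans
  if (length(sites) > 1L) {
    for (i in seq_len(length(sites) - 1L)) {
      a <- sites[[i]]; b <- sites[[i + 1L]]
      a_end <- max(a$end, a$start - 0.5); b_start <- b$start - 0.5 * (b$end < b$start)
      if (b_start <= a_end)
        stop(sprintf("overlapping variants: [%s] and [%s] have intersecting reference spans",
                     a$record, b$record), call. = FALSE)
    }
  }
  sites
}

# Trim shared suffix then prefix bases (VCF minimal representation); returns
# the normalized span [start, end] (end < start for a pure insertion) and the
# remaining alt string ("" for a pure deletion).
.normalize_allele <- function(pos, ref, alt) {
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1L, nchar(ref) - 1L)
    alt <- substr(alt, 1L, nchar(alt) - 1L)
  }
  while (nchar(ref) >= 1L && nchar(alt) >= 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L) &&
         !(nchar(ref) == 1L && nchar(alt) == 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  if (ref == alt) stop(sprintf("variant at pos %d: ref and alt alleles are identical", pos),
                       call. = FALSE)
  list(start = as.integer(pos), end = as.integer(pos + nchar(ref) - 1L), alt = alt)
}

.validate_graph <- function(g, reference = NULL) {
  if (nrow(g$edges) > 0L && any(g$edges$from >= g$edges$to))
    stop("internal error: node order is not topological", call. = FALSE)
  recon <- paste(g$nodes$seq[g$nodes$is_ref], collapse = "")
  if (!is.null(reference) && recon != reference)
    stop("internal error: reference-path nodes do not reconstruct the reference",
         call. = FALSE)
  if (nrow(g$columns) != sum(nchar(g$nodes$seq)))
    stop("internal error: column count differs from total node length", call. = FALSE)
  invisible(g)
}

#' Linearize a graph into dynamic-programming columns
#'
#' Enumerates all node characters in topological node order; each column
#' carries its anchored, 1-based reference coordinate.  Alternate-path columns
#' are right-aligned: the last base of an alternate node takes the reference
#' coordinate of the span it replaces, earlier bases count backwards, and
#' bases overhanging the span (insertions) share the anchor coordinate of the
#' adjacent reference position.
#'
#' @param graph A `ref_graph`.
#' @return Data frame with one row per column: `column` (1-based, in the order
#'   the dynamic program fills them), `node` (node id), `offset` (1-based
#'   offset within the node) and `coord` (anchored reference coordinate).
#' @export
linearize <- function(graph) {
  stopifnot(inherits(graph, "ref_graph"))
  n <- nrow(graph$nodes)
  lens <- nchar(graph$nodes$seq)
  node <- rep.int(graph$nodes$id, lens)
  offset <- sequence(lens)
  coord <- integer(sum(lens))
  pos <- 1L
  for (i in seq_len(n)) {
    e <- graph$nodes$ref_end[i]; len <- lens[i]; sp <- graph$nodes$span[i]
    raw <- (e - len + 1L):e
    floorc <- if (sp >= 1L) e - sp + 1L else e
    coord[pos:(pos + len - 1L)] <- pmax(raw, floorc)
    pos <- pos + len
  }
  data.frame(column = seq_along(node), node = node, offset = offset, coord = coord)
}

#' Enumerate all source-to-sink paths of a graph
#'
#' @param graph A `ref_graph`.
#' @param limit Refuse to enumerate more than this many paths.
#' @return List of integer vectors of node ids.
#' @export
enumerate_paths <- function(graph, limit = 1e4) {
  stopifnot(inherits(graph, "ref_graph"))
  n <- nrow(graph$nodes)
  succ <- split(graph$edges$to, factor(graph$edges$from, levels = seq_len(n)))
  has_in <- seq_len(n) %in% graph$edges$to
  # count paths first (topological order = id order, reversed)
  npath <- numeric(n)
  for (v in rev(seq_len(n)))
    npath[v] <- if (length(succ[[v]]) == 0L) 1 else sum(npath[succ[[v]]])
  total <- sum(npath[!has_in])
  if (total > limit)
    stop(sprintf("graph has %g source-to-sink paths, above the enumeration guard (%g)",
                 total, limit), call. = FALSE)
  out <- vector("list", 0L)
  walk <- function(v, acc) {
    acc <- c(acc, v)
    if (length(succ[[v]]) == 0L) out[[length(out) + 1L]] <<- acc
    else for (w in succ[[v]]) walk(w, acc)
  }
  for (v in which(!has_in)) walk(v, integer(0))
  out
}

#' Sequence spelled by a node path
#'
#' @param graph A `ref_graph`.
#' @param path Integer vector of node ids (e.g. from [enumerate_paths()]).
#' @return Character string.
#' @export
path_sequence <- function(graph, path) {
  paste(graph$nodes$seq[match(path, graph$nodes$id)], collapse = "")
}

#' @export
print.ref_graph <- function(x, ...) {
  cat(sprintf("<ref_graph> %s: %d bp reference, %d nodes, %d edges, %d DP columns\n",
              x$ref_name, x$ref_length, nrow(x$nodes), nrow(x$edges), nrow(x$columns)))
  invisible(x)
}

#' Save / load a reference graph
#'
#' Plain-text, line-oriented serialization: a header line, one `node` line per
#' node (`id`, `ref_end`, `span`, `is_ref`, `seq`) and one `edge` line per
#' edge.  The round trip is the identity on all fields.
#'
#' @param graph A `ref_graph`.
#' @param path File path.
#' @return `load_graph` returns the `ref_graph`; `save_graph` returns `path`
#'   invisibly.
#' @export
save_graph <- function(graph, path) {
  stopifnot(inherits(graph, "ref_graph"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#goldalign-graph\tv1",
               sprintf("ref\t%s\t%d", graph$ref_name, graph$ref_length)), con)
  writeLines(sprintf("node\t%d\t%d\t%d\t%d\t%s",
                     graph$nodes$id, graph$nodes$ref_end, graph$nodes$span,
                     as.integer(graph$nodes$is_ref), graph$nodes$seq), con)
  if (nrow(graph$edges) > 0L)
    writeLines(sprintf("edge\t%d\t%d", graph$edges$from, graph$edges$to), con)
  invisible(path)
}

#' @rdname save_graph
#' @export
load_graph <- function(path) {
  lines <- readLines(path)
  bad <- function(i, why) stop(sprintf("malformed graph file %s, line %d: %s",
                                       path, i, why), call. = FALSE)
  if (length(lines) < 2L || lines[1] != "#goldalign-graph\tv1")
    bad(1L, "missing or unrecognized header")
  hdr <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  if (length(hdr) != 3L || hdr[1] != "ref") bad(2L, "expected 'ref\\tNAME\\tLENGTH'")
  nodes <- list(); edges_from <- integer(); edges_to <- integer()
  for (i in seq_along(lines)[-(1:2)]) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (f[1] == "node") {
      if (length(f) != 6L) bad(i, "node line needs 6 fields")
      if (grepl("[^ACGTN]", f[6])) bad(i, "node sequence outside {A,C,G,T,N}")
      nodes[[length(nodes) + 1L]] <- f
    } else if (f[1] == "edge") {
      if (length(f) != 3L) bad(i, "edge line needs 3 fields")
      edges_from <- c(edges_from, as.integer(f[2]))
      edges_to <- c(edges_to, as.integer(f[3]))
    } else bad(i, sprintf("unknown record type '%s'", f[1]))
  }
  if (length(nodes) == 0L) bad(length(lines), "no node lines (truncated file?)")
  nodes_df <- data.frame(
    id      = as.integer(vapply(nodes, `[[`, character(1), 2L)),
    ref_end = as.integer(vapply(nodes, `[[`, character(1), 3L)),
    span    = as.integer(vapply(nodes, `[[`, character(1), 4L)),
    is_ref  = as.integer(vapply(nodes, `[[`, character(1), 5L)) == 1L,
    seq     = vapply(nodes, `[[`, character(1), 6L),
    stringsAsFactors = FALSE
  )
  if (any(is.na(nodes_df$id)) || any(nodes_df$id != seq_len(nrow(nodes_df))))
    stop(sprintf("malformed graph file %s: node ids are not 1..n in order", path),
         call. = FALSE)
  g <- structure(list(nodes = nodes_df,
                      edges = data.frame(from = edges_from, to = edges_to),
                      ref_name = hdr[2], ref_length = as.integer(hdr[3]),
                      columns = NULL),
                 class = "ref_graph")
  if (nrow(g$edges) > 0L &&
      (anyNA(g$edges) || any(g$edges$from >= g$edges$to) ||
       any(g$edges$to > nrow(nodes_df)) || any(g$edges$from < 1L)))
    stop(sprintf("malformed graph file %s: invalid edge", path), call. = FALSE)
  g$columns <- linearize(g)
  .validate_graph(g)
  g
}
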