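## Auditing heuristic aligners against guaranteed-optimal alignments.
##
## A heuristic alignment is "correct-by-score" when the score it reports
## equals the true optimal alignment score for that read under the same
## scoring function; it is "correct-by-location" when its coordinate matches
## the truth coordinate within a tolerance.  Both definitions require that
## the heuristic was run with the very scoring function the optimum was
## computed for — a heuristic score above the optimum is a configuration
## error, not a data point, and is raised as such.

.cigar_ref_span <- function(cigar) {
  cg <- .parse_cigar(cigar)
  if (is.null(cg)) return(NA_integer_)
  sum(cg$len[cg$op %in% c("M", "D", "=", "X", "N")])
}

#' Audit heuristic alignments by score
#'
#' Compares each primary heuristic alignment's reported score (`AS` tag)
#' against the optimal score for the same read and bins the outcome by the
#' optimal score.  A read is `correct_by_score` iff it is aligned and its
#' heuristic score equals the optimum; unaligned reads are counted separately
#' (they are not correct).  A heuristic score exceeding the optimum raises a
#' scoring-function-mismatch error naming the read.
#'
#' @param heuristic Data frame from [read_sam()] (secondary/supplementary
#'   records are dropped automatically), or any data frame with columns
#'   `qname`, `unaligned` and a score column `score` or an `AS` tag.
#' @param optimal Data frame keyed by read id with the optimal scores: either
#'   [align_batch()] output (`id`, `best_score`) or a data frame with
#'   `qname`/`id` and `optimal_score`/`best_score`.
#' @param bin_width Width of the optimal-score bins of the summary (default
#'   10).
#' @return List of class `score_audit` with `records` (per-read `qname`,
#'   `heuristic_score`, `optimal_score`, `status`) and `summary` (per bin:
#'   `bin`, `n`, `frac_correct`, `frac_incorrect`, `frac_unaligned`).
#' @export
score_audit <- function(heuristic, optimal, bin_width = 10) {
  heuristic <- as.data.frame(heuristic)
  if (!is.null(heuristic$secondary))
    heuristic <- heuristic[!heuristic$secondary & !heuristic$supplementary, ,
                           drop = FALSE]
  hid <- if (!is.null(heuristic$qname)) heuristic$qname else heuristic$id
  hscore <- if (!is.null(heuristic$score)) heuristic$score else
    if (!is.null(heuristic$tags)) sam_tag(heuristic, "AS") else
      heuristic$best_score
  hunaligned <- if (!is.null(heuristic$unaligned)) heuristic$unaligned else
    !heuristic$aligned

  optimal <- as.data.frame(optimal)
  oid <- if (!is.null(optimal$id)) optimal$id else optimal$qname
  oscore <- if (!is.null(optimal$optimal_score)) optimal$optimal_score else
    optimal$best_score

  idx <- match(hid, oid)
  if (anyNA(idx))
    stop(sprintf("read '%s' present in the heuristic set but absent from the optimal set",
                 hid[which(is.na(idx))[1]]), call. = FALSE)
  opt <- oscore[idx]
  over <- !hunaligned & !is.na(hscore) & hscore > opt
  if (any(over))
    stop(sprintf(paste0("scoring mismatch: read '%s' has heuristic score %d above ",
                        "the optimal score %d; the heuristic was not run with ",
                        "this scoring function"),
                 hid[which(over)[1]], hscore[which(over)[1]], opt[which(over)[1]]),
         call. = FALSE)
  status <- ifelse(hunaligned | is.na(hscore), "unaligned",
                   ifelse(hscore == opt, "correct_by_score", "incorrect_by_score"))
  records <- data.frame(qname = hid,
                        heuristic_score = ifelse(hunaligned, NA, hscore),
                        optimal_score = opt, status = status,
                        stringsAsFactors = FALSE)
  bins <- bin_width * floor(opt / bin_width)
  summary <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    s <- status[bins == b]
    data.frame(bin = b, n = length(s),
               frac_correct = mean(s == "correct_by_score"),
               frac_incorrect = mean(s == "incorrect_by_score"),
               frac_unaligned = mean(s == "unaligned"))
  }))
  structure(list(records = records, summary = summary, bin_width = bin_width),
            class = "score_audit")
}

#' @export
print.score_audit <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("<score_audit> %d reads: %.1f%% correct-by-score, %.1f%% incorrect, %.1f%% unaligned\n",
              n, 100 * mean(x$records$status == "correct_by_score"),
              100 * mean(x$records$status == "incorrect_by_score"),
              100 * mean(x$records$status == "unaligned")))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Audit heuristic alignments by location
#'
#' A read is correct-by-location iff it is aligned to the expected reference
#' sequence and its coordinate is within `tolerance` bases of the truth
#' coordinate.  Truth coordinates anchor the rightmost aligned read base (the
#' engine's and simulator's convention); when a heuristic record carries a
#' CIGAR, its leftmost `POS` is converted to the rightmost-base anchor
#' (`POS + reference-span(CIGAR) - 1`) before comparison, otherwise `POS` is
#' compared as-is.
#'
#' @param heuristic Data frame from [read_sam()].
#' @param truth Data frame with `qname`/`id`, `coord` and optionally `rname`.
#' @param tolerance Allowed coordinate difference in bp (default 5).
#' @return List of class `location_audit` with `records` (per-read `qname`,
#'   `pos`, `truth`, `correct`) and the overall `frac_correct`.
#' @export
location_audit <- function(heuristic, truth, tolerance = 5) {
  heuristic <- as.data.frame(heuristic)
  if (!is.null(heuristic$secondary))
    heuristic <- heuristic[!heuristic$secondary & !heuristic$supplementary, ,
                           drop = FALSE]
  truth <- as.data.frame(truth)
  tid <- if (!is.null(truth$id)) truth$id else truth$qname
  idx <- match(heuristic$qname, tid)
  if (anyNA(idx))
    stop(sprintf("read '%s' has no truth entry", heuristic$qname[which(is.na(idx))[1]]),
         call. = FALSE)
  tcoord <- truth$coord[idx]
  pos <- heuristic$pos
  if (!is.null(heuristic$cigar)) {
    span <- vapply(heuristic$cigar, .cigar_ref_span, integer(1), USE.NAMES = FALSE)
    pos <- ifelse(is.na(span), pos, pos + span - 1L)
  }
  same_ref <- if (!is.null(truth$rname) && !is.null(heuristic$rname))
    heuristic$rname == truth$rname[idx] else TRUE
  correct <- !heuristic$unaligned & same_ref & abs(pos - tcoord) <= tolerance
  records <- data.frame(qname = heuristic$qname, pos = pos, truth = tcoord,
                        correct = correct, stringsAsFactors = FALSE)
  structure(list(records = records, frac_correct = mean(correct),
                 tolerance = tolerance),
            class = "location_audit")
}

#' MAPQ calibration report
#'
#' Groups reads by aligner-assigned mapping quality and compares each group's
#' empirical error rate with the MAPQ definition
#' `MAPQ = -10 * log10(Pr[read is incorrectly mapped])`: a perfectly
#' calibrated aligner has `empirical_mapq == mapq` in every bin.  Bins with no
#' incorrect reads are reported at the cap value and flagged.
#'
#' @param records Data frame with columns `mapq` (integer) and `correct`
#'   (logical, correct-by-location).
#' @param cap Empirical MAPQ reported for zero-incorrect bins (default 60).
#' @return Data frame with one row per distinct MAPQ: `mapq`, `n`,
#'   `incorrect_fraction`, `empirical_mapq`, `capped`.
#' @export
mapq_calibration <- function(records, cap = 60) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L)
    return(data.frame(mapq = integer(0), n = integer(0),
                      incorrect_fraction = numeric(0),
                      empirical_mapq = numeric(0), capped = logical(0)))
  stopifnot(!is.null(records$mapq), !is.null(records$correct))
  out <- do.call(rbind, lapply(sort(unique(records$mapq)), function(q) {
    sel <- records$correct[records$mapq == q]
    frac <- mean(!sel)
    emp <- if (frac == 0) cap else min(-10 * log10(frac), cap)
    data.frame(mapq = q, n = length(sel), incorrect_fraction = frac,
               empirical_mapq = emp, capped = frac == 0)
  }))
  rownames(out) <- NULL
  out
}

#' Parameter-sweep ratio report
#'
#' Summarizes a parameter sweep as ratios against a baseline run, one column
#' per setting: percent of reads aligned, percent correct-by-score, mean
#' alignment-score difference (optimal minus heuristic) over aligned reads,
#' the same over incorrect-by-score aligned reads, and wall time.  The
#' baseline column is identically 1 by construction.
#'
#' @param runs Named list; each element a list with `records` (the per-read
#'   records of a [score_audit()], or a data frame with `qname`, `status`,
#'   `heuristic_score`, `optimal_score`) and `time` (wall seconds).
#' @param baseline Name of the baseline run, present in `runs`.
#' @return List of class `sweep_report` with `measurements` (absolute values)
#'   and `ratios` (each measurement divided by the baseline's), both with one
#'   row per statistic and one column per setting.
#' @export
sweep_report <- function(runs, baseline) {
  if (!baseline %in% names(runs))
    stop(sprintf("baseline '%s' is not among the runs", baseline), call. = FALSE)
  ids <- lapply(runs, function(r) sort(r$records$qname))
  if (!all(vapply(ids, identical, logical(1), ids[[1]])))
    stop("all runs must evaluate the same read set", call. = FALSE)
  meas <- vapply(runs, function(r) {
    rec <- r$records
    aligned <- rec$status != "unaligned"
    diffs <- rec$optimal_score - rec$heuristic_score
    wrong <- aligned & rec$status == "incorrect_by_score"
    c(pct_aligned = 100 * mean(aligned),
      pct_correct_score = 100 * mean(rec$status == "correct_by_score"),
      mean_as_diff_aligned = if (any(aligned)) mean(diffs[aligned]) else NA_real_,
      mean_as_diff_incorrect = if (any(wrong)) mean(diffs[wrong]) else NA_real_,
      time = r$time)
  }, numeric(5))
  ratios <- meas / meas[, baseline]
  structure(list(measurements = meas, ratios = ratios, baseline = baseline),
            class = "sweep_report")
}

#' @export
print.sweep_report <- function(x, ...) {
  cat(sprintf("<sweep_report> ratios vs baseline '%s':\n", x$baseline))
  print(round(x$ratios, 2))
  invisible(x)
}
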