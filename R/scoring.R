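#' Scoring model for heuristic-free alignment
#'
#' A scoring model bundles the alignment mode with the match bonus, the
#' quality-scaled mismatch penalty range, affine gap penalties and the penalty
#' applied to ambiguous (`N`) positions.  Penalties are stored as non-negative
#' magnitudes; during alignment bonuses add to and penalties subtract from the
#' signed score.
#'
#' In `semiglobal` mode every read base is aligned end-to-end while unaligned
#' reference flanks are free (fitting alignment).  In `local` mode any read
#' substring may align and cell scores are floored at zero (Smith-Waterman);
#' local mode requires `match > 0`, otherwise no alignment can rise above the
#' zero floor.
#'
#' A mismatch against a base of Phred quality `q` costs
#' `mismatch_min + floor((mismatch_max - mismatch_min) * min(q, quality_ceiling) / quality_ceiling)`,
#' i.e. the penalty is interpolated between `mismatch_min` (quality 0) and
#' `mismatch_max` (quality at or above the ceiling).  When no quality is
#' available the maximum penalty applies.
#'
#' @param mode `"semiglobal"` or `"local"`.
#' @param match Non-negative integer bonus for a matching base.
#' @param mismatch_min,mismatch_max Non-negative integer penalty bounds for a
#'   mismatching base, `mismatch_min <= mismatch_max`.
#' @param gap_open Non-negative integer penalty charged on the first base of a
#'   gap, in addition to `gap_extend`.
#' @param gap_extend Non-negative integer penalty per gap base.
#' @param ambig_penalty Non-negative integer penalty for any aligned pair
#'   involving an `N`; `N` never matches.
#' @param quality_ceiling Phred value at which the mismatch penalty saturates
#'   at `mismatch_max`.
#' @return An object of class `scoring_model`.
#' @seealso [scoring_preset()], [mismatch_penalty()], [score_range()],
#'   [select_cell_width()]
#' @examples
#' m <- scoring_model("semiglobal", match = 0, mismatch_min = 2, mismatch_max = 6,
#'                    gap_open = 5, gap_extend = 3)
#' mismatch_penalty(m, 20)
#' @export
scoring_model <- function(mode = c("semiglobal", "local"),
                          match = 0L,
                          mismatch_min = 2L,
                          mismatch_max = 6L,
                          gap_open = 5L,
                          gap_extend = 3L,
                          ambig_penalty = 1L,
                          quality_ceiling = 40L) {
  mode <- match.arg(mode)
  num1 <- function(x, name) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != round(x))
      stop(sprintf("'%s' must be a single non-negative integer", name), call. = FALSE)
    as.integer(x)
  }
  m <- structure(list(
    mode            = mode,
    match           = num1(match, "match"),
    mismatch_min    = num1(mismatch_min, "mismatch_min"),
    mismatch_max    = num1(mismatch_max, "mismatch_max"),
    gap_open        = num1(gap_open, "gap_open"),
    gap_extend      = num1(gap_extend, "gap_extend"),
    ambig_penalty   = num1(ambig_penalty, "ambig_penalty"),
    quality_ceiling = num1(quality_ceiling, "quality_ceiling")
  ), class = "scoring_model")
  if (m$mismatch_min > m$mismatch_max)
    stop("'mismatch_min' must not exceed 'mismatch_max'", call. = FALSE)
  if (m$quality_ceiling < 1L)
    stop("'quality_ceiling' must be >= 1", call. = FALSE)
  if (m$mode == "local" && m$match == 0L)
    stop("local mode requires match > 0 (otherwise nothing scores above the zero floor)",
         call. = FALSE)
  m
}

#' @export
print.scoring_model <- function(x, ...) {
  cat(sprintf(
    "<scoring_model> mode=%s match=%d mismatch=[%d,%d] gap=%d/%d N=%d qceil=%d\n",
    x$mode, x$match, x$mismatch_min, x$mismatch_max,
    x$gap_open, x$gap_extend, x$ambig_penalty, x$quality_ceiling))
  invisible(x)
}

#' Quality-scaled mismatch penalty
#'
#' @param model A [scoring_model()].
#' @param q Phred quality value(s), or `NA`/`NULL` when no quality is known
#'   (the maximum penalty then applies).
#' @return Non-negative integer penalty magnitude(s), in
#'   `[mismatch_min, mismatch_max]`.
#' @export
mismatch_penalty <- function(model, q = NULL) {
  stopifnot(inherits(model, "scoring_model"))
  if (is.null(q)) return(model$mismatch_max)
  q <- as.numeric(q)
  if (length(q) == 0L) return(integer(0))
  if (any(q < 0, na.rm = TRUE)) stop("Phred quality must be >= 0", call. = FALSE)
  pen <- model$mismatch_min +
    floor((model$mismatch_max - model$mismatch_min) *
            pmin(q, model$quality_ceiling) / model$quality_ceiling)
  pen[is.na(q)] <- model$mismatch_max
  as.integer(pen)
}

#' Possible alignment score range for a read length
#'
#' The maximum is a full-length run of matches; the minimum is zero in local
#' mode (zero floor) and otherwise a safe per-base worst-cost bound,
#' `-read_length * max(mismatch_max, gap_open + gap_extend)`: every consumed
#' read base costs at most a maximal mismatch or a freshly opened gap base, so
#' the true optimum can never fall below this bound.
#'
#' @param model A [scoring_model()].
#' @param read_length Read length in bases, `>= 1`.
#' @return Integer vector `c(min_score, max_score)`.
#' @export
score_range <- function(model, read_length) {
  stopifnot(inherits(model, "scoring_model"),
            is.numeric(read_length), length(read_length) == 1L, read_length >= 1)
  read_length <- as.integer(read_length)
  max_score <- read_length * model$match
  min_score <- if (model$mode == "local") 0L else
    -read_length * max(model$mismatch_max, model$gap_open + model$gap_extend)
  c(min_score = as.integer(min_score), max_score = as.integer(max_score))
}

#' Select the score-cell width for a batch
#'
#' Mirrors the runtime operand-width rule of SIMD exact aligners: if the
#' difference between the maximum and minimum possible alignment scores exceeds
#' 255 for the given read length and scoring function, 16-bit (`"wide"`) score
#' cells are required; otherwise biased unsigned 8-bit-representable
#' (`"narrow"`) cells suffice.  The rule is strict: a range of exactly 255 is
#' still narrow.
#'
#' @inheritParams score_range
#' @return `"narrow"` or `"wide"`.
#' @export
select_cell_width <- function(model, read_length) {
  r <- score_range(model, read_length)
  if ((r[["max_score"]] - r[["min_score"]]) > 255L) "wide" else "narrow"
}

# Documented preset table.  Values are this package's documented defaults for
# the three scoring families it mimics; every field can be overridden.
.presets <- list(
  `sg-default` = list(mode = "semiglobal", match = 0L, mismatch_min = 2L,
                      mismatch_max = 6L, gap_open = 5L, gap_extend = 3L),
  `local-default` = list(mode = "local", match = 2L, mismatch_min = 2L,
                         mismatch_max = 6L, gap_open = 5L, gap_extend = 3L),
  `local-flat` = list(mode = "local", match = 1L, mismatch_min = 4L,
                      mismatch_max = 4L, gap_open = 6L, gap_extend = 1L)
)

#' Named scoring presets
#'
#' Three ready-made models covering the common scoring families of short-read
#' aligners: `"sg-default"` (end-to-end semiglobal, match 0, quality-scaled
#' mismatch 2..6, gaps 5/3), `"local-default"` (local, match 2, mismatch 2..6,
#' gaps 5/3) and `"local-flat"` (local with a constant mismatch penalty:
#' match 1, mismatch 4, gaps 6/1).
#'
#' @param name Preset name.
#' @param ... Field overrides passed to [scoring_model()].
#' @return A [scoring_model()].
#' @export
scoring_preset <- function(name, ...) {
  if (length(name) != 1L || !name %in% names(.presets))
    stop(sprintf("unknown preset '%s'; valid presets: %s",
                 paste(name, collapse = ","),
                 paste(names(.presets), collapse = ", ")), call. = FALSE)
  args <- utils::modifyList(.presets[[name]], list(...))
  do.call(scoring_model, args)
}

#' @rdname scoring_preset
#' @export
scoring_presets <- function() names(.presets)
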