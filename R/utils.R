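# Internal helpers shared across modules: run/interval arithmetic on the
# sample grid, and seed-local evaluation.
#
# Convention: sample i (1-based) covers the half-open time slab
# [(i-1)/fs, i/fs); intervals are half-open [start_s, end_s). All duration
# and gap comparisons are done in integer samples to keep threshold
# comparisons exact on the sample grid.

# maximal runs of TRUE as a data.frame(first, last) in sample indices
runs_from_mask <- function(mask) {
  stopifnot(is.logical(mask))
  if (!any(mask)) {
    return(data.frame(first = integer(0), last = integer(0)))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(first = starts[keep], last = ends[keep])
}

mask_from_runs <- function(runs, n) {
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(runs))) {
    mask[runs$first[i]:runs$last[i]] <- TRUE
  }
  mask
}

# merge runs separated by a gap of strictly fewer than gap_n samples
merge_run_gaps <- function(runs, gap_n) {
  if (nrow(runs) < 2L || gap_n <= 0L) return(runs)
  first <- runs$first
  last <- runs$last
  out_first <- first[1]
  out_last <- last[1]
  for (i in 2:length(first)) {
    gap <- first[i] - out_last[length(out_last)] - 1L
    if (gap < gap_n) {
      out_last[length(out_last)] <- last[i]
    } else {
      out_first <- c(out_first, first[i])
      out_last <- c(out_last, last[i])
    }
  }
  data.frame(first = out_first, last = out_last)
}

# keep runs of at least min_n samples (strict = FALSE) or more than min_n
# samples (strict = TRUE)
filter_run_length <- function(runs, min_n, strict = FALSE) {
  len <- runs$last - runs$first + 1L
  keep <- if (strict) len > min_n else len >= min_n
  runs[keep, , drop = FALSE]
}

runs_to_intervals <- function(runs, fs) {
  data.frame(
    start_s = (runs$first - 1L) / fs,
    end_s = runs$last / fs
  )
}

intervals_to_runs <- function(intervals, fs, n) {
  if (nrow(intervals) == 0L) {
    return(data.frame(first = integer(0), last = integer(0)))
  }
  first <- pmax(1L, as.integer(round(intervals$start_s * fs)) + 1L)
  last <- pmin(as.integer(n), as.integer(round(intervals$end_s * fs)))
  keep <- last >= first
  data.frame(first = first[keep], last = last[keep])
}

# evaluate code under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a positive finite scalar", name), call. = FALSE)
  }
  invisible(x)
}
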