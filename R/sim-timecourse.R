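#' Simulate a meiotic stage timecourse
#'
#' Per day and line, the total live-cell count follows the growth curve
#' (default: ~8-fold rise over the first seven days, then plateau). Each
#' meiotic stage contributes zero cells before its onset day and Poisson
#' counts with a linearly rising mean afterwards; remaining cells are
#' reported as stage `"other"`.
#'
#' @param true_onsets Named integer vector stage -> onset day; defaults to
#'   leptotene 6, zygotene 9, pachytene 12.
#' @param growth_curve Function day -> expected total cells, or `NULL` for
#'   the default `n0 * 8^(min(day, 7)/7)`.
#' @param n_days Number of days (days are `1..n_days`; 0 gives an empty
#'   table).
#' @param n_lines Number of replicate cell lines.
#' @param stage_rate Poisson mean of a stage's count on its onset day; the
#'   mean rises by `stage_rate` per subsequent day.
#' @param n0 Starting total cell count for the default growth curve.
#' @param seed Integer seed.
#' @return data.frame with columns `day`, `line`, `stage`, `count`.
#' @export
#' @examples
#' tc <- simulate_timecourse(seed = 1)
#' detect_onset(tc, "zygotene")
simulate_timecourse <- function(true_onsets = c(leptotene = 6, zygotene = 9,
                                                pachytene = 12),
                                growth_curve = NULL, n_days = 15L,
                                n_lines = 3L, stage_rate = 5,
                                n0 = 1000, seed = 1L) {
  check_count(n_days, "n_days")
  check_count(n_lines, "n_lines")
  check_pos(stage_rate, "stage_rate")
  if (is.null(names(true_onsets)) || anyDuplicated(names(true_onsets)))
    ms_stop("`true_onsets` must be uniquely named by stage")
  if (is.null(growth_curve))
    growth_curve <- function(day) n0 * 8^(pmin(day, 7) / 7)
  if (n_days == 0L)
    return(data.frame(day = integer(0), line = character(0),
                      stage = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  days <- seq_len(n_days)
  stages <- names(true_onsets)
  withr::with_seed(as.integer(seed) + OP_OFFSET[["timecourse"]], {
    rows <- list()
    for (li in seq_len(n_lines)) {
      line <- sprintf("line%d", li)
      for (d in days) {
        total <- rpois(1, growth_curve(d))
        stage_counts <- vapply(stages, function(s) {
          onset <- true_onsets[[s]]
          if (d < onset) 0L
          else as.integer(rpois(1, stage_rate * (d - onset + 1)))
        }, integer(1))
        other <- max(0L, total - sum(stage_counts))
        rows[[length(rows) + 1L]] <-
          data.frame(day = d, line = line,
                     stage = c(stages, "other"),
                     count = c(stage_counts, other),
                     stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
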