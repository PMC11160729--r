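# internal helpers shared across modules

ms_stop <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

ms_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# One RNG stream per operation: seed + fixed offset, so adding an operation
# never perturbs the draws of another. Offsets are small; keep seed < 2^31.
OP_OFFSET <- c(
  states      = 101L,
  counts      = 102L,
  integration = 202L,
  capture     = 303L,
  wells       = 404L,
  timecourse  = 505L,
  whitelist   = 606L,
  sort        = 707L
)

with_op_seed <- function(seed, op, code) {
  stopifnot(op %in% names(OP_OFFSET))
  withr::with_seed(as.integer(seed) + OP_OFFSET[[op]], code)
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    ms_stop("invalid `%s`: must be a probability in [0, 1]", field)
  invisible(x)
}

check_pos <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    ms_stop("invalid `%s`: must be strictly positive", field)
  invisible(x)
}

check_count <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x))
    ms_stop("invalid `%s`: must be a non-negative integer", field)
  invisible(as.integer(x))
}

hamming <- function(a, b) {
  # vectorized over b; a is a single string, all same nchar
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  vapply(strsplit(b, "", fixed = TRUE),
         function(bv) sum(av != bv), integer(1))
}
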