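# Internal helpers: classed conditions and seeded RNG scoping.

pk_error <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "potkit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_alphabet  <- function(msg) pk_error("potkit_alphabet_error", msg)
abort_frame     <- function(msg) pk_error("potkit_frame_error", msg)
abort_lookup    <- function(msg) pk_error("potkit_lookup_error", msg)
abort_design    <- function(msg) pk_error("potkit_design_error", msg)
abort_annotation<- function(msg) pk_error("potkit_annotation_error", msg)
abort_amplify   <- function(msg) pk_error("potkit_amplification_error", msg)
abort_integrate <- function(msg) pk_error("potkit_integration_error", msg)
abort_verify    <- function(msg) pk_error("potkit_verification_error", msg)
abort_recode    <- function(msg) pk_error("potkit_recoding_error", msg)
abort_constraint<- function(msg) pk_error("potkit_constraint_error", msg)
abort_bounds    <- function(msg) pk_error("potkit_bounds_error", msg)
abort_data      <- function(msg) pk_error("potkit_data_error", msg)
abort_usage     <- function(msg) pk_error("potkit_usage_error", msg)

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the RNG untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

# number of (possibly overlapping) exact occurrences of `pat` in `x`
count_matches <- function(pat, x) {
  if (nchar(pat) == 0L) return(0L)
  n <- 0L
  from <- 1L
  repeat {
    hit <- regexpr(pat, substr(x, from, nchar(x)), fixed = TRUE)
    if (hit == -1L) break
    n <- n + 1L
    from <- from + hit  # advance one past the match start: counts overlaps
  }
  n
}

# first match position (1-based) of `pat` in `x`, or 0 if absent
match_pos <- function(pat, x) {
  p <- regexpr(pat, x, fixed = TRUE)
  if (p == -1L) 0L else as.integer(p)
}

# stable row-major order helper for (row, col) coordinate matrices
order_rowmajor <- function(coords) {
  order(coords[, 1L], coords[, 2L])
}
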