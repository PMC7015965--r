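# Internal helpers: classed error conditions and seed discipline.

# Fixed Mersenne prime for universal hashing; 2^31 - 1 keeps every
# intermediate product below 2^53 so all modular arithmetic is exact in
# doubles (see hash_items()).
.MM_PRIME <- 2147483647

mm_stop <- function(class, msg) {
  stop(errorCondition(msg, class = c(paste0("mstmap_", class), "mstmap_error")))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min)
    mm_stop("invalid_parameter", sprintf("'%s' must be a single integer >= %d", name, min))
  as.integer(x)
}

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed %% 2147483647))
  code
}

#' Derive a phase-specific seed from a master seed
#'
#' All randomness in a pipeline run flows from one master seed; each phase
#' (hashing, coarsest-level placement, prolongation jitter, ...) draws from
#' a seed derived deterministically from the master seed and a short tag,
#' so phases stay decoupled and reruns are bit-exact.
#'
#' @param seed master integer seed.
#' @param tag short character tag naming the consumer.
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% 2147483647
  s <- (abs(seed) %% 2147483647)
  ((s * 48271 + h * 16807 + 12345) %% 2147483646) + 1
}

# Validate and normalize an item set: non-negative integer indices,
# duplicates removed, sorted.
as_item_set <- function(items, allow_empty = FALSE) {
  if (is.null(items) || length(items) == 0L) {
    if (allow_empty) return(integer(0))
    mm_stop("empty_input", "item set is empty")
  }
  if (!is.numeric(items) || anyNA(items) || any(items < 0) || any(items != floor(items)))
    mm_stop("invalid_parameter", "items must be non-negative integers")
  sort(unique(as.numeric(items)))
}
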