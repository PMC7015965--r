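#' MinHash hash family
#'
#' Creates `d` independent hash functions, each an affine map
#' `(a * y + b) mod P` with `P = 2^31 - 1` (a Mersenne prime) and
#' `(a, b)` drawn from a seeded RNG.  Item indices are first scrambled by
#' a seeded 4-byte simple-tabulation hash shared by the family: affine
#' maps alone are 2-universal but not min-wise independent enough (on
#' structured inputs such as runs of consecutive indices their minima
#' are correlated and the Jaccard estimate is biased), while tabulation
#' hashing restores the concentration the estimator needs.  The same
#' `(d, seed)` always yields the identical family, so signatures
#' computed anywhere from the same family are comparable.
#'
#' @param d number of hash functions (signature length).
#' @param seed integer RNG seed.
#' @return an object of class `"mh_family"`.
#' @examples
#' fam <- hash_family(64, seed = 1)
#' sig <- minhash_signature(c(0, 5, 9), fam)
#' @export
hash_family <- function(d, seed = 1L) {
  d <- check_count(d, "d")
  p <- .MM_PRIME
  pars <- with_seed(seed, list(
    a = sample.int(p - 1L, d, replace = TRUE),
    b = sample.int(p, d, replace = TRUE) - 1,
    tab = matrix(sample.int(p, 4L * 256L, replace = TRUE) - 1L, nrow = 256L)
  ))
  a <- as.numeric(pars$a)
  structure(list(
    d = d, seed = as.integer(seed), prime = p,
    a = a, b = as.numeric(pars$b), tab = pars$tab,
    # split multiplier for exact double-precision modular products
    a_hi = a %/% 65536, a_lo = a %% 65536
  ), class = "mh_family")
}

# Seeded simple tabulation hash of item indices: fold to 32 bits, split
# into 4 bytes, XOR one random table entry per byte.  Output < 2^31.
mix_items <- function(family, items) {
  x <- items %% 4294967291       # largest prime < 2^32
  b1 <- x %% 256
  b2 <- (x %/% 256) %% 256
  b3 <- (x %/% 65536) %% 256
  b4 <- x %/% 16777216
  t <- family$tab
  bitwXor(bitwXor(t[b1 + 1L, 1L], t[b2 + 1L, 2L]),
          bitwXor(t[b3 + 1L, 3L], t[b4 + 1L, 4L]))
}

# Hash all items under all d functions: returns a d x m matrix.
# Exactness: mixed items are < 2^31; a_hi < 2^15, a_lo < 2^16, so every
# product stays below 2^48 < 2^53.
hash_items <- function(family, items) {
  p <- family$prime
  xm <- mix_items(family, items) %% p
  xs <- (xm * 65536) %% p
  (outer(family$a_hi, xs) %% p + outer(family$a_lo, xm) + family$b) %% p
}

#' MinHash signature of an item set
#'
#' Component `i` is the minimum of hash function `i` over the items of the
#' set.  The probability that two signatures agree in one component equals
#' the Jaccard similarity of the underlying sets.
#'
#' @param items set of non-negative integer feature indices.
#' @param family a [hash_family()].
#' @return an object of class `"mh_signature"` with fields `values`
#'   (length `d`), `flavor = "plain"`, `d`, `seed`.
#' @export
minhash_signature <- function(items, family) {
  if (!inherits(family, "mh_family"))
    mm_stop("invalid_parameter", "'family' must be a hash_family()")
  items <- as_item_set(items)
  h <- hash_items(family, items)
  v <- h[cbind(seq_len(family$d), max.col(-h, ties.method = "first"))]
  structure(list(values = v, flavor = "plain", d = family$d, seed = family$seed),
            class = "mh_signature")
}

#' MinHash signatures for a list of item sets
#'
#' Batch form of [minhash_signature()]: one column per record.
#'
#' @param sets list of item sets.
#' @param family a [hash_family()].
#' @return an object of class `"mh_signatures"`: a `d x n` value matrix
#'   plus `flavor`, `d`, `seed`.
#' @export
minhash_signatures <- function(sets, family) {
  vals <- vapply(sets, function(s) minhash_signature(s, family)$values,
                 numeric(family$d))
  structure(list(values = matrix(vals, nrow = family$d),
                 flavor = "plain", d = family$d, seed = family$seed),
            class = "mh_signatures")
}

#' Estimate Jaccard similarity from two signatures
#'
#' The fraction of equal components; an unbiased estimator of the Jaccard
#' similarity (plain flavor) or generalized Jaccard similarity (weighted
#' flavor).  Signatures are comparable only if they share flavor, length
#' `d` and seed lineage; anything else is an error, never a silent zero.
#'
#' @param a,b signatures from the same family.
#' @return estimated similarity in `[0, 1]`.
#' @export
estimate_similarity <- function(a, b) {
  if (!inherits(a, "mh_signature") || !inherits(b, "mh_signature"))
    mm_stop("invalid_parameter", "arguments must be signatures")
  if (a$flavor != b$flavor || a$d != b$d || a$seed != b$seed)
    mm_stop("incompatible_signature",
            "signatures differ in flavor, d or seed lineage")
  mean(a$values == b$values)
}

#' @rdname estimate_similarity
#' @export
estimate_distance <- function(a, b) 1 - estimate_similarity(a, b)

#' Exact Jaccard index of two item sets
#'
#' `|A intersect B| / |A union B|`.  Serves as the exact oracle against
#' which MinHash estimates are judged.  Both sets empty is defined as 1
#' (identical sets) by convention.
#'
#' @param a,b item sets (vectors of non-negative integer indices).
#' @return Jaccard similarity in `[0, 1]`.
#' @export
jaccard_exact <- function(a, b) {
  a <- as_item_set(a, allow_empty = TRUE)
  b <- as_item_set(b, allow_empty = TRUE)
  if (length(a) == 0L && length(b) == 0L) return(1)
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

#' Generalized Jaccard similarity of two non-negative vectors
#'
#' `sum(min(v, w)) / sum(max(v, w))`; the quantity estimated by weighted
#' MinHash.
#'
#' @param v,w non-negative numeric vectors of equal length.
#' @return similarity in `[0, 1]`.
#' @export
generalized_jaccard <- function(v, w) {
  if (length(v) != length(w))
    mm_stop("inconsistent_input", "vectors differ in length")
  if (any(v < 0) || any(w < 0))
    mm_stop("invalid_parameter", "weights must be non-negative")
  den <- sum(pmax(v, w))
  if (den == 0) return(1)
  sum(pmin(v, w)) / den
}

#' Binarize a numeric vector by its mean
#'
#' Returns the 0-based indices of entries strictly greater than the vector
#' mean -- the rule used to turn grey-level images into item sets.  A
#' constant vector yields an empty set; callers that go on to sketch the
#' result must handle that case.
#'
#' @param x numeric vector.
#' @return item set of 0-based indices.
#' @export
binarize_by_mean <- function(x) {
  if (length(x) < 1L) mm_stop("empty_input", "empty vector")
  which(x > mean(x)) - 1L
}

#' Item set from a token sequence
#'
#' Maps distinct tokens to vocabulary indices; occurrence, not count.
#'
#' @param tokens character vector of tokens.
#' @param vocabulary named integer vector or list mapping token to 0-based
#'   index.
#' @return item set of vocabulary indices.
#' @export
set_from_tokens <- function(tokens, vocabulary) {
  if (length(tokens) == 0L) return(integer(0))
  toks <- unique(as.character(tokens))
  miss <- setdiff(toks, names(vocabulary))
  if (length(miss) > 0L)
    mm_stop("unknown_token",
            paste0("tokens not in vocabulary: ", paste(miss, collapse = ", ")))
  sort(unname(unlist(vocabulary[toks])))
}

#' Write / read signatures as TSV
#'
#' One record per line (`id` followed by the `d` component values), with a
#' one-line `#` header recording `d`, `seed` and `flavor` so lineage
#' survives the round trip.
#'
#' @param sigs an `"mh_signatures"` batch.
#' @param path output file.
#' @param ids record ids; default 0-based column numbers.
#' @return `path` invisibly; `read_signatures()` returns a list with
#'   `ids` and the `"mh_signatures"` batch.
#' @export
write_signatures <- function(sigs, path, ids = NULL) {
  if (!inherits(sigs, "mh_signatures"))
    mm_stop("invalid_parameter", "'sigs' must be an mh_signatures batch")
  n <- ncol(sigs$values)
  if (is.null(ids)) ids <- seq_len(n) - 1L
  header <- sprintf("# d=%d seed=%d flavor=%s", sigs$d, sigs$seed, sigs$flavor)
  body <- vapply(seq_len(n), function(j)
    paste(c(format(ids[j]), sprintf("%.0f", sigs$values[, j])), collapse = "\t"),
    character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_signatures
#' @export
read_signatures <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1]
  m <- regmatches(hdr, regexec("# d=(\\d+) seed=(-?\\d+) flavor=(\\w+)", hdr))[[1]]
  if (length(m) != 4L) mm_stop("parse", "missing signature header")
  d <- as.integer(m[2]); seed <- as.integer(m[3]); flavor <- m[4]
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  ids <- as.numeric(vapply(parts, `[`, character(1), 1L))
  vals <- vapply(parts, function(p) as.numeric(p[-1L]), numeric(d))
  list(ids = ids,
       signatures = structure(list(values = matrix(vals, nrow = d),
                                   flavor = flavor, d = d, seed = seed),
                              class = "mh_signatures"))
}

#' Exact pairwise Jaccard distance matrix
#'
#' Dense `n x n` matrix of exact Jaccard distances between item sets,
#' computed through a sparse incidence matrix.  Intended for oracles and
#' evaluation at moderate `n`, not for the indexing path.
#'
#' @param sets list of item sets.
#' @return numeric matrix of distances with zero diagonal.
#' @export
jaccard_distance_matrix <- function(sets) {
  n <- length(sets)
  if (n < 1L) mm_stop("empty_input", "no sets")
  sets <- lapply(sets, as_item_set)
  sizes <- lengths(sets)
  ii <- rep.int(seq_len(n), sizes)
  jj <- unlist(sets) + 1
  x <- Matrix::sparseMatrix(i = ii, j = jj, x = 1)
  inter <- as.matrix(Matrix::tcrossprod(x))
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0  # two empty sets: identical by convention
  diag(d) <- 0
  d
}
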