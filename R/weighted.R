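#' Weighted MinHash family (consistent weighted sampling)
#'
#' Sampling parameters for Ioffe-style consistent weighted sampling: for
#' each of the `d` samples and each of the `dim` feature dimensions, draws
#' `r ~ Gamma(2, 1)`, `c ~ Gamma(2, 1)` and `beta ~ Uniform(0, 1)`.  A
#' sample of a non-negative vector is the pair `(k, t_k)` where `k` is the
#' dimension attaining the minimal transformed value and `t_k` its
#' discretized log-weight level; two vectors collide in one sample with
#' probability equal to their generalized Jaccard similarity.
#'
#' @param d number of samples (signature length).
#' @param dim dimensionality of the vectors to be sketched (at most 2^20).
#' @param seed integer RNG seed.
#' @return an object of class `"wmh_family"`.
#' @export
weighted_hash_family <- function(d, dim, seed = 1L) {
  d <- check_count(d, "d")
  dim <- check_count(dim, "dim")
  if (dim > 2^20)
    mm_stop("invalid_parameter", "dim must be <= 2^20 for exact component packing")
  pars <- with_seed(seed, list(
    r    = matrix(stats::rgamma(d * dim, shape = 2, rate = 1), nrow = d),
    lnc  = matrix(log(stats::rgamma(d * dim, shape = 2, rate = 1)), nrow = d),
    beta = matrix(stats::runif(d * dim), nrow = d)
  ))
  structure(list(d = d, dim = dim, seed = as.integer(seed),
                 r = pars$r, lnc = pars$lnc, beta = pars$beta),
            class = "wmh_family")
}

# Pack a (dimension index, level) pair into one exactly-representable
# double: k * 2^32 + t + 2^31, with k < 2^20 and |t| < 2^31.  Equality of
# packed values is equivalent to equality of pairs, so the plain-flavor
# comparison and indexing machinery applies unchanged.
pack_pair <- function(k, t) k * 4294967296 + (t + 2147483648)

#' Weighted MinHash signature of a non-negative vector
#'
#' @param v non-negative numeric vector of length `family$dim` with at
#'   least one positive entry.
#' @param family a [weighted_hash_family()].
#' @return an object of class `"mh_signature"` with `flavor = "weighted"`;
#'   `values` holds the packed `(k, t)` component pairs.
#' @export
weighted_minhash_signature <- function(v, family) {
  if (!inherits(family, "wmh_family"))
    mm_stop("invalid_parameter", "'family' must be a weighted_hash_family()")
  if (length(v) != family$dim)
    mm_stop("inconsistent_input", "vector length does not match family dim")
  if (anyNA(v) || any(v < 0))
    mm_stop("invalid_parameter", "weights must be non-negative")
  nz <- which(v > 0)
  if (length(nz) == 0L) mm_stop("empty_input", "all-zero weight vector")
  d <- family$d
  lv <- matrix(log(v[nz]), nrow = d, ncol = length(nz), byrow = TRUE)
  r <- family$r[, nz, drop = FALSE]
  beta <- family$beta[, nz, drop = FALSE]
  t_ <- floor(lv / r + beta)
  # ln a = ln c - r * (t - beta) - r ; the argmin dimension is the sample
  lna <- family$lnc[, nz, drop = FALSE] - r * (t_ - beta) - r
  idx <- max.col(-lna, ties.method = "first")
  sel <- cbind(seq_len(d), idx)
  tt <- t_[sel]
  if (any(abs(tt) >= 2147483647))
    mm_stop("invalid_parameter", "weight magnitudes out of sketchable range")
  structure(list(values = pack_pair(nz[idx] - 1, tt),
                 flavor = "weighted", d = d, seed = family$seed),
            class = "mh_signature")
}

#' @rdname weighted_minhash_signature
#' @param vectors numeric matrix, one record per row.
#' @return `weighted_minhash_signatures()`: an `"mh_signatures"` batch,
#'   one column per row of `vectors`.
#' @export
weighted_minhash_signatures <- function(vectors, family) {
  vals <- vapply(seq_len(nrow(vectors)),
                 function(i) weighted_minhash_signature(vectors[i, ], family)$values,
                 numeric(family$d))
  structure(list(values = matrix(vals, nrow = family$d),
                 flavor = "weighted", d = family$d, seed = family$seed),
            class = "mh_signatures")
}
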