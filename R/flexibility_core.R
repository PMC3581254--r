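#' Weighted contact number per residue
#'
#' The weighted contact number (WCN) of residue \eqn{i} is the sum of
#' inverse-squared distances to every other residue,
#' \deqn{D_i = \sum_{j \ne i} 1 / r_{ij}^2,}
#' with \eqn{r_{ij}} the Euclidean distance between the C\eqn{\alpha} atoms of
#' residues \eqn{i} and \eqn{j}. High WCN marks densely packed (rigid)
#' positions; its inverse behaves like a B-factor (high = flexible).
#'
#' @param coords Numeric N x 3 matrix of C-alpha coordinates in Angstrom,
#'   N >= 2.
#' @return Numeric vector of length N with the WCN of each residue
#'   (Angstrom^-2), strictly positive.
#' @examples
#' compute_wcn(rbind(c(0, 0, 0), c(2, 0, 0)))  # both 1/4
#' @export
compute_wcn <- function(coords) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("'coords' must be an N x 3 matrix")
  n <- nrow(coords)
  if (n < 2L) stop("WCN needs at least 2 residues")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  d2 <- as.matrix(stats::dist(coords))^2
  if (any(d2[upper.tri(d2)] == 0)) {
    stop("coincident C-alpha coordinates: pairwise distances must be > 0")
  }
  diag(d2) <- Inf
  unname(rowSums(1 / d2))
}

#' Sequence-neighbour flexibility profile (SEQ)
#'
#' Averages inverse WCN over a symmetric sequence window: residue \eqn{i} and
#' its \eqn{n} flanking residues on each side. Window positions falling
#' outside the chain are ignored. Two edge policies are provided: `"mean"`
#' divides by the number of terms actually included (a true average, the
#' default), `"fixed_denominator"` always divides by \eqn{2n + 1} so that
#' truncated windows at the termini are deflated.
#'
#' @param inv_wcn Numeric vector of inverse WCN values (Angstrom^2).
#' @param n Window half-width, integer >= 1.
#' @param edge Edge policy at the chain termini, see Details.
#' @return Numeric vector of SEQ values, same length as `inv_wcn`.
#' @examples
#' seq_profile(c(2, 4, 6), n = 1)  # c(3, 4, 5)
#' @export
seq_profile <- function(inv_wcn, n, edge = c("mean", "fixed_denominator")) {
  edge <- match.arg(edge)
  if (length(n) != 1L || !is.finite(n) || n < 1) stop("'n' must be >= 1")
  n <- as.integer(n)
  N <- length(inv_wcn)
  cs <- cumsum(c(0, inv_wcn))
  i <- seq_len(N)
  lo <- pmax(1L, i - n)
  hi <- pmin(N, i + n)
  sums <- cs[hi + 1L] - cs[lo]
  denom <- if (edge == "mean") hi - lo + 1L else rep(2L * n + 1L, N)
  unname(sums / denom)
}

#' Structure-neighbour flexibility profile (STR)
#'
#' Averages inverse WCN over the spatial neighbourhood of each residue: the
#' residue itself plus every residue whose C-alpha lies strictly closer than
#' `cutoff`. Distances exactly equal to the cutoff are excluded.
#'
#' @param coords Numeric N x 3 matrix of C-alpha coordinates (Angstrom).
#' @param inv_wcn Numeric vector of inverse WCN values, length N.
#' @param cutoff Distance cutoff in Angstrom, > 0.
#' @return Numeric vector of STR values, length N.
#' @examples
#' xyz <- cbind(c(0, 2, 10), 0, 0)
#' str_profile(xyz, c(1, 3, 5), cutoff = 3)  # c(2, 2, 5)
#' @export
str_profile <- function(coords, inv_wcn, cutoff) {
  coords <- as.matrix(coords)
  if (nrow(coords) != length(inv_wcn)) {
    stop("'coords' and 'inv_wcn' disagree on the number of residues")
  }
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff <= 0) {
    stop("'cutoff' must be a positive distance")
  }
  inside <- as.matrix(stats::dist(coords)) < cutoff  # diagonal 0 < cutoff: self in
  unname(as.vector(inside %*% inv_wcn) / rowSums(inside))
}

#' Per-protein z-normalization
#'
#' Standardizes a per-residue profile within one protein:
#' \eqn{z_i = (x_i - \bar x) / \sigma_x}, using the population standard
#' deviation (divide by N), so the output has mean 0 and population SD exactly
#' 1. SEQ, STR and B-factor profiles are all normalized this way before any
#' comparison across proteins.
#'
#' @param values Numeric vector, length >= 2, not constant.
#' @return Numeric vector of z-scores.
#' @examples
#' znormalize(c(1, 2, 3))
#' @export
znormalize <- function(values) {
  N <- length(values)
  if (N < 2L) stop("z-normalization needs at least 2 values")
  if (!all(is.finite(values))) stop("non-finite values")
  mu <- mean(values)
  sigma <- sqrt(sum((values - mu)^2) / N)
  if (sigma == 0) stop("constant profile: standard deviation is zero")
  unname((values - mu) / sigma)
}

#' Flexibility profile of a chain
#'
#' Runs the full per-chain pipeline: weighted contact number from C-alpha
#' coordinates, its inverse, the SEQ and STR context profiles, and per-protein
#' z-scores of SEQ, STR and the crystallographic B-factor.
#'
#' @param chain A [chain_structure] object (see [read_chain()] /
#'   [make_chain()]).
#' @param n SEQ window half-width (default 1, i.e. the nearest two sequence
#'   neighbours).
#' @param cutoff STR distance cutoff in Angstrom (default 3).
#' @param edge Edge policy for SEQ windows at the termini, see
#'   [seq_profile()].
#' @return A `flexibility_profile`: a data frame with one row per residue and
#'   columns `res_seq`, `icode`, `aa`, `is_catalytic`, `wcn`, `inv_wcn`,
#'   `seq`, `str`, `z_seq`, `z_str`, `b_factor`, `z_b`, carrying the `n` and
#'   `cutoff` used as attributes.
#' @examples
#' ch <- make_chain(synthetic_spec(n_residues = 30, seed = 1))
#' pr <- chain_profile(ch)
#' round(mean(pr$z_seq), 12)  # 0 by construction
#' @export
chain_profile <- function(chain, n = 1, cutoff = 3,
                          edge = c("mean", "fixed_denominator")) {
  stopifnot(inherits(chain, "chain_structure"))
  edge <- match.arg(edge)
  coords <- as.matrix(chain[, c("x", "y", "z")])
  wcn <- compute_wcn(coords)
  inv_wcn <- 1 / wcn
  seq_ <- seq_profile(inv_wcn, n = n, edge = edge)
  str_ <- str_profile(coords, inv_wcn, cutoff = cutoff)
  out <- data.frame(
    res_seq = chain$res_seq,
    icode = chain$icode,
    aa = chain$aa,
    is_catalytic = chain$is_catalytic,
    wcn = wcn,
    inv_wcn = inv_wcn,
    seq = seq_,
    str = str_,
    z_seq = znormalize(seq_),
    z_str = znormalize(str_),
    b_factor = chain$b_factor,
    z_b = znormalize(chain$b_factor),
    stringsAsFactors = FALSE
  )
  attr(out, "pdb_id") <- attr(chain, "pdb_id")
  attr(out, "chain_id") <- attr(chain, "chain_id")
  attr(out, "n") <- n
  attr(out, "cutoff") <- cutoff
  attr(out, "edge") <- edge
  class(out) <- c("flexibility_profile", "data.frame")
  out
}
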