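#' Draining-vein leakage model
#'
#' Ascending veins carry blood-oxygenation changes from deep cortical depths
#' toward the pial surface, so the observed gradient-echo BOLD profile at a
#' given depth contains contributions from all deeper depths:
#' observed = W local, with W lower-triangular (depths ordered deep to
#' superficial, index 1 = white-matter boundary) and unit diagonal.
#'
#' The default parameterisation is a cumulative drain: a fraction `lambda` of
#' each depth's local signal is added to every more superficial depth
#' (`W[i, j] = lambda` for j deeper than i). Any full lower-triangular matrix
#' with unit diagonal can be supplied instead, e.g. read from a TSV via
#' [read_leakage_tsv()].
#'
#' @param n_depths number of depth levels
#' @param lambda drained fraction per deeper level (default 0.3)
#' @param W optional explicit weight matrix (overrides `lambda`)
#' @return a `leakage_model` list: `W`, `n_depths`, `provenance`
#' @export
leakage_model <- function(n_depths, lambda = 0.3, W = NULL) {
  if (is.null(W)) {
    W <- diag(n_depths)
    W[lower.tri(W)] <- lambda
    prov <- sprintf("cumulative-drain (lambda = %g)", lambda)
  } else {
    W <- as.matrix(W)
    prov <- "custom"
  }
  if (nrow(W) != n_depths || ncol(W) != n_depths)
    stop("leakage matrix dimension mismatch")
  if (any(abs(diag(W) - 1) > 1e-12))
    stop("leakage matrix must have unit diagonal")
  if (any(W[upper.tri(W)] != 0))
    stop("leakage matrix must be lower-triangular (deep-to-superficial order)")
  if (any(W < 0)) stop("leakage weights must be non-negative")
  structure(list(W = W, n_depths = n_depths, provenance = prov),
            class = "leakage_model")
}

#' @export
print.leakage_model <- function(x, ...) {
  cat(sprintf("leakage_model: %d depths, %s\n", x$n_depths, x$provenance))
  invisible(x)
}

#' Apply the draining forward model
#'
#' observed_i = local_i + sum over deeper j of W[i, j] local_j. Profiles are
#' ordered deep (index 1, white matter) to superficial (index n, pial).
#'
#' @param local_profile numeric vector (or matrix depths x profiles)
#' @param leakage a [leakage_model()]
#' @return observed profile(s), same shape
#' @export
forward_drain <- function(local_profile, leakage) {
  v <- is.null(dim(local_profile))
  X <- if (v) matrix(local_profile, ncol = 1) else as.matrix(local_profile)
  if (nrow(X) != leakage$n_depths)
    stop("profile length does not match leakage model depths")
  out <- leakage$W %*% X
  if (v) drop(out) else out
}

#' Invert the draining model (spatial deconvolution)
#'
#' Recovers the local laminar profile from the observed one by sequential
#' forward substitution from the deepest level upward: at each depth the
#' estimated contribution of all deeper depths is subtracted. Algebraically
#' identical to solving W x = observed.
#'
#' @param observed_profile numeric vector (or matrix depths x profiles),
#'   deep-to-superficial order
#' @param leakage a [leakage_model()]
#' @return local profile(s), same shape
#' @export
deconvolve_drain <- function(observed_profile, leakage) {
  v <- is.null(dim(observed_profile))
  X <- if (v) matrix(observed_profile, ncol = 1) else
    as.matrix(observed_profile)
  if (nrow(X) != leakage$n_depths)
    stop("profile length does not match leakage model depths")
  W <- leakage$W
  if (any(abs(diag(W) - 1) > 1e-12))
    stop("leakage matrix must have unit diagonal")
  n <- nrow(X)
  out <- X
  for (i in seq_len(n)) {
    if (i > 1)
      out[i, ] <- X[i, ] - W[i, seq_len(i - 1), drop = FALSE] %*%
        out[seq_len(i - 1), , drop = FALSE]
  }
  if (v) drop(out) else out
}

#' Read / write leakage matrices as TSV
#' @param path file path
#' @return for the reader, a [leakage_model()]
#' @export
read_leakage_tsv <- function(path) {
  W <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(W) <- NULL
  leakage_model(nrow(W), W = W)
}

#' @rdname read_leakage_tsv
#' @param leakage a [leakage_model()]
#' @export
write_leakage_tsv <- function(leakage, path) {
  utils::write.table(leakage$W, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Convert a profile between depth conventions
#'
#' Internal computations order depths deep (white matter) to superficial
#' (pial); display convention is depth fraction from the pial surface
#' (0% = pial). This simply reverses the depth axis.
#'
#' @param profile vector or matrix (depths in rows)
#' @return reversed profile
#' @export
flip_depth_convention <- function(profile) {
  if (is.null(dim(profile))) rev(profile) else
    profile[rev(seq_len(nrow(profile))), , drop = FALSE]
}
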