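#' Leading left eigenvector of a swipe-pattern matrix
#'
#' The first left eigenvector of the adjacency matrix ranks zones by their
#' popularity as swipe destinations: entries combine aggregated arrival
#' weights with the prominence of the vertices the arrivals depart from.
#' Perturbed matrices `A - diag(p)` can have negative diagonal entries, so
#' the computation shifts by `c = max(0, -min(diag))`, making the matrix
#' non-negative (off-diagonal entries are non-negative by construction, and
#' strictly positive once the baseline graph is added). The shifted matrix
#' then has a real, simple Perron eigenvalue with a positive eigenvector;
#' eigenvectors are invariant under the shift and the eigenvalue is shifted
#' back before returning.
#'
#' @param M square numeric matrix with non-negative off-diagonal entries.
#' @return An `eigen_result`: list with `value` (leading eigenvalue of `M`)
#'   and `vector` (left eigenvector, unit Euclidean norm, oriented so its
#'   dominant entry is positive).
#' @export
leading_left_eigenvector <- function(M) {
  if (inherits(M, "adjacency_matrix")) M <- M$A
  if (!is.matrix(M) || nrow(M) != ncol(M) || any(!is.finite(M)))
    stop("M must be a square matrix with finite entries")
  offdiag <- M; diag(offdiag) <- 0
  if (any(offdiag < 0)) stop("off-diagonal entries must be non-negative")
  shift <- max(0, -min(diag(M)))
  e <- eigen(t(M + diag(shift, nrow(M))))
  k <- which.max(Re(e$values))
  if (abs(Im(e$values[k])) > 1e-10)
    stop("leading eigenvalue unexpectedly complex")
  v <- Re(e$vectors[, k])
  if (v[which.max(abs(v))] < 0) v <- -v
  v <- v / sqrt(sum(v^2))
  structure(list(value = Re(e$values[k]) - shift, vector = v),
            class = "eigen_result")
}

#' Do the plate vertices dominate an eigenvector?
#'
#' `TRUE` iff the four largest entries of the vector belong to the plate
#' vertices, in the strict sense: the smallest plate entry exceeds the
#' largest non-plate entry. Ties fail, which pins the degenerate
#' baseline-only network's sharing score at exactly zero.
#'
#' @param x1 an `eigen_result` or numeric vector of length 16.
#' @param zm a [zone_map()].
#' @return Logical.
#' @export
plates_dominant <- function(x1, zm) {
  if (inherits(x1, "eigen_result")) x1 <- x1$vector
  if (length(x1) != nrow(zm$zones)) stop("eigenvector length must be 16")
  psi <- plate_vertices(zm) + 1L
  min(x1[psi]) > max(x1[-psi])
}

.perturbed <- function(A, q, psi1) {
  P <- A
  P[cbind(psi1, psi1)] <- P[cbind(psi1, psi1)] - q
  P
}

.dominant_at <- function(A, q, zm, psi1) {
  plates_dominant(leading_left_eigenvector(.perturbed(A, q, psi1)), zm)
}

#' Sharing score: largest plate perturbation preserving plate dominance
#'
#' The sharing score of a session is the largest uniform diagonal
#' perturbation `q`, subtracted from the four plate vertices of the adjacency
#' matrix (`P = A - q * diag(1_psi)`), for which the plate vertices still
#' carry the four largest entries of the first left eigenvector. A large
#' enough negative perturbation always makes the plates dominant and a large
#' enough positive one always defeats them, so the score is located by
#' bisection after verifying on a coarse grid that the dominance indicator is
#' a step function of `q` (it is, for baseline-coupled networks; a
#' non-monotone pattern diverts to a dense grid scan and is flagged). Higher
#' scores reward even distribution of delivery swipes over the four plates
#' relative to all other between-zone swipe activity; off-task swipes and
#' uneven delivery both lower the score.
#'
#' @param A an `adjacency_matrix` from [normalise_with_baseline()] (or a bare
#'   16x16 matrix).
#' @param zm a [zone_map()].
#' @param tol bisection tolerance on `q` (default 1e-4).
#' @param bracket initial search interval (default `c(-1, 1)`; expanded by
#'   doubling, up to magnitude 16, if the dominance condition does not hold
#'   at the lower end or fail at the upper end).
#' @param grid_n number of points of the monotonicity verification grid.
#' @return A `sharing_score_result`: list with `score`, `variant`, `bracket`
#'   (final bisection interval: condition holds at its lower end and fails at
#'   its upper end), `degenerate`, `monotone` and `n_eval`.
#' @export
compute_sharing_score <- function(A, zm = default_zone_map(), tol = 1e-4,
                                  bracket = c(-1, 1), grid_n = 64L) {
  variant <- NA_character_
  degenerate <- FALSE
  if (inherits(A, "adjacency_matrix")) {
    variant <- A$variant
    degenerate <- A$degenerate
    A <- A$A
  }
  if (!is.numeric(tol) || tol <= 0) stop("tol must be positive")
  if (degenerate) {
    # baseline-only network: the four plate entries tie the rest exactly at
    # q = 0, dominate for any q < 0 and are dominated for q > 0
    return(structure(list(score = 0, variant = variant, bracket = c(0, 0),
                          degenerate = TRUE, monotone = TRUE, n_eval = 0L),
                     class = "sharing_score_result"))
  }
  psi1 <- plate_vertices(zm) + 1L
  n_eval <- 0L
  dom <- function(q) {
    n_eval <<- n_eval + 1L
    .dominant_at(A, q, zm, psi1)
  }

  lo <- min(bracket); hi <- max(bracket)
  while (!dom(lo) && lo > -16) lo <- lo * 2
  if (!dom(lo)) stop("plate dominance does not hold even at q = ", lo)
  while (dom(hi) && hi < 16) hi <- hi * 2
  if (dom(hi)) stop("plate dominance persists even at q = ", hi)

  qs <- seq(lo, hi, length.out = grid_n)
  ind <- vapply(qs, dom, logical(1))
  monotone <- all(diff(ind) <= 0)
  if (!monotone) {
    warning("dominance indicator non-monotone on verification grid; ",
            "falling back to dense grid scan")
    score <- sharing_score_grid(A, zm, step = tol, bracket = c(lo, hi))
    return(structure(list(score = score, variant = variant,
                          bracket = c(score - tol, score + tol),
                          degenerate = FALSE, monotone = FALSE,
                          n_eval = n_eval),
                     class = "sharing_score_result"))
  }
  lo <- qs[max(which(ind))]
  hi <- if (any(!ind)) qs[min(which(!ind))] else hi
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (dom(mid)) lo <- mid else hi <- mid
  }
  structure(list(score = (lo + hi) / 2, variant = variant,
                 bracket = c(lo, hi), degenerate = FALSE, monotone = TRUE,
                 n_eval = n_eval),
            class = "sharing_score_result")
}

#' @export
print.sharing_score_result <- function(x, ...) {
  cat("<sharing_score>", if (!is.na(x$variant)) x$variant, "score",
      format(x$score, digits = 6),
      if (x$degenerate) "(degenerate)",
      if (!x$monotone) "(non-monotone)", "\n")
  invisible(x)
}

#' Dense grid-scan reference for the sharing score
#'
#' Locates the largest perturbation preserving plate dominance by scanning a
#' grid of `q` values, using batched power iteration on the shifted
#' transposed matrices — a route independent of the dense eigendecomposition
#' used by [compute_sharing_score()], suitable as a cross-check. The whole
#' bracket is scanned at `coarse_step`, and the single coarse cell bracketing
#' the dominance boundary is rescanned at `step`, so the returned value has
#' resolution `step`.
#'
#' @param A an `adjacency_matrix` or bare 16x16 matrix.
#' @param zm a [zone_map()].
#' @param step fine grid step (default 1e-5).
#' @param bracket scan interval.
#' @param coarse_step step of the full-bracket scan (default 1e-3).
#' @return The largest grid value of `q` at which the plates dominate.
#' @export
sharing_score_grid <- function(A, zm = default_zone_map(), step = 1e-5,
                               bracket = c(-1, 1), coarse_step = 1e-3) {
  if (inherits(A, "adjacency_matrix")) A <- A$A
  psi1 <- plate_vertices(zm) + 1L
  scan <- function(qs) .dominance_scan(A, qs, psi1)
  if (step >= coarse_step) {
    qs <- seq(bracket[1], bracket[2], by = step)
    ind <- scan(qs)
    if (!any(ind)) stop("plates never dominate on the scan grid")
    return(qs[max(which(ind))])
  }
  qs <- seq(bracket[1], bracket[2], by = coarse_step)
  ind <- scan(qs)
  if (!any(ind)) stop("plates never dominate on the scan grid")
  k <- max(which(ind))
  if (k == length(qs)) return(qs[k])
  fine <- seq(qs[k], qs[k + 1], by = step)
  indf <- scan(fine)
  fine[max(which(indf))]
}

# Batched power iteration: dominance of the plate entries of the leading left
# eigenvector of A - q*diag(1_psi), for a whole vector of q at once. Each
# column is shifted by max(0, q) so the iterated matrix is non-negative
# (strictly positive off the diagonal once the baseline is present), making
# the Perron pair simple and the iteration convergent.
.dominance_scan <- function(A, qs, psi1, tol = 1e-13, maxit = 20000L) {
  n <- nrow(A)
  m <- length(qs)
  tA <- t(A)
  cmax <- pmax(0, qs)
  V <- matrix(1 / sqrt(n), n, m)
  for (it in seq_len(maxit)) {
    W <- tA %*% V
    W[psi1, ] <- W[psi1, ] - V[psi1, , drop = FALSE] *
      rep(qs, each = length(psi1))
    W <- W + V * rep(cmax, each = n)
    nrm <- sqrt(colSums(W^2))
    nrm[nrm == 0] <- 1
    W <- W / rep(nrm, each = n)
    delta <- max(abs(W - V))
    V <- W
    if (delta < tol) break
  }
  apply(V[psi1, , drop = FALSE], 2, min) >
    apply(V[-psi1, , drop = FALSE], 2, max)
}

#' Difference between indirect and direct sharing scores
#'
#' Positive values indicate reliance on the two-step, stack-then-redistribute
#' sharing strategy: inter-plate swipes raise the indirect score but not the
#' direct one. Sessions with no plate-origin swipes have identical direct and
#' indirect networks, hence a difference of exactly zero.
#'
#' @param indirect,direct `sharing_score_result`s for the same session.
#' @return Numeric: `indirect$score - direct$score`.
#' @export
sharing_score_difference <- function(indirect, direct) {
  stopifnot(inherits(indirect, "sharing_score_result"),
            inherits(direct, "sharing_score_result"))
  if (!is.na(indirect$variant) && indirect$variant != "indirect")
    stop("first argument must be an indirect-variant score")
  if (!is.na(direct$variant) && direct$variant != "direct")
    stop("second argument must be a direct-variant score")
  indirect$score - direct$score
}
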