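#' Exact first-passage probability for the sliding walker
#'
#' Closed-form (linear-solve) probability that an unbiased +/-1 lattice
#' walker starting at position 0 reaches the absorbing target at
#' `+spacing` before being lost to dissociation, when every step carries a
#' microscopic dissociation probability `q` and the wall at `-left_extent`
#' reflects. This is the associative (pure-sliding) transfer probability in
#' the saturating-trap limit, and serves as the independent oracle for the
#' stochastic walker.
#'
#' The hitting probabilities satisfy the discrete boundary-value problem
#' \deqn{u(x) = \frac{1-q}{2}\,[u(x-1) + u(x+1)]}{u(x) = (1-q)/2 (u(x-1)+u(x+1))}
#' with \eqn{u(\mathrm{spacing}) = 1}. At the reflecting wall the walker
#' survives dissociation with probability \eqn{1-q} and takes its one
#' available step inward, so \eqn{u(-L) = (1-q)\,u(-L+1)}. The tridiagonal
#' system is solved exactly.
#'
#' @param spacing Target distance in bp (>= 1).
#' @param q Per-step dissociation probability in \[0, 1).
#' @param left_extent Distance in bp from the start to the reflecting wall
#'   (>= 0; 0 places the wall at the starting position).
#' @return Probability in \[0, 1\] of reaching `+spacing`.
#' @export
#' @examples
#' first_passage_oracle(spacing = 2, q = 0.5, left_extent = 0)  # 1/7
#' first_passage_oracle(spacing = 1, q = 0)                     # 1
first_passage_oracle <- function(spacing, q, left_extent = 1L) {
  stopifnot(length(spacing) == 1, length(q) == 1, length(left_extent) == 1)
  spacing <- as.integer(spacing)
  left_extent <- as.integer(left_extent)
  if (spacing < 1) stop("spacing must be >= 1 bp")
  if (q < 0 || q >= 1) stop("q must lie in [0, 1)")
  if (left_extent < 0) stop("left_extent must be >= 0")

  # unknowns u(x) for x = -L, ..., spacing-1; u(spacing) = 1 enters the RHS
  n <- left_extent + spacing
  s <- (1 - q) / 2
  A <- diag(n)
  b <- numeric(n)
  idx <- function(x) x + left_extent + 1L  # lattice coord -> matrix row

  for (x in seq(-left_extent, spacing - 1L)) {
    i <- idx(x)
    if (x == -left_extent) {
      # reflecting wall: survive w.p. (1-q), step inward
      if (spacing - x == 1L) b[i] <- (1 - q) else A[i, idx(x + 1L)] <- -(1 - q)
    } else {
      A[i, idx(x - 1L)] <- -s
      if (x + 1L == spacing) b[i] <- s else A[i, idx(x + 1L)] <- -s
    }
  }
  u <- tryCatch(solve(A, b),
                error = function(e) stop("singular first-passage system: ",
                                         conditionMessage(e)))
  unname(min(max(u[idx(0L)], 0), 1))
}
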