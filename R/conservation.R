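# Exact rational linear algebra for conservation analysis.
#
# Stoichiometric matrices have small integer entries, so all elimination is
# done in exact rational arithmetic (integer numerators/denominators held in
# doubles, reduced by gcd after every operation).  No floating tolerance is
# involved anywhere: a conservation law holds exactly or not at all.

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

rat_reduce <- function(num, den) {
  stopifnot(all(den != 0))
  g <- mapply(gcd2, abs(num), abs(den))
  g[g == 0] <- 1
  s <- sign(den)
  list(num = num * s / g, den = abs(den) / g)
}

# Reduced row echelon form of a rational matrix (num/den), with partial
# pivoting on exact magnitude.  Returns num, den, pivot columns.
rref_rational <- function(num, den = NULL) {
  if (is.null(den)) den <- matrix(1, nrow(num), ncol(num))
  n <- nrow(num); m <- ncol(num)
  piv <- integer(0)
  row <- 1L
  for (col in seq_len(m)) {
    if (row > n) break
    cand <- which(num[row:n, col] != 0) + row - 1L
    if (!length(cand)) next
    # full magnitude pivoting within the column for stability of the exact
    # arithmetic (keeps numerators small)
    mag <- abs(num[cand, col] / den[cand, col])
    p <- cand[which.max(mag)]
    if (p != row) {
      num[c(row, p), ] <- num[c(p, row), ]; den[c(row, p), ] <- den[c(p, row), ]
    }
    # normalize pivot row to leading 1
    pn <- num[row, col]; pd <- den[row, col]
    r <- rat_reduce(num[row, ] * pd, den[row, ] * pn)
    num[row, ] <- r$num; den[row, ] <- r$den
    # eliminate all other rows
    for (i in seq_len(n)[-row]) {
      if (num[i, col] == 0) next
      fn <- num[i, col]; fd <- den[i, col]
      # row_i <- row_i - f * row_row
      nn <- num[i, ] * den[row, ] * fd - fn * num[row, ] * den[i, ]
      dd <- den[i, ] * den[row, ] * fd
      r <- rat_reduce(nn, dd)
      num[i, ] <- r$num; den[i, ] <- r$den
    }
    piv <- c(piv, col)
    row <- row + 1L
  }
  list(num = num, den = den, pivots = piv, rank = length(piv))
}

# Integer basis of the null space of an integer matrix M (null(M) = {x: Mx=0}).
null_basis_int <- function(M) {
  if (nrow(M) == 0L)
    return(diag(1, ncol(M)))
  r <- rref_rational(M, NULL)
  piv <- r$pivots
  free <- setdiff(seq_len(ncol(M)), piv)
  if (!length(free)) return(matrix(0, ncol(M), 0))
  B <- matrix(0, ncol(M), length(free))
  for (k in seq_along(free)) {
    f <- free[k]
    x_num <- numeric(ncol(M)); x_den <- rep(1, ncol(M))
    x_num[f] <- 1
    for (i in seq_along(piv)) {      # pivot rows have leading 1 at piv[i]
      x_num[piv[i]] <- -r$num[i, f]
      x_den[piv[i]] <- r$den[i, f]
    }
    l <- 1
    for (d in unique(x_den)) l <- l * d / gcd2(l, d)   # lcm of denominators
    v <- x_num * (l / x_den)
    g <- 0; for (a in v) g <- gcd2(g, a)
    if (g > 1) v <- v / g
    if (sum(v) < 0) v <- -v
    B[, k] <- v
  }
  B
}

#' Conservation laws of a reaction network
#'
#' Computes an exact integer basis of the left null space of the
#' stoichiometric matrix: every row `b` of the basis satisfies
#' `b %*% S == 0`, so `sum(b * n)` is invariant under all reactions.  The
#' elimination is carried out in exact rational arithmetic, so the result
#' involves no floating-point tolerance.
#'
#' The returned object also fixes a choice of `N - M` independent species
#' (the complement of one pivot species per law) and the affine
#' reconstruction of the full state from the independent one, with totals
#' taken from the network's initial state.
#'
#' @param net A [reaction_network()].
#' @return An object of class `conservation_basis` with elements
#'   `basis` (M x N integer matrix), `totals` (length M, concentration
#'   frame), `independent_idx`, `dependent_idx`, and `L` (the `N x (N-M)`
#'   linear part of the reconstruction map).
#' @examples
#' net <- make_paper_model("F1")
#' find_conservation_laws(net)
#' @export
find_conservation_laws <- function(net) {
  S <- stoich_matrix(net)
  N <- nrow(S)
  B <- t(null_basis_int(t(S)))            # M x N, rows are conservation laws
  M <- nrow(B)
  if (M > 0L) {
    rr <- rref_rational(B, NULL)
    dep <- rr$pivots                      # one dependent species per law
    # use the rref'd (still exact) basis so that basis[, dep] is the identity
    Bn <- rr$num / rr$den
  } else {
    dep <- integer(0)
    Bn <- B
  }
  ind <- setdiff(seq_len(N), dep)
  L <- matrix(0, N, length(ind))
  L[cbind(ind, seq_along(ind))] <- 1
  if (M > 0L) L[dep, ] <- -Bn[, ind, drop = FALSE]
  x0 <- initial_state(net, "concentration")
  totals <- if (M > 0L) as.numeric(B %*% x0) else numeric(0)
  # constant part of the reconstruction: solve basis %*% x = totals for the
  # dependent species with independent species at zero (exact row reduction
  # of the augmented system)
  offset <- numeric(N)
  if (M > 0L) {
    rr2 <- rref_rational(cbind(B, totals), NULL)
    offset[dep] <- (rr2$num / rr2$den)[seq_len(M), N + 1L]
  }
  rownames(B) <- if (M > 0L) paste0("cl", seq_len(M)) else NULL
  colnames(B) <- net$species$id
  structure(list(basis = B, totals = totals, independent_idx = ind,
                 dependent_idx = dep, L = L, offset = offset,
                 species = net$species$id),
            class = "conservation_basis")
}

#' @export
print.conservation_basis <- function(x, ...) {
  M <- nrow(x$basis)
  cat(sprintf("%d conservation law(s); %d independent species\n",
              M, length(x$independent_idx)))
  for (i in seq_len(M)) {
    b <- x$basis[i, ]
    terms <- paste(ifelse(b[b != 0] == 1, x$species[b != 0],
                          paste0(b[b != 0], " ", x$species[b != 0])),
                   collapse = " + ")
    cat(sprintf("  %s = %.6g\n", terms, x$totals[i]))
  }
  invisible(x)
}

# Reconstruct a full concentration vector from the independent components:
# x = offset + L %*% y.  Exact affine map precomputed at construction.
reconstruct_state <- function(cons, y) {
  x <- cons$offset + as.numeric(cons$L %*% y)
  names(x) <- cons$species
  x
}
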