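#' @useDynLib adhops, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- auxiliary index utilities ---------------------------------------------

aux_key <- function(k) paste(k, collapse = ",")

# Vectorised keys for the rows of an integer matrix (one aux index per row).
row_keys <- function(K) {
  if (nrow(K) == 0L) return(character(0))
  do.call(paste, c(lapply(seq_len(ncol(K)), function(j) K[, j]), sep = ","))
}

# Fast packed codes for aux index rows: positional encoding in base B packed
# into doubles (exact below 2^53), chunked over modes when one double cannot
# hold the row; used for internal matching only, never shown to users.
fast_keys <- function(K, B) {
  n_modes <- ncol(K)
  if (n_modes == 0L) return(rep(0, nrow(K)))
  chunk <- max(1L, floor(52 / log2(B)))
  n_chunks <- ceiling(n_modes / chunk)
  codes <- matrix(0, nrow(K), n_chunks)
  for (ch in seq_len(n_chunks)) {
    cols <- ((ch - 1L) * chunk + 1L):min(ch * chunk, n_modes)
    codes[, ch] <- K[, cols, drop = FALSE] %*% B^(seq_along(cols) - 1)
  }
  if (n_chunks == 1L) codes[, 1L]
  else do.call(paste, c(lapply(seq_len(n_chunks), function(j) codes[, j]),
                        sep = "_"))
}

#' Step an auxiliary index along one mode
#'
#' Returns k +/- e_n. Stepping below zero is invalid: hierarchy terms indexed
#' by a vector with a negative element are identically zero.
#'
#' @param k non-negative integer vector
#' @param n mode index
#' @param dir +1 (up) or -1 (down)
#' @return the new index vector, or `NULL` when the step is invalid
#' @export
aux_step <- function(k, n, dir = 1L) {
  if (dir < 0 && k[n] == 0L) return(NULL)
  k[n] <- k[n] + as.integer(dir)
  k
}

# ---- triangular basis -------------------------------------------------------

# all non-negative integer vectors of length n with sum <= kmax, as a matrix
enumerate_triangle <- function(n, kmax) {
  if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
  out <- lapply(0:kmax, function(v) {
    rest <- enumerate_triangle(n - 1L, kmax - v)
    cbind(rep.int(v, nrow(rest)), rest, deparse.level = 0)
  })
  do.call(rbind, out)
}

# graded lexicographic row order: by depth, then lexicographic
graded_lex_order <- function(K) {
  depth <- if (ncol(K)) rowSums(K) else rep(0L, nrow(K))
  do.call(order, c(list(depth), lapply(seq_len(ncol(K)), function(j) K[, j])))
}

#' Triangular auxiliary basis
#'
#' Enumerates all auxiliary index vectors with total depth `sum(k) <= k_max`,
#' in deterministic graded lexicographic order with the physical wave function
#' (zero vector) first. Modes flagged Markovian are excluded from the depth
#' budget and enter only as first-order singletons (their index is at most 1
#' and all other entries of such a vector are 0): fast-decaying correction
#' modes only exchange amplitude directly with the physical wave function.
#'
#' @param n_modes number of bath modes
#' @param k_max triangular truncation depth (>= 0)
#' @param markovian logical vector of length `n_modes` (default all FALSE)
#' @return object of class `hierarchy_basis`: list with the index matrix `K`
#'   (one row per auxiliary), `keys`, `n_modes`, `k_max`, `markovian`.
#' @examples
#' triangular_basis(2, 2)$K
#' nrow(triangular_basis(5, 10)$K)  # choose(15, 5) = 3003
#' @export
triangular_basis <- function(n_modes, k_max, markovian = NULL) {
  stopifnot(n_modes >= 1L, k_max >= 0L)
  if (is.null(markovian)) markovian <- rep(FALSE, n_modes)
  stopifnot(length(markovian) == n_modes)
  nm <- which(!markovian)
  Knm <- enumerate_triangle(length(nm), k_max)
  K <- matrix(0L, nrow = nrow(Knm), ncol = n_modes)
  if (length(nm)) K[, nm] <- Knm
  if (any(markovian)) {
    singles <- diag(1L, n_modes)[markovian, , drop = FALSE]
    K <- rbind(K, singles)
  }
  storage.mode(K) <- "integer"
  K <- K[graded_lex_order(K), , drop = FALSE]
  new_hierarchy_basis(K, n_modes, k_max, markovian)
}

new_hierarchy_basis <- function(K, n_modes, k_max, markovian) {
  B <- k_max + 2
  structure(list(K = K, keys = row_keys(K), codes = fast_keys(K, B), B = B,
                 n_modes = n_modes, k_max = k_max, markovian = markovian),
            class = "hierarchy_basis")
}

#' @export
print.hierarchy_basis <- function(x, ...) {
  cat(sprintf("hierarchy basis: %d auxiliaries, %d modes, k_max = %d (%d Markovian modes)\n",
              nrow(x$K), x$n_modes, x$k_max, sum(x$markovian)))
  invisible(x)
}

#' Closed-form size of the triangular basis
#'
#' The number of depth-<=-k_max auxiliaries over `n_modes` modes is
#' C(n_modes + k_max, k_max). The count is computed in exact integer
#' arithmetic (it overflows double precision already for a thousand modes at
#' k_max = 10, where it exceeds 10^23) and returned as a double, with the
#' exact decimal digits in attribute `"digits"`.
#'
#' @param n_modes number of (non-Markovian) modes
#' @param k_max truncation depth
#' @return numeric count; `attr(, "digits")` holds the exact integer as a
#'   decimal string.
#' @examples
#' basis_size_closed_form(5, 10)  # 3003
#' attr(basis_size_closed_form(1000, 10), "digits")
#' @export
basis_size_closed_form <- function(n_modes, k_max) {
  digits <- choose_exact(n_modes + k_max, k_max)
  structure(as.numeric(digits), digits = digits)
}

# Exact binomial coefficient as a decimal digit string, via limb arithmetic
# (base 1e7). C(n, k) is built as a running product C(n-k+i, i), i = 1..k;
# each intermediate is an exact integer so the small divisions are exact.
choose_exact <- function(n, k) {
  k <- min(k, n - k)
  if (k < 0) return("0")
  base <- 1e7
  limbs <- 1 # little-endian limb vector
  mul_small <- function(x, m) {
    carry <- 0
    for (i in seq_along(x)) {
      v <- x[i] * m + carry
      x[i] <- v %% base
      carry <- v %/% base
    }
    while (carry > 0) {
      x <- c(x, carry %% base)
      carry <- carry %/% base
    }
    x
  }
  div_small <- function(x, d) {
    rem <- 0
    for (i in rev(seq_along(x))) {
      v <- rem * base + x[i]
      x[i] <- v %/% d
      rem <- v %% d
    }
    stopifnot(rem == 0)
    while (length(x) > 1 && x[length(x)] == 0) x <- x[-length(x)]
    x
  }
  if (k >= 1) for (i in seq_len(k)) {
    limbs <- mul_small(limbs, n - k + i)
    limbs <- div_small(limbs, i)
  }
  paste0(limbs[length(limbs)],
         paste(sprintf("%07d", rev(limbs[-length(limbs)])), collapse = ""))
}

# ---- neighbor connectivity --------------------------------------------------

# Integer matrices (n_aux x n_modes) giving, for each auxiliary and mode, the
# row of k + e_n (up) / k - e_n (down) in the basis, or 0 when absent.
build_neighbor_tables <- function(basis) {
  K <- basis$K
  n_aux <- nrow(K); n_modes <- ncol(K)
  up <- matrix(0L, n_aux, n_modes)
  down <- matrix(0L, n_aux, n_modes)
  for (m in seq_len(n_modes)) {
    Ku <- K; Ku[, m] <- Ku[, m] + 1L
    up[, m] <- match(fast_keys(Ku, basis$B), basis$codes, nomatch = 0L)
    has <- K[, m] > 0L
    if (any(has)) {
      Kd <- K[has, , drop = FALSE]; Kd[, m] <- Kd[, m] - 1L
      down[has, m] <- match(fast_keys(Kd, basis$B), basis$codes, nomatch = 0L)
    }
  }
  list(up = up, down = down)
}

#' Nearest neighbors of an auxiliary in a basis
#'
#' For each mode, the position of k + e_n and k - e_n within the basis, or
#' `NA` when that neighbor is outside the basis (including the always-invalid
#' step below zero).
#'
#' @param basis a [triangular_basis()]
#' @param aux an index vector belonging to the basis
#' @return list with integer vectors `up` and `down` (NA = absent)
#' @export
aux_neighbors <- function(basis, aux) {
  pos <- match(aux_key(aux), basis$keys)
  if (is.na(pos)) stop("auxiliary is not a member of the basis")
  n_modes <- basis$n_modes
  up <- integer(n_modes); down <- integer(n_modes)
  for (m in seq_len(n_modes)) {
    ku <- aux_step(aux, m, +1L)
    up[m] <- match(aux_key(ku), basis$keys, nomatch = NA_integer_)
    kd <- aux_step(aux, m, -1L)
    down[m] <- if (is.null(kd)) NA_integer_ else
      match(aux_key(kd), basis$keys, nomatch = NA_integer_)
  }
  list(up = up, down = down)
}
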