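#' Specification of a rank- and sparsity-constrained feedback matrix
#'
#' Describes an `n_rows x n_cols` fixed random feedback matrix connecting
#' `n_cols` output errors to `n_rows` hidden neurons, with prescribed rank and
#' sparsity (fraction of exactly-zero entries). Feasibility requires
#' `rank * (1 - sparsity) >= 1`: below that product some error signal can
#' never reach the layer, so generation refuses rather than silently training
#' a network blind to some classes.
#'
#' @param n_rows Hidden-layer width `N`.
#' @param n_cols Number of error signals `M` (output classes).
#' @param rank Target rank `R`, integer in `[1, min(N, M)]`.
#' @param sparsity Target fraction of zero entries `S` in `[0, 1)`. The
#'   per-row support size is `k = round(M * (1 - S))`, so the realized
#'   sparsity is within `1/M` of the request.
#' @param init_bound Half-width of the uniform value distribution; default
#'   `1/sqrt(k)`, which keeps the variance of `B e` invariant across
#'   sparsity levels.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `feedback_spec`.
#' @examples
#' feedback_spec(400, 10, rank = 10, sparsity = 0.9, seed = 1)
#' @export
feedback_spec <- function(n_rows, n_cols, rank, sparsity, init_bound = NULL,
                          seed = 1L) {
  stopifnot(is.numeric(n_rows), is.numeric(n_cols), is.numeric(rank),
            is.numeric(sparsity))
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  rank <- as.integer(rank)
  if (n_rows < 1L || n_cols < 1L) stop("matrix dimensions must be positive",
                                       call. = FALSE)
  if (rank < 1L || rank > min(n_rows, n_cols)) {
    stop(sprintf("rank must lie in [1, %d]", min(n_rows, n_cols)),
         call. = FALSE)
  }
  if (sparsity < 0 || sparsity >= 1) stop("sparsity must lie in [0, 1)",
                                          call. = FALSE)
  k <- as.integer(round(n_cols * (1 - sparsity)))
  if (k < 1L) {
    stop(sprintf(
      "infeasible: per-row support k = round(%d * %.3f) < 1; every row would be empty",
      n_cols, 1 - sparsity), call. = FALSE)
  }
  # tolerance guards float representation of sparsity (e.g. 10 * (1 - 0.9))
  if (rank * (1 - sparsity) < 1 - 1e-9) {
    stop(sprintf(
      paste0("infeasible feedback spec: rank * connectivity = %d * %.3f = %.3f < 1; ",
             "some error columns would be all-zero and those errors would never ",
             "be propagated backwards"),
      rank, 1 - sparsity, rank * (1 - sparsity)), call. = FALSE)
  }
  if (rank * k < n_cols) {
    stop(sprintf(
      "infeasible: rank * per-row support = %d * %d < %d columns; cannot cover every error",
      rank, k, n_cols), call. = FALSE)
  }
  if (is.null(init_bound)) init_bound <- 1 / sqrt(k)
  if (!is.numeric(init_bound) || init_bound <= 0) {
    stop("init_bound must be positive", call. = FALSE)
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols, rank = rank, sparsity = sparsity,
         nnz_per_row = k, init_bound = init_bound, seed = as.integer(seed)),
    class = "feedback_spec"
  )
}

#' @export
print.feedback_spec <- function(x, ...) {
  cat(sprintf("<feedback_spec> %d x %d, rank %d, sparsity %.3f (k = %d/row), seed %d\n",
              x$n_rows, x$n_cols, x$rank, x$sparsity, x$nnz_per_row, x$seed))
  invisible(x)
}

new_feedback_matrix <- function(values, spec) {
  structure(
    list(values = values,
         measured_rank = measure_rank(values),
         measured_sparsity = measure_sparsity(values),
         spec = spec),
    class = "feedback_matrix"
  )
}

#' @export
print.feedback_matrix <- function(x, ...) {
  cat(sprintf("<feedback_matrix> %d x %d, rank %d, sparsity %.3f\n",
              nrow(x$values), ncol(x$values), x$measured_rank,
              x$measured_sparsity))
  invisible(x)
}

# Accept either a feedback_matrix or a bare matrix wherever feedback is used.
feedback_values <- function(B) {
  if (is.null(B)) return(NULL)
  if (inherits(B, "feedback_matrix")) B$values else as.matrix(B)
}

# Deal the columns 1..M (in a random order) round-robin across R base rows of
# capacity k each, then top each row up with random unused columns. Guarantees
# the union of supports covers every column whenever R * k >= M.
deal_supports <- function(R, M, k) {
  perm <- sample.int(M)
  supports <- vector("list", R)
  row <- 1L
  for (col in perm) {
    tries <- 0L
    while (length(supports[[row]]) >= k) {
      row <- row %% R + 1L
      tries <- tries + 1L
      if (tries > R) stop("internal: support dealing overflow", call. = FALSE)
    }
    supports[[row]] <- c(supports[[row]], col)
    row <- row %% R + 1L
  }
  lapply(supports, function(s) {
    extra <- k - length(s)
    if (extra > 0L) {
      pool <- setdiff(seq_len(M), s)
      s <- c(s, pool[sample.int(length(pool), extra)])
    }
    sort(s)
  })
}

#' Generate a feedback matrix with prescribed rank and sparsity
#'
#' Construction: `R` linearly independent base rows are sampled, each with
#' exactly `k = round(M (1 - S))` nonzeros drawn uniform on
#' `[-init_bound, init_bound]`; their supports are dealt round-robin over a
#' random column order so that together they cover all `M` columns. The
#' remaining `N - R` rows are uniform-random nonzero scalar multiples of
#' randomly chosen base rows — linearly dependent rows must share their
#' parent's zero pattern, so every row keeps exactly `k` nonzeros. Row order
#' is then shuffled. The realized rank is verified by SVD; in the
#' measure-zero event of rank deficiency the base rows are resampled with an
#' incremented seed (at most 100 retries, then a hard error).
#'
#' @param spec A [feedback_spec()]; feasibility (`R (1 - S) >= 1`) is
#'   enforced by the spec constructor.
#' @return A `feedback_matrix` with fields `values`, `measured_rank`,
#'   `measured_sparsity`, `spec`. Guaranteed: `measured_rank == spec$rank`,
#'   `|measured_sparsity - spec$sparsity| <= 1/M`, and no all-zero column.
#' @examples
#' B <- generate_feedback(feedback_spec(100, 10, rank = 5, sparsity = 0.5, seed = 3))
#' B$measured_rank
#' @export
generate_feedback <- function(spec) {
  stopifnot(inherits(spec, "feedback_spec"))
  N <- spec$n_rows; M <- spec$n_cols; R <- spec$rank; k <- spec$nnz_per_row
  b <- spec$init_bound
  for (attempt in 0:100) {
    base <- withr::with_seed(spec$seed + attempt, {
      supports <- deal_supports(R, M, k)
      base <- matrix(0, nrow = R, ncol = M)
      for (r in seq_len(R)) {
        base[r, supports[[r]]] <- stats::runif(k, min = -b, max = b)
      }
      base
    })
    if (measure_rank(base) == R) break
    if (attempt == 100L) {
      stop("failed to draw a full-rank base after 100 retries", call. = FALSE)
    }
  }
  values <- withr::with_seed(spec$seed + 101L, {
    values <- base
    if (N > R) {
      parent <- sample.int(R, N - R, replace = TRUE)
      scale <- sample(c(-1, 1), N - R, replace = TRUE) *
        stats::runif(N - R, min = 0.1, max = 1)
      values <- rbind(base, base[parent, , drop = FALSE] * scale)
    }
    values[sample.int(N), , drop = FALSE]
  })
  fb <- new_feedback_matrix(values, spec)
  if (fb$measured_rank != R) {
    stop("internal: generated matrix does not have the requested rank",
         call. = FALSE)
  }
  if (any(colSums(values != 0) == 0L)) {
    stop("internal: generated matrix has an all-zero error column",
         call. = FALSE)
  }
  fb
}

#' Generate a single-connection (SSDFA) feedback matrix
#'
#' Each of the `N` rows holds exactly one nonzero, so each hidden neuron
#' receives exactly one error signal and its error is a product of three
#' scalars. Columns are assigned by dealing a random permutation of the `M`
#' columns round-robin down the rows (so every error column is covered and
#' receives at least `floor(N/M)` connections), with any remaining
#' `N mod M` rows assigned uniformly at random. Sparsity is `(M-1)/M` and
#' rank is `M`.
#'
#' @param n_rows Hidden-layer width `N`; must satisfy `N >= M` so that every
#'   error column can be covered.
#' @param n_cols Number of error signals `M`.
#' @param init_bound Half-width of the uniform value distribution; default 1.
#' @param seed Integer seed.
#' @return A `feedback_matrix` with one structural nonzero per row.
#' @examples
#' B <- generate_ssdfa(25, 10, seed = 1)
#' B$measured_sparsity  # 0.9
#' @export
generate_ssdfa <- function(n_rows, n_cols, init_bound = 1, seed = 1L) {
  N <- as.integer(n_rows); M <- as.integer(n_cols)
  if (N < M) {
    stop(sprintf(
      "infeasible: %d rows cannot cover %d error columns; some error would be unused",
      N, M), call. = FALSE)
  }
  if (!is.numeric(init_bound) || init_bound <= 0) {
    stop("init_bound must be positive", call. = FALSE)
  }
  values <- withr::with_seed(as.integer(seed), {
    cycles <- N %/% M
    rem <- N %% M
    cols <- c(rep(sample.int(M), times = cycles),
              if (rem > 0L) sample.int(M, rem, replace = TRUE))
    vals <- sample(c(-1, 1), N, replace = TRUE) *
      stats::runif(N, min = 0.1, max = 1) * init_bound
    B <- matrix(0, nrow = N, ncol = M)
    B[cbind(seq_len(N), cols)] <- vals
    B
  })
  spec <- feedback_spec(N, M, rank = M, sparsity = (M - 1) / M,
                        init_bound = init_bound, seed = seed)
  new_feedback_matrix(values, spec)
}

#' Fraction of exactly-zero entries
#'
#' Sparsity is quantified as the percentage of zero-valued connections; this
#' measures the structural zeros exactly, with no epsilon thresholding of
#' generated values.
#'
#' @param B A matrix or `feedback_matrix`.
#' @return Scalar in `[0, 1]`.
#' @examples
#' measure_sparsity(diag(3))  # 2/3
#' @export
measure_sparsity <- function(B) {
  B <- feedback_values(B)
  if (length(B) == 0L) stop("empty matrix", call. = FALSE)
  mean(B == 0)
}

#' Numerical rank of a matrix
#'
#' The number of linearly independent rows/columns, computed as the count of
#' singular values above `tol`.
#'
#' @param B A matrix or `feedback_matrix`.
#' @param tol Positive threshold; defaults to
#'   `max(dim(B)) * .Machine$double.eps * max(singular values)`.
#' @return Integer rank.
#' @examples
#' measure_rank(rbind(c(1, 2), c(2, 4)))  # 1
#' @export
measure_rank <- function(B, tol = NULL) {
  B <- feedback_values(B)
  if (length(B) == 0L) stop("empty matrix", call. = FALSE)
  d <- svd(B, nu = 0, nv = 0)$d
  if (is.null(tol)) tol <- max(dim(B)) * .Machine$double.eps * max(d)
  if (length(tol) != 1L || !is.finite(tol) || tol < 0) {
    stop("tol must be a nonnegative scalar", call. = FALSE)
  }
  sum(d > tol)
}

#' Alignment angle between a feedback matrix and downstream forward weights
#'
#' For hidden layer `l` of an `n`-layer network the diagnostic compares `B_l`
#' with the product of all downstream forward weight matrices
#' `P = W_n ... W_{l+1}` (shape `M x width_l`, the transpose of `B_l`'s
#' shape). Both `t(P)` and `B_l` are vectorized and the angle between them is
#' returned in degrees in `[0, 180]`. Under backpropagation the error would
#' travel through `t(P)`; small angles mean the fixed feedback delivers
#' gradient-like directions, and training drives forward weights into
#' alignment with the feedback.
#'
#' @param B A matrix or `feedback_matrix` of shape `width_l x M`.
#' @param downstream_weights A single matrix or list of matrices
#'   `W_{l+1}, ..., W_n` in forward order.
#' @return Angle in degrees.
#' @examples
#' W2 <- matrix(rnorm(6), 2, 3)
#' alignment_angle(t(W2), W2)  # 0
#' @export
alignment_angle <- function(B, downstream_weights) {
  B <- feedback_values(B)
  if (is.matrix(downstream_weights)) downstream_weights <- list(downstream_weights)
  if (!length(downstream_weights)) stop("no downstream weights", call. = FALSE)
  P <- Reduce(function(acc, w) as.matrix(w) %*% acc,
              downstream_weights[-1], as.matrix(downstream_weights[[1]]))
  if (nrow(P) != ncol(B) || ncol(P) != nrow(B)) {
    stop(sprintf("downstream product has shape %dx%d, expected %dx%d",
                 nrow(P), ncol(P), ncol(B), nrow(B)), call. = FALSE)
  }
  v1 <- as.vector(B)
  v2 <- as.vector(t(P))
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    stop("alignment angle undefined for a zero-norm operand", call. = FALSE)
  }
  cosang <- sum(v1 * v2) / (n1 * n2)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Write a feedback matrix as a plain-text triplet file
#'
#' Serializes the structural nonzeros as `row col value` triplets with a
#' `#key value` header carrying the dimensions, target rank/sparsity,
#' init bound and seed. Values are printed with 17 significant digits so that
#' [read_feedback()] round-trips bitwise.
#'
#' @param fb A `feedback_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_feedback <- function(fb, path) {
  stopifnot(inherits(fb, "feedback_matrix"))
  B <- fb$values
  idx <- which(B != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  header <- c(
    sprintf("#n_rows %d", nrow(B)),
    sprintf("#n_cols %d", ncol(B)),
    sprintf("#rank %d", fb$spec$rank),
    sprintf("#sparsity %.17g", fb$spec$sparsity),
    sprintf("#init_bound %.17g", fb$spec$init_bound),
    sprintf("#seed %d", fb$spec$seed),
    "row col value"
  )
  body <- sprintf("%d %d %.17g", idx[, 1], idx[, 2], B[idx])
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a feedback matrix from a triplet file
#'
#' Inverse of [write_feedback()]; the reconstructed values are bitwise equal
#' to the serialized matrix and the rank/sparsity metadata are re-measured on
#' load.
#'
#' @param path File written by [write_feedback()].
#' @return A `feedback_matrix`.
#' @export
read_feedback <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get <- function(key) {
    m <- grep(paste0("^#", key, " "), hdr, value = TRUE)
    if (!length(m)) stop(sprintf("feedback file %s: missing header key '%s'",
                                 path, key), call. = FALSE)
    sub(paste0("^#", key, " "), "", m[1])
  }
  N <- as.integer(get("n_rows")); M <- as.integer(get("n_cols"))
  body <- lines[!grepl("^#", lines)]
  body <- body[body != "" & body != "row col value"]
  if (length(body)) {
    parts <- do.call(rbind, strsplit(body, " ", fixed = TRUE))
    rows <- as.integer(parts[, 1]); cols <- as.integer(parts[, 2])
    vals <- as.numeric(parts[, 3])
  } else {
    rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  }
  if (any(rows < 1L | rows > N | cols < 1L | cols > M)) {
    stop(sprintf("feedback file %s: triplet index out of range", path),
         call. = FALSE)
  }
  B <- matrix(0, nrow = N, ncol = M)
  B[cbind(rows, cols)] <- vals
  spec <- feedback_spec(N, M, rank = as.integer(get("rank")),
                        sparsity = as.numeric(get("sparsity")),
                        init_bound = as.numeric(get("init_bound")),
                        seed = as.integer(get("seed")))
  new_feedback_matrix(B, spec)
}

#' @rdname feedback_tidiers
#' @export
tidy.feedback_matrix <- function(x, ...) {
  idx <- which(x$values != 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  tibble::tibble(row = as.integer(idx[, 1]), col = as.integer(idx[, 2]),
                 value = x$values[idx])
}

#' Tidiers for feedback matrices
#'
#' `tidy()` returns the structural nonzeros as a `row`/`col`/`value` tibble;
#' `glance()` returns a one-row summary with dimensions and measured
#' rank/sparsity.
#'
#' @param x A `feedback_matrix`.
#' @param ... Unused.
#' @name feedback_tidiers
#' @export
glance.feedback_matrix <- function(x, ...) {
  tibble::tibble(
    n_rows = nrow(x$values), n_cols = ncol(x$values),
    rank = x$measured_rank, sparsity = x$measured_sparsity,
    nnz = sum(x$values != 0), seed = x$spec$seed
  )
}
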