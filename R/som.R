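#' SOM grid of meta-EPs
#'
#' Rectangular lattice of codebook vectors ("meta-EPs"). Node indexing is
#' row-major and 1-based: node `k` sits at row `(k-1) %/% width + 1`,
#' column `(k-1) %% width + 1`. The default 40 x 40 grid carries 1600
#' meta-EPs.
#'
#' @param width,height grid shape.
#' @param codebook `K x D` numeric matrix of meta-EPs (K = width*height).
#' @return object of class `som_grid` with fields `width`, `height`,
#'   `codebook`, `coords` (`K x 2` matrix of (row, col)).
#' @export
som_grid <- function(width, height, codebook) {
  width <- as.integer(width); height <- as.integer(height)
  K <- width * height
  if (!is.matrix(codebook) || nrow(codebook) != K)
    stop("som_grid: codebook must be a ", K, " x D matrix")
  coords <- cbind(row = rep(seq_len(height), each = width),
                  col = rep(seq_len(width), times = height))
  structure(list(width = width, height = height,
                 codebook = codebook, coords = coords),
            class = "som_grid")
}

#' @export
print.som_grid <- function(x, ...) {
  cat(sprintf("som_grid: %d x %d (%d nodes), D = %d\n", x$width, x$height,
              x$width * x$height, ncol(x$codebook)))
  invisible(x)
}

#' Training schedule for sequential SOM learning
#'
#' Adaptation gain `alpha` and Gaussian neighborhood radius `sigma` both
#' decrease linearly over epochs (an epoch is one full pass over all EPs).
#'
#' @param epochs number of epochs (positive integer).
#' @param alpha_start,alpha_end adaptation gain endpoints,
#'   `0 < alpha_end <= alpha_start <= 1`.
#' @param sigma_start,sigma_end neighborhood radius endpoints (grid units,
#'   both > 0, non-increasing).
#' @return object of class `training_schedule`.
#' @export
training_schedule <- function(epochs, alpha_start = 0.05, alpha_end = 0.005,
                              sigma_start = 10, sigma_end = 1) {
  epochs <- as.integer(epochs)
  if (epochs < 1) stop("training_schedule: epochs must be >= 1")
  if (!(alpha_end >= 0 && alpha_end <= alpha_start && alpha_start <= 1))
    stop("training_schedule: need 0 <= alpha_end <= alpha_start <= 1")
  if (!(sigma_end > 0 && sigma_end <= sigma_start))
    stop("training_schedule: need 0 < sigma_end <= sigma_start")
  structure(list(epochs = epochs, alpha_start = alpha_start,
                 alpha_end = alpha_end, sigma_start = sigma_start,
                 sigma_end = sigma_end),
            class = "training_schedule")
}

#' Default epoch count for a target of ~200,000 profile presentations
#'
#' @param n_profiles number of EPs.
#' @param target total presentations aimed for (default 2e5).
#' @return integer epochs, at least 1; warns when `n_profiles` exceeds the
#'   target so a single epoch already overshoots.
#' @export
default_epochs <- function(n_profiles, target = 200000L) {
  if (n_profiles < 1) stop("default_epochs: need at least one profile")
  if (n_profiles > target) {
    warning("default_epochs: ", n_profiles, " profiles exceed the ~",
            target, " presentation target; using 1 epoch")
    return(1L)
  }
  max(1L, as.integer(round(target / n_profiles)))
}

#' Linear (PCA) initialization of the meta-EPs
#'
#' The two leading principal axes of the EP covariance are mapped onto the
#' width and height of the grid: the meta-EP at (row r, col c) is
#' `mu + a(c) * 2*sqrt(lambda1) * u1 + b(r) * 2*sqrt(lambda2) * u2`, with
#' `a`, `b` linear maps of columns/rows onto `[-1, 1]`. This puts the data
#' mean in the center of the SOM and makes training deterministic (no
#' random initialization). If the second eigenvalue is (numerically) zero,
#' an arbitrary unit vector orthogonal to `u1` is used with a flat axis and
#' a warning.
#'
#' @param profiles `N x D` EP matrix (N >= 2 for a non-degenerate
#'   covariance).
#' @param width,height grid shape (defaults 40 x 40).
#' @param span half-width of the grid in units of `sqrt(lambda)` along each
#'   axis (default 2).
#' @return a [som_grid()].
#' @export
linear_initialize <- function(profiles, width = 40L, height = 40L, span = 2) {
  X <- as.matrix(profiles)
  if (nrow(X) < 1) stop("linear_initialize: empty profile matrix")
  D <- ncol(X)
  mu <- colMeans(X)
  if (nrow(X) == 1) {
    eval <- c(0, 0)
    u1 <- c(1, rep(0, D - 1)); u2 <- c(0, 1, rep(0, D - 2))[seq_len(D)]
  } else {
    cv <- stats::cov(X)
    ed <- eigen(cv, symmetric = TRUE)
    eval <- pmax(ed$values, 0)
    u1 <- ed$vectors[, 1]
    tol <- max(eval[1], 1) * 1e-12
    if (D >= 2 && eval[2] > tol) {
      u2 <- ed$vectors[, 2]
    } else {
      warning("linear_initialize: fewer than 2 informative components; ",
              "using a flat orthogonal second axis")
      u2 <- .orthogonal_unit(u1, D)
      eval[2] <- 0
    }
    if (eval[1] <= tol) eval[1] <- 0
  }
  a <- if (width == 1) 0 else (2 * (seq_len(width) - 1) / (width - 1)) - 1
  b <- if (height == 1) 0 else (2 * (seq_len(height) - 1) / (height - 1)) - 1
  K <- width * height
  codebook <- matrix(rep(mu, each = K), nrow = K)
  amp1 <- span * sqrt(eval[1]); amp2 <- span * sqrt(if (D >= 2) eval[2] else 0)
  arep <- rep(a, times = height)   # row-major node order
  brep <- rep(b, each = width)
  codebook <- codebook + outer(arep, amp1 * u1) + outer(brep, amp2 * u2)
  colnames(codebook) <- colnames(X)
  som_grid(width, height, codebook)
}

.orthogonal_unit <- function(u, D) {
  if (D == 1) return(1)
  basis <- diag(D)
  proj <- abs(as.vector(basis %*% u))
  v <- basis[, which.min(proj)]
  v <- v - sum(v * u) * u
  v / sqrt(sum(v^2))
}

#' Gaussian neighborhood function on the grid
#'
#' `exp(-d^2 / (2 sigma^2))` with `d` the Euclidean distance between the
#' two nodes' grid coordinates; equals 1 at distance 0 and decays
#' asymptotically to zero for distant nodes.
#'
#' @param node_a,node_b grid coordinates, numeric `(row, col)` pairs.
#' @param sigma neighborhood radius, > 0.
#' @return value in `(0, 1]`.
#' @export
neighborhood <- function(node_a, node_b, sigma) {
  if (sigma <= 0) stop("neighborhood: validation error: sigma must be > 0")
  d2 <- sum((as.numeric(node_a) - as.numeric(node_b))^2)
  exp(-d2 / (2 * sigma^2))
}

#' Train the SOM by deterministic sequential competitive learning
#'
#' For each epoch, `alpha` and `sigma` are set by linear interpolation
#' between their endpoints; profiles are presented in input order (no
#' shuffling -- determinism). For each presented EP `e`, the best-matching
#' node is the one with minimal squared Euclidean distance (ties go to the
#' lowest node index), and every meta-EP is updated as
#' `x_j' = x_j + alpha * h(j, winner; sigma) * (e - x_j)` with the Gaussian
#' [neighborhood()]. After the final epoch, assignments are recomputed once
#' with frozen meta-EPs.
#'
#' @param profiles `N x D` EP matrix.
#' @param grid a [som_grid()] (typically from [linear_initialize()]).
#' @param schedule a [training_schedule()].
#' @return list with `grid` (trained [som_grid()]) and `assignment`
#'   (integer vector: node index per profile).
#' @export
som_train <- function(profiles, grid, schedule) {
  X <- as.matrix(profiles)
  if (nrow(X) < 1) stop("som_train: validation error: empty profile list")
  if (ncol(X) != ncol(grid$codebook))
    stop("som_train: validation error: profile dimension ", ncol(X),
         " != codebook dimension ", ncol(grid$codebook))
  stopifnot(inherits(schedule, "training_schedule"))
  res <- som_train_cpp(X, grid$codebook, grid$coords,
                       schedule$epochs, schedule$alpha_start,
                       schedule$alpha_end, schedule$sigma_start,
                       schedule$sigma_end)
  out_grid <- som_grid(grid$width, grid$height, res$codebook)
  colnames(out_grid$codebook) <- colnames(grid$codebook)
  list(grid = out_grid, assignment = as.integer(res$assignment))
}

#' Assign profiles to their best-matching nodes (frozen codebook)
#' @param profiles `N x D` matrix.
#' @param grid a [som_grid()].
#' @return integer vector of node indices (ties to the lowest index).
#' @export
som_assign <- function(profiles, grid) {
  X <- as.matrix(profiles)
  as.integer(som_assign_cpp(X, grid$codebook))
}

#' Mean quantization error
#'
#' Mean Euclidean distance between each EP and its assigned meta-EP.
#'
#' @param profiles `N x D` matrix.
#' @param grid a [som_grid()].
#' @param assignment integer vector from [som_train()] or [som_assign()].
#' @return non-negative scalar.
#' @export
quantization_error <- function(profiles, grid, assignment) {
  X <- as.matrix(profiles)
  if (length(assignment) != nrow(X))
    stop("quantization_error: assignment length mismatch")
  d <- sqrt(rowSums((X - grid$codebook[assignment, , drop = FALSE])^2))
  mean(d)
}

#' Write / read a SOM grid as TSV (node, row, col, meta-EP columns)
#' @param grid a [som_grid()].
#' @param path TSV path.
#' @export
write_som <- function(grid, path) {
  dt <- data.table::data.table(node = seq_len(nrow(grid$codebook)),
                               row = grid$coords[, "row"],
                               col = grid$coords[, "col"])
  cb <- data.table::as.data.table(grid$codebook)
  if (is.null(colnames(grid$codebook)))
    data.table::setnames(cb, paste0("d", seq_len(ncol(cb))))
  data.table::fwrite(cbind(dt, cb), path, sep = "\t")
  invisible(path)
}

#' @rdname write_som
#' @return `read_som` returns a [som_grid()].
#' @export
read_som <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  width <- max(dt$col); height <- max(dt$row)
  cb <- as.matrix(dt[, !c("node", "row", "col")])
  som_grid(width, height, cb)
}
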