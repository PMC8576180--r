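#' Probe ("DIC") displacement field
#'
#' Container for full-field surface displacement measurements: reference
#' probe coordinates and 3-component displacements per probe per inflation
#' stage, as produced by a stereo digital-image-correlation system (or by the
#' synthetic generator).
#'
#' @param coords n_probes x 3 matrix of reference coordinates, mm.
#' @param u n_probes x 3 x n_stages array of displacements, mm.
#' @param stage_ids optional stage labels (default `1:n_stages`).
#' @return object of class `probe_field`.
#' @export
probe_field <- function(coords, u, stage_ids = NULL) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  if (length(dim(u)) == 2L) u <- array(u, c(dim(u), 1L))
  stopifnot(length(dim(u)) == 3L, dim(u)[2] == 3L)
  if (dim(u)[1] != nrow(coords))
    stop("coordinate/displacement row counts do not match")
  if (is.null(stage_ids)) stage_ids <- seq_len(dim(u)[3])
  stopifnot(length(stage_ids) == dim(u)[3])
  if (nrow(coords) > 1L) {
    o <- do.call(order, as.data.frame(coords))
    d <- diff(coords[o, , drop = FALSE])
    if (any(rowSums(abs(d)) < 1e-9))
      stop("duplicate probe coordinates within 1e-9 mm")
  }
  structure(list(coords = coords, u = u, stage_ids = stage_ids),
            class = "probe_field")
}

#' @method print probe_field
#' @export
print.probe_field <- function(x, ...) {
  cat(sprintf("probe_field: %d probes, %d stages, max |u| %.4g mm\n",
              nrow(x$coords), dim(x$u)[3],
              max(sqrt(x$u[, 1, ]^2 + x$u[, 2, ]^2 + x$u[, 3, ]^2))))
  invisible(x)
}

#' Fit a k-nearest-neighbor displacement interpolator
#'
#' Builds the interpolation model between probe points and arbitrary query
#' locations: the prediction at a query is the unweighted mean of the
#' displacements of its `k` nearest probes (Euclidean distance on reference
#' coordinates; ties broken by probe index order). Deterministic given the
#' input order.
#'
#' @param field a [probe_field()].
#' @param k neighbor count (default 5).
#' @return object of class `knn_interpolator`.
#' @export
fit_interpolator <- function(field, k = 5L) {
  stopifnot(inherits(field, "probe_field"))
  if (k < 1L || k > nrow(field$coords))
    stop("k must be between 1 and the probe count")
  structure(list(coords = field$coords, u = field$u,
                 stage_ids = field$stage_ids, k = as.integer(k)),
            class = "knn_interpolator")
}

#' @rdname fit_interpolator
#' @param object a fitted `knn_interpolator`.
#' @param query m x 3 matrix of query coordinates.
#' @param stage stage id to interpolate (must exist in the model).
#' @param ... unused.
#' @return m x 3 matrix of interpolated displacements.
#' @export
predict.knn_interpolator <- function(object, query, stage = 1, ...) {
  s <- match(stage, object$stage_ids)
  if (is.na(s)) stop("unknown stage: ", stage)
  query <- as.matrix(query)
  idx <- knn_cpp(object$coords, query, object$k)
  us <- object$u[, , s, drop = TRUE]
  if (is.null(dim(us))) us <- matrix(us, ncol = 3)
  out <- matrix(0, nrow(query), 3)
  for (j in seq_len(object$k)) out <- out + us[idx[, j], , drop = FALSE]
  out / object$k
}

#' Sparse kNN interpolation operator
#'
#' The linear map `W` whose rows average the `k` nearest reference points of
#' each query (entries 1/k). Applied to a stacked 3n displacement vector via
#' `W %x% I3` (see [expand_operator()]); the same operator drives the probe
#' residual term of the adjoint load.
#'
#' @param ref_coords N x 3 reference point coordinates.
#' @param query_coords Q x 3 query coordinates.
#' @param k neighbor count.
#' @return a `dgCMatrix` of dimension Q x N.
#' @export
interpolation_matrix <- function(ref_coords, query_coords, k = 5L) {
  ref_coords <- as.matrix(ref_coords)
  query_coords <- as.matrix(query_coords)
  idx <- knn_cpp(ref_coords, query_coords, k)
  Q <- nrow(query_coords)
  Matrix::sparseMatrix(i = rep(seq_len(Q), k), j = as.integer(idx),
                       x = 1 / k, dims = c(Q, nrow(ref_coords)))
}

#' @rdname interpolation_matrix
#' @param W a Q x N operator from [interpolation_matrix()].
#' @return the 3Q x 3N operator acting on interleaved (x,y,z) dof vectors.
#' @export
expand_operator <- function(W) {
  W %x% Matrix::Diagonal(3)
}

#' Write the interpolation operator as a sparse triplet file
#'
#' @param W operator from [interpolation_matrix()].
#' @param path output path (CSV with columns row,col,value).
#' @export
write_operator_triplets <- function(W, path) {
  T3 <- methods::as(W, "TsparseMatrix")
  utils::write.csv(data.frame(row = T3@i + 1L, col = T3@j + 1L, value = T3@x),
                   path, row.names = FALSE)
  invisible(path)
}

#' Cross-validated interpolation accuracy
#'
#' Splits the probes into `folds` seeded folds; for each fold fits the kNN
#' interpolator on the remainder and scores the held-out probes. "Accuracy"
#' is the coefficient of determination (R^2, computed against the held-out
#' mean), per fold and displacement component, pooled over stages; the mean
#' accuracy averages over folds and components. A zero-variance component in
#' a fold is reported `NA` with a warning and excluded from the mean.
#'
#' @param field a [probe_field()].
#' @param folds number of folds (default 10).
#' @param k neighbor count (default 5).
#' @param seed RNG seed for the fold assignment.
#' @return object of class `cv_report`: `scores` (folds x 3 matrix),
#'   `mean_accuracy`, `folds`, `k`.
#' @export
cross_validate <- function(field, folds = 10L, k = 5L, seed = 1L) {
  n <- nrow(field$coords)
  if (n < folds) stop("probe count must be at least the number of folds")
  ns <- dim(field$u)[3]
  assign_fold <- local({
    set.seed(seed)
    sample(rep(seq_len(folds), length.out = n))
  })
  scores <- matrix(NA_real_, folds, 3,
                   dimnames = list(NULL, c("ux", "uy", "uz")))
  for (f in seq_len(folds)) {
    test <- which(assign_fold == f)
    train <- which(assign_fold != f)
    tf <- probe_field(field$coords[train, , drop = FALSE],
                      field$u[train, , , drop = FALSE], field$stage_ids)
    mod <- fit_interpolator(tf, k = k)
    pred <- array(0, c(length(test), 3, ns))
    for (s in seq_len(ns))
      pred[, , s] <- predict(mod, field$coords[test, , drop = FALSE],
                             stage = field$stage_ids[s])
    truth <- field$u[test, , , drop = FALSE]
    for (comp in 1:3) {
      y <- as.numeric(truth[, comp, ])
      yhat <- as.numeric(pred[, comp, ])
      sst <- sum((y - mean(y))^2)
      if (sst == 0) {
        warning(sprintf("fold %d component %d: zero-variance target, score undefined",
                        f, comp))
        next
      }
      scores[f, comp] <- 1 - sum((y - yhat)^2) / sst
    }
  }
  structure(list(scores = scores,
                 mean_accuracy = mean(scores, na.rm = TRUE),
                 folds = folds, k = k, seed = seed),
            class = "cv_report")
}

#' @method print cv_report
#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: %d-fold, k = %d; mean accuracy (R^2) = %.4f\n",
              x$folds, x$k, x$mean_accuracy))
  cat("per-component means:",
      paste(sprintf("%s = %.4f", colnames(x$scores),
                    colMeans(x$scores, na.rm = TRUE)), collapse = ", "), "\n")
  invisible(x)
}

#' Probe field CSV I/O
#'
#' Long-format CSV with columns `probe_id,x,y,z,stage,ux,uy,uz`; the
#' roundtrip is lossless to better than 1e-9.
#'
#' @param path CSV path.
#' @return a [probe_field()] (`read_probe_csv`); invisibly the path
#'   (`write_probe_csv`).
#' @export
read_probe_csv <- function(path) {
  tab <- utils::read.csv(path)
  need <- c("probe_id", "x", "y", "z", "stage", "ux", "uy", "uz")
  if (!all(need %in% names(tab)))
    stop("probe CSV must have columns ", paste(need, collapse = ","))
  if (nrow(tab) == 0L) stop("empty probe field in ", path)
  ids <- sort(unique(tab$probe_id))
  stages <- sort(unique(tab$stage))
  n <- length(ids); ns <- length(stages)
  first <- tab[match(ids, tab$probe_id), ]
  coords <- as.matrix(first[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  u <- array(NA_real_, c(n, 3, ns))
  pi_ <- match(tab$probe_id, ids)
  si <- match(tab$stage, stages)
  u[cbind(pi_, 1L, si)] <- tab$ux
  u[cbind(pi_, 2L, si)] <- tab$uy
  u[cbind(pi_, 3L, si)] <- tab$uz
  if (any(is.na(u))) stop("probe CSV is missing probe/stage combinations")
  probe_field(coords, u, stage_ids = stages)
}

#' @rdname read_probe_csv
#' @param field a [probe_field()].
#' @export
write_probe_csv <- function(field, path) {
  n <- nrow(field$coords); ns <- dim(field$u)[3]
  rows <- do.call(rbind, lapply(seq_len(ns), function(s) {
    data.frame(probe_id = seq_len(n),
               x = field$coords[, 1], y = field$coords[, 2],
               z = field$coords[, 3],
               stage = field$stage_ids[s],
               ux = field$u[, 1, s], uy = field$u[, 2, s],
               uz = field$u[, 3, s])
  }))
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
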